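#' Construct a current-time trace
#'
#' A trace is a uniformly sampled ionic-current recording through a
#' solid-state nanopore. Currents are held internally in nanoamperes;
#' unit conversion happens only at the I/O boundary (see [read_trace()]).
#' The time of sample `i` (0-based) is `start_time + i / sampling_rate`.
#'
#' @param samples Numeric vector of current values in nanoamperes. Must be
#'   non-empty and finite.
#' @param sampling_rate Sampling rate in hertz (finite, > 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param meta Named list or character vector of free-form metadata
#'   (condition labels such as salt, temperature, incubation minutes,
#'   applied voltage).
#' @return An object of class `pd_trace`: a list with fields `samples`,
#'   `sampling_rate`, `start_time` and `meta`.
#' @seealso [read_trace()], [detect_events()], [simulate_trace()]
#' @examples
#' tr <- pd_trace(rnorm(1000, 10, 0.01), sampling_rate = 1e5)
#' tr
#' @export
pd_trace <- function(samples, sampling_rate, start_time = 0, meta = list()) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("'samples' must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  stopifnot(is.numeric(start_time), length(start_time) == 1L,
            is.finite(start_time))
  meta <- as.list(meta)
  if (length(meta) && (is.null(names(meta)) || any(names(meta) == ""))) {
    stop("'meta' entries must all be named", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time),
         meta = lapply(meta, as.character)),
    class = "pd_trace"
  )
}

#' @export
print.pd_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<pd_trace> %d samples @ %g Hz (%.4g s), current %.4g..%.4g nA\n",
              length(x$samples), x$sampling_rate, dur,
              min(x$samples), max(x$samples)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A [pd_trace()].
#' @return Numeric vector of times in seconds, one per sample.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "pd_trace"))
  trace$start_time + (seq_along(trace$samples) - 1) / trace$sampling_rate
}

# Parse "# key=value" comment lines into a named character vector.
parse_header_block <- function(lines) {
  kv <- character(0)
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(body, 1L, eq - 1L))
      val <- trimws(substr(body, eq + 1L, nchar(body)))
      kv[key] <- val
    }
  }
  kv
}

#' Read a current-time trace from delimited text
#'
#' Reads the package's plain-text trace dialect: an optional block of
#' `# key=value` header lines, an optional column-name row, then one row
#' per sample, comma- or tab-delimited. The sampling rate must be supplied
#' either by the header key `sampling_rate_hz` or by the `sampling_rate`
#' argument (the argument wins). Currents are converted to nanoamperes on
#' load: unit `"nA"` (default) is taken as-is, `"pA"` is divided by 1000.
#' The unit may come from the header key `unit` or the `unit` argument.
#'
#' If a time column is present and its median spacing disagrees with the
#' declared sampling rate by more than 1%, a warning is raised and recorded
#' in `meta$rate_mismatch`; the declared rate wins.
#'
#' The reader is locale-independent (decimal point only) and accepts both
#' LF and CRLF line endings.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the first data row.
#' @param columns Named integer vector mapping roles to column indices,
#'   e.g. `c(time = 1, current = 2)`. Use `c(current = 1)` for a
#'   current-only file. Exactly one current column must resolve.
#' @param sampling_rate Optional explicit sampling rate in Hz; overrides the
#'   header.
#' @param unit Optional current unit, `"nA"` or `"pA"`; overrides the header.
#' @param negate Logical; negate currents on load (recordings under negative
#'   applied voltage, so that blockades are downward deviations). Default
#'   `FALSE`.
#' @return A [pd_trace()]. Header keys other than `sampling_rate_hz` and
#'   `unit` are carried into `meta`.
#' @export
read_trace <- function(path, delim = NULL, columns = c(time = 1, current = 2),
                       sampling_rate = NULL, unit = NULL, negate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty trace file: ", path, call. = FALSE)

  is_hdr <- startsWith(lines, "#")
  hdr <- parse_header_block(lines[is_hdr])
  body <- lines[!is_hdr]
  if (!length(body)) stop("trace file has no data rows: ", path, call. = FALSE)

  if (is.null(delim)) delim <- if (grepl("\t", body[[1]])) "\t" else ","

  # optional column-name row: first body row with a non-numeric first field
  first_fields <- strsplit(body[[1]], delim, fixed = TRUE)[[1]]
  has_names <- suppressWarnings(anyNA(as.numeric(trimws(first_fields))))
  col_names <- NULL
  if (has_names) {
    col_names <- trimws(first_fields)
    body <- body[-1]
    if (!length(body)) stop("trace file has no data rows: ", path, call. = FALSE)
  }

  # resolve column map against names when available
  if (!is.null(col_names)) {
    idx_cur <- match(c("current_nA", "current_pA", "current", "i"), col_names)
    idx_cur <- idx_cur[!is.na(idx_cur)]
    idx_t <- match(c("time_s", "time", "t"), col_names)
    idx_t <- idx_t[!is.na(idx_t)]
    if (length(idx_cur)) columns <- c(
      if (length(idx_t)) c(time = idx_t[[1]]), c(current = idx_cur[[1]]))
    if (is.null(unit) && length(idx_cur) && col_names[idx_cur[[1]]] == "current_pA") {
      unit <- "pA"
    }
  }
  if (!"current" %in% names(columns)) {
    stop("column map must name a 'current' column", call. = FALSE)
  }

  fields <- strsplit(body, delim, fixed = TRUE)
  ncol_needed <- max(columns)
  bad <- which(vapply(fields, length, 1L) < ncol_needed)
  if (length(bad)) {
    stop(sprintf("row %d has fewer than %d fields", bad[[1]], ncol_needed),
         call. = FALSE)
  }
  get_col <- function(j) {
    raw <- vapply(fields, `[[`, "", j)
    val <- suppressWarnings(as.numeric(trimws(raw)))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite value '%s' at data row %d",
                   raw[bad[[1]]], bad[[1]]), call. = FALSE)
    }
    val
  }
  current <- get_col(columns[["current"]])

  unit <- unit %||% unname(hdr["unit"])
  if (is.na(unit %||% NA)) unit <- "nA"
  unit <- match.arg(unit, c("nA", "pA"))
  if (unit == "pA") current <- current / 1000
  if (isTRUE(negate)) current <- -current

  rate <- sampling_rate %||%
    suppressWarnings(as.numeric(hdr["sampling_rate_hz"]))
  if (is.null(rate) || is.na(rate)) {
    stop("sampling rate not available: supply header key 'sampling_rate_hz' ",
         "or the 'sampling_rate' argument", call. = FALSE)
  }
  stop_if_not_scalar_pos(rate, "sampling_rate")

  meta <- as.list(hdr[setdiff(names(hdr), c("sampling_rate_hz", "unit"))])
  start_time <- 0
  if ("time" %in% names(columns)) {
    tcol <- get_col(columns[["time"]])
    start_time <- tcol[[1]]
    if (length(tcol) > 2) {
      dt_obs <- stats::median(diff(tcol))
      if (dt_obs > 0 && abs(dt_obs - 1 / rate) / (1 / rate) > 0.01) {
        msg <- sprintf(
          "time-column spacing (%.6g s) disagrees with declared rate %g Hz by >1%%; declared rate wins",
          dt_obs, rate)
        warning(msg, call. = FALSE)
        meta$rate_mismatch <- msg
      }
    }
  }
  pd_trace(current, sampling_rate = rate, start_time = start_time, meta = meta)
}

#' Write a trace as delimited text
#'
#' Inverse of [read_trace()]: writes a `# key=value` header block (always
#' including `sampling_rate_hz` and `unit=nA`), a column-name row
#' `time_s,current_nA`, and one row per sample at full precision (17
#' significant digits), so that `read_trace(write_trace(x))` reproduces
#' `x` exactly.
#'
#' @param trace A [pd_trace()].
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path, delim = ",") {
  stopifnot(inherits(trace, "pd_trace"))
  hdr <- c(sprintf("# sampling_rate_hz=%s", format_full(trace$sampling_rate)),
           "# unit=nA",
           if (length(trace$meta))
             sprintf("# %s=%s", names(trace$meta), unlist(trace$meta)))
  tms <- trace_times(trace)
  rows <- paste(format_full(tms), format_full(trace$samples), sep = delim)
  writeLines(c(hdr, paste("time_s", "current_nA", sep = delim), rows), path)
  invisible(path)
}
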