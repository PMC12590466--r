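EVENT_COLS <- c("start_s", "dwell_s", "peak_current_nA", "ecd_pC",
                "baseline_nA")

#' Construct an event table
#'
#' One row per detected translocation event. Column names carry the units:
#' `start_s` and `dwell_s` in seconds, `peak_current_nA` and `baseline_nA`
#' in nanoamperes, `ecd_pC` (event charge deficit) in picocoulombs
#' (1 nA*ms = 1 pC). Events must be sorted by start time and
#' non-overlapping; dwell times strictly positive; the ECD can never
#' exceed the event's bounding rectangle `peak * dwell * 1000`.
#'
#' @param df Data frame with (at least) the mandatory columns listed above.
#'   An empty (0-row) table is valid.
#' @param meta Named list of condition metadata copied from the source
#'   trace.
#' @param provenance Named list describing where the table came from
#'   (source file, detection settings digest).
#' @return An object of class `pd_events` (a data frame with `meta` and
#'   `provenance` attributes).
#' @export
pd_events <- function(df = NULL, meta = list(), provenance = list()) {
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(EVENT_COLS)), EVENT_COLS))
  }
  df <- as.data.frame(df)
  missing_cols <- setdiff(EVENT_COLS, names(df))
  if (length(missing_cols)) {
    stop("event table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, union(EVENT_COLS, names(df)), drop = FALSE]
  rownames(df) <- NULL
  out <- structure(df, class = c("pd_events", "data.frame"),
                   meta = as.list(meta), provenance = as.list(provenance))
  validate_events(out)
  out
}

#' Validate an event table against its invariants
#'
#' Checks finiteness of every numeric field, `dwell_s > 0`,
#' `peak_current_nA >= 0`, `0 <= ecd_pC <= peak_current_nA * dwell_s * 1000`
#' (with a 1e-9 relative slack for floating-point), and that events are
#' sorted by start and non-overlapping.
#'
#' @param events A `pd_events` table.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_events <- function(events) {
  stopifnot(inherits(events, "pd_events"))
  if (nrow(events) == 0L) return(invisible(TRUE))
  num <- as.matrix(events[, EVENT_COLS])
  if (anyNA(num) || any(!is.finite(num))) {
    stop("event table contains non-finite values", call. = FALSE)
  }
  if (any(events$dwell_s <= 0)) {
    stop("event table contains dwell_s <= 0", call. = FALSE)
  }
  if (any(events$peak_current_nA < 0) || any(events$ecd_pC < 0)) {
    stop("peak_current_nA and ecd_pC must be >= 0", call. = FALSE)
  }
  cap <- events$peak_current_nA * events$dwell_s * 1000
  if (any(events$ecd_pC > cap * (1 + 1e-9) + 1e-12)) {
    stop("ecd_pC exceeds peak_current_nA * dwell_s * 1000", call. = FALSE)
  }
  if (nrow(events) > 1L) {
    s <- events$start_s
    e <- s + events$dwell_s
    if (is.unsorted(s, strictly = FALSE)) {
      stop("events must be sorted by start_s", call. = FALSE)
    }
    if (any(s[-1] < e[-nrow(events)] - 1e-12)) {
      stop("events must be non-overlapping", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.pd_events <- function(x, ...) {
  cat(sprintf("<pd_events> %d events\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Write an event table as delimited text
#'
#' Writes `# key=value` header lines for metadata and provenance, a header
#' row whose column names carry the units, then one row per event at 17
#' significant digits so the round trip [read_events()] reproduces every
#' field at full stored precision. Output is byte-stable: the same table
#' always produces the same file.
#'
#' @param events A [pd_events()] table (validated before writing).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  meta <- attr(events, "meta")
  prov <- attr(events, "provenance")
  hdr <- c(
    if (length(meta)) sprintf("# meta.%s=%s", names(meta), unlist(meta)),
    if (length(prov)) sprintf("# provenance.%s=%s", names(prov), unlist(prov))
  )
  cols <- lapply(events[, EVENT_COLS], format_full)
  rows <- do.call(paste, c(cols, sep = ","))
  writeLines(c(hdr, paste(EVENT_COLS, collapse = ","), rows), path)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path Path to the file.
#' @return A [pd_events()] table with `meta` and `provenance` restored.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(lines, "#")
  kv <- parse_header_block(lines[is_hdr])
  body <- lines[!is_hdr]
  if (!length(body)) stop("malformed event table: no header row", call. = FALSE)
  cols <- strsplit(body[[1]], ",", fixed = TRUE)[[1]]
  if (!all(EVENT_COLS %in% cols)) {
    stop("malformed event table header: expected columns ",
         paste(EVENT_COLS, collapse = ","), call. = FALSE)
  }
  rows <- body[-1]
  if (length(rows)) {
    mat <- do.call(rbind, strsplit(rows, ",", fixed = TRUE))
    if (ncol(mat) != length(cols)) {
      stop("malformed event table: ragged rows", call. = FALSE)
    }
    df <- as.data.frame(apply(mat, 2, as.numeric, simplify = FALSE))
    names(df) <- cols
    if (anyNA(df)) stop("malformed event table: non-numeric field", call. = FALSE)
  } else {
    df <- NULL
  }
  keys <- names(kv) %||% character(0)
  meta <- as.list(kv[startsWith(keys, "meta.")])
  names(meta) <- sub("^meta\\.", "", names(meta))
  prov <- as.list(kv[startsWith(keys, "provenance.")])
  names(prov) <- sub("^provenance\\.", "", names(prov))
  pd_events(df, meta = meta, provenance = prov)
}

#' Paired ECD / peak-current features for plotting
#'
#' Order-preserving projection of the two discriminating event features:
#' event charge deficit (a molecular-weight proxy) against peak blockade
#' current, the scatter conventionally used to separate full-length from
#' fragmented molecules.
#'
#' @param events A [pd_events()] table.
#' @return Data frame with columns `ecd_pC` and `peak_current_nA`, one row
#'   per event in table order; empty for an empty table.
#' @export
scatter_features <- function(events) {
  stopifnot(inherits(events, "pd_events"))
  data.frame(ecd_pC = events$ecd_pC,
             peak_current_nA = events$peak_current_nA)
}
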