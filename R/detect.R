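#' Detection settings for translocation-event search
#'
#' Thresholds are expressed as multiples of the robust noise scale sigma
#' (1.4826 * MAD of the baseline-subtracted trace), so settings transfer
#' across recordings with different noise levels. An event opens where the
#' current drops more than `threshold_sigmas * sigma` below the local
#' baseline and extends to the nearest crossings of
#' `hysteresis_sigmas * sigma` on either side.
#'
#' @param baseline_window_s Width of the centered moving-median baseline
#'   window, seconds. Must cover at least 10 samples of the trace it is
#'   applied to.
#' @param threshold_sigmas Event-opening threshold, in noise sigmas
#'   (default 5).
#' @param hysteresis_sigmas Event-boundary threshold, in noise sigmas
#'   (default 1); must be < `threshold_sigmas`.
#' @param min_dwell_s Minimum dwell time, seconds. `NULL` (default) means
#'   3 samples at the trace's sampling rate.
#' @param merge_gap_s Events separated by less than this gap are merged,
#'   seconds. `NULL` (default) means 1 sample.
#' @return An object of class `pd_detection_settings`.
#' @export
detection_settings <- function(baseline_window_s = 0.05,
                               threshold_sigmas = 5,
                               hysteresis_sigmas = 1,
                               min_dwell_s = NULL,
                               merge_gap_s = NULL) {
  stop_if_not_scalar_pos(baseline_window_s, "baseline_window_s")
  stop_if_not_scalar_pos(threshold_sigmas, "threshold_sigmas")
  stop_if_not_scalar_pos(hysteresis_sigmas, "hysteresis_sigmas")
  if (!is.null(min_dwell_s)) stop_if_not_scalar_pos(min_dwell_s, "min_dwell_s")
  if (!is.null(merge_gap_s)) stop_if_not_scalar_pos(merge_gap_s, "merge_gap_s")
  if (hysteresis_sigmas >= threshold_sigmas) {
    stop("hysteresis_sigmas must be < threshold_sigmas", call. = FALSE)
  }
  structure(list(baseline_window_s = baseline_window_s,
                 threshold_sigmas = threshold_sigmas,
                 hysteresis_sigmas = hysteresis_sigmas,
                 min_dwell_s = min_dwell_s,
                 merge_gap_s = merge_gap_s),
            class = "pd_detection_settings")
}

settings_digest <- function(settings, trace) {
  fs <- trace$sampling_rate
  sprintf("win=%gs;thr=%gsig;hys=%gsig;min_dwell=%gs;merge_gap=%gs",
          settings$baseline_window_s, settings$threshold_sigmas,
          settings$hysteresis_sigmas,
          settings$min_dwell_s %||% (3 / fs),
          settings$merge_gap_s %||% (1 / fs))
}

#' Estimate the open-pore baseline and noise scale
#'
#' The open-pore baseline is the steady current through the unobstructed
#' nanopore; blockades are measured relative to it. A centered moving
#' median tracks slow drift while ignoring the transient current drops,
#' and the noise scale is the robust sigma
#' `1.4826 * median(|sample - baseline|)`, insensitive to the events
#' themselves.
#'
#' @param trace A [pd_trace()].
#' @param window_s Moving-median window width in seconds; must cover at
#'   least 10 samples and no more than the trace length.
#' @return List with `baseline` (numeric, one value per sample) and
#'   `sigma` (scalar robust noise scale, nanoamperes).
#' @export
estimate_baseline <- function(trace, window_s = 0.05) {
  stopifnot(inherits(trace, "pd_trace"))
  stop_if_not_scalar_pos(window_s, "window_s")
  k <- round(window_s * trace$sampling_rate)
  if (k < 10) stop("baseline window must contain at least 10 samples",
                   call. = FALSE)
  if (k %% 2 == 0) k <- k + 1
  n <- length(trace$samples)
  if (n < k) stop("trace shorter than the baseline window", call. = FALSE)
  baseline <- as.numeric(stats::runmed(trace$samples, k, endrule = "median"))
  sigma <- 1.4826 * stats::median(abs(trace$samples - baseline))
  list(baseline = baseline, sigma = sigma)
}

#' Detect translocation events in a trace
#'
#' Events are downward current deviations: an event opens where
#' `baseline - current > threshold_sigmas * sigma`, is extended backward
#' and forward to the nearest crossings of `hysteresis_sigmas * sigma`,
#' and closes on re-crossing. Candidate events separated by less than
#' `merge_gap_s` are merged, then events shorter than `min_dwell_s` are
#' discarded. Per event the features are
#' * `peak_current_nA` = max of (baseline - current), a positive magnitude;
#' * `dwell_s` = width of the half-open sample interval between the
#'   hysteresis crossings;
#' * `ecd_pC` = rectangle-rule integral of the positive deviations,
#'   `sum(max(baseline - current, 0)) / rate * 1000` (1 nA*ms = 1 pC) —
#'   only positive deviations count, so noise excursions above baseline
#'   cannot cancel charge.
#'
#' Detection is deterministic: the same trace and settings always give the
#' same table, and raising `threshold_sigmas` can only remove events.
#'
#' @param trace A [pd_trace()].
#' @param settings A [detection_settings()].
#' @return A [pd_events()] table, sorted and non-overlapping, with the
#'   trace metadata and a digest of the settings in its provenance.
#' @export
detect_events <- function(trace, settings = detection_settings()) {
  stopifnot(inherits(trace, "pd_trace"),
            inherits(settings, "pd_detection_settings"))
  fs <- trace$sampling_rate
  bl <- estimate_baseline(trace, settings$baseline_window_s)
  dev <- bl$baseline - trace$samples
  thr_open <- settings$threshold_sigmas * bl$sigma
  thr_edge <- settings$hysteresis_sigmas * bl$sigma
  min_dwell_s <- settings$min_dwell_s %||% (3 / fs)
  merge_gap <- max(1L, round((settings$merge_gap_s %||% (1 / fs)) * fs))

  prov <- list(source = "in-memory trace",
               detection_settings = settings_digest(settings, trace))
  empty <- pd_events(meta = trace$meta, provenance = prov)

  above_edge <- dev > thr_edge
  if (!any(above_edge)) return(empty)

  r <- rle(above_edge)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  # keep only runs containing at least one opening-threshold crossing
  has_open <- vapply(seq_along(starts), function(i) {
    any(dev[starts[i]:ends[i]] > thr_open)
  }, logical(1))
  starts <- starts[has_open]; ends <- ends[has_open]
  if (!length(starts)) return(empty)

  # merge events separated by < merge_gap samples
  if (length(starts) > 1L) {
    gap <- starts[-1] - ends[-length(ends)] - 1L
    new_group <- c(TRUE, gap >= merge_gap)
    grp <- cumsum(new_group)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }

  dwell <- (ends - starts + 1L) / fs
  keep <- dwell >= min_dwell_s - 1e-12
  starts <- starts[keep]; ends <- ends[keep]; dwell <- dwell[keep]
  if (!length(starts)) return(empty)

  feat <- vapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    d <- dev[idx]
    c(peak = max(d),
      ecd = sum(pmax(d, 0)) / fs * 1000,
      base = stats::median(bl$baseline[idx]))
  }, numeric(3))

  df <- data.frame(
    start_s = trace$start_time + (starts - 1L) / fs,
    dwell_s = dwell,
    peak_current_nA = feat["peak", ],
    ecd_pC = feat["ecd", ],
    baseline_nA = feat["base", ]
  )
  pd_events(df, meta = trace$meta, provenance = prov)
}
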