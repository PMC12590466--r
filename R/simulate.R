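#' Configuration for stochastic self-cleavage fragmentation
#'
#' Heat- and cation-catalyzed RNA self-cleavage (2'-OH transesterification
#' of the phosphodiester backbone) is modelled as memoryless, stochastic
#' scission: every one of the `full_length_nt - 1` internal bonds of a
#' strand is cut independently at `per_bond_rate` cuts per minute, so the
#' number of cuts per molecule after `time_min` minutes is Poisson with
#' mean `per_bond_rate * (full_length_nt - 1) * time_min`, cut positions
#' uniform among bonds, and fragment lengths approximately exponential
#' once cutting is appreciable. The intact (zero-cut) fraction decays as
#' `exp(-per_bond_rate * (L - 1) * t)` — first-order kinetics with
#' molecular rate constant `k = per_bond_rate * (L - 1)` per minute.
#'
#' @param full_length_nt Strand length in nucleotides (default 3600, an
#'   MS2-genome-like archetype).
#' @param per_bond_rate Cuts per phosphodiester bond per minute, > 0
#'   (0 allowed: no cleavage).
#' @param time_min Incubation time, minutes, >= 0.
#' @param n_molecules Number of molecules, >= 1.
#' @param seed RNG seed (mandatory; all simulator output is reproducible
#'   bit-for-bit from config + seed).
#' @return An object of class `fragmentation_config`.
#' @export
fragmentation_config <- function(full_length_nt = 3600, per_bond_rate,
                                 time_min, n_molecules, seed) {
  stop_if_not_scalar_pos(full_length_nt, "full_length_nt")
  stopifnot(full_length_nt >= 2, full_length_nt == round(full_length_nt))
  stop_if_not_scalar_pos(per_bond_rate, "per_bond_rate", strict = FALSE)
  stop_if_not_scalar_pos(time_min, "time_min", strict = FALSE)
  stop_if_not_scalar_pos(n_molecules, "n_molecules")
  stopifnot(n_molecules == round(n_molecules))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(full_length_nt = as.integer(full_length_nt),
                 per_bond_rate = per_bond_rate, time_min = time_min,
                 n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed)),
            class = "fragmentation_config")
}

#' Simulate stochastic self-cleavage of RNA strands
#'
#' @param cfg A [fragmentation_config()].
#' @return List of class `fragment_sim` with
#' * `lengths`: integer vector of all fragment lengths (nt), concatenated
#'   over molecules; total nucleotides are conserved exactly
#'   (`sum(lengths) == n_molecules * full_length_nt`);
#' * `molecule`: parallel index of the parent molecule;
#' * `intact`: logical, one per molecule, `TRUE` when the molecule took
#'   zero cuts (the mean is an unbiased estimate of
#'   `exp(-per_bond_rate * (L - 1) * time_min)`);
#' * `n_cuts`: integer cuts per molecule;
#' * `config`: the input configuration.
#' @examples
#' cfg <- fragmentation_config(per_bond_rate = 1e-5, time_min = 30,
#'                             n_molecules = 1000, seed = 7)
#' sim <- simulate_fragments(cfg)
#' mean(sim$intact)
#' @export
simulate_fragments <- function(cfg) {
  stopifnot(inherits(cfg, "fragmentation_config"))
  L <- cfg$full_length_nt
  lambda <- cfg$per_bond_rate * (L - 1) * cfg$time_min
  with_seed(cfg$seed, {
    cuts <- stats::rpois(cfg$n_molecules, lambda)
    pieces <- lapply(seq_len(cfg$n_molecules), function(i) {
      if (cuts[i] == 0L) return(L)
      pos <- sort.int(sample.int(L - 1L, min(cuts[i], L - 1L)))
      diff(c(0L, pos, L))
    })
    lengths <- unlist(pieces, use.names = FALSE)
    molecule <- rep.int(seq_len(cfg$n_molecules),
                        vapply(pieces, length, integer(1)))
    structure(list(lengths = as.integer(lengths), molecule = molecule,
                   intact = cuts == 0L, n_cuts = cuts, config = cfg),
              class = "fragment_sim")
  })
}

#' Map fragment lengths to mean peak blockade currents
#'
#' Peak blockade current grows with strand length; the mapping used here
#' is a configurable power law `i(L) = i_full * (L / full_length)^alpha`
#' (default `alpha = 1`, linear) plus optional Gaussian scatter, clipped
#' at zero. The functional form is a simulator convention — real data
#' only establish that the mapping is monotone — but it has the property
#' the mixture model assumes: equal-length full-length molecules give a
#' Gaussian peak-current population and exponentially distributed
#' fragment lengths give an approximately exponential one.
#'
#' @param lengths Fragment lengths in nucleotides, all >= 1.
#' @param i_full_nA Mean peak current of a full-length strand, nA.
#' @param alpha Power-law exponent (> 0; 1 = linear).
#' @param scatter_sigma_nA Gaussian scatter around the mean, nA, >= 0.
#' @param full_length_nt Reference full length, nucleotides.
#' @param seed RNG seed for the scatter.
#' @return Numeric vector of peak currents, nA, same length as `lengths`.
#' @export
length_to_peak_current <- function(lengths, i_full_nA = 1, alpha = 1,
                                   scatter_sigma_nA = 0,
                                   full_length_nt = 3600, seed = 1) {
  stopifnot(is.numeric(lengths))
  if (any(lengths < 1)) stop("'lengths' must be >= 1 nt", call. = FALSE)
  stop_if_not_scalar_pos(i_full_nA, "i_full_nA")
  stop_if_not_scalar_pos(alpha, "alpha")
  stop_if_not_scalar_pos(scatter_sigma_nA, "scatter_sigma_nA", strict = FALSE)
  mean_i <- i_full_nA * (lengths / full_length_nt)^alpha
  if (scatter_sigma_nA > 0) {
    mean_i <- with_seed(seed,
      mean_i + stats::rnorm(length(lengths), 0, scatter_sigma_nA))
  }
  pmax(mean_i, 0)
}

#' Draw peak currents directly from the mixture model
#'
#' Ground-truth sampler for the Gaussian + exponential mixture: each draw
#' picks the Gaussian component with probability `w` (sampled from the
#' normal distribution truncated to non-negative support) or the
#' exponential component otherwise, then values below the detection
#' threshold are rejected and counted — the rejected count is the exact
#' ground truth for sub-threshold-mass accounting.
#'
#' @param params A [mixture_params()].
#' @param n Number of accepted draws to return, >= 1.
#' @param threshold Detection threshold, nA, >= 0; an error is raised if
#'   the acceptance probability `1 - F(threshold)` is below 1%.
#' @param seed RNG seed.
#' @return Numeric vector of `n` peak currents (all `>= threshold`) with
#'   attribute `n_rejected`, the number of sub-threshold draws discarded.
#' @export
simulate_peak_currents <- function(params, n, threshold = 0, seed = 1) {
  stopifnot(inherits(params, "mixture_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  stop_if_not_scalar_pos(threshold, "threshold", strict = FALSE)
  accept_p <- 1 - mixture_cdf(threshold, params)
  if (accept_p < 0.01) {
    stop(sprintf(
      "threshold %.4g nA leaves acceptance probability %.4g < 1%%",
      threshold, accept_p), call. = FALSE)
  }
  with_seed(seed, {
    out <- numeric(0)
    n_rejected <- 0L
    while (length(out) < n) {
      m <- max(ceiling((n - length(out)) / accept_p * 1.2), 100L)
      comp <- stats::runif(m) < params$w
      draw <- numeric(m)
      ng <- sum(comp)
      if (ng) {
        # truncated-to-[0, Inf) normal by inverse CDF
        u <- stats::runif(ng)
        p0 <- stats::pnorm(0, params$mu, params$sigma)
        draw[comp] <- stats::qnorm(p0 + u * (1 - p0), params$mu, params$sigma)
      }
      if (m - ng) draw[!comp] <- stats::rexp(m - ng, rate = 1 / params$beta)
      keep <- draw >= threshold
      acc <- which(keep)
      need <- n - length(out)
      if (length(acc) >= need) {
        # count rejections only up to the draw that completes the sample,
        # so n_rejected is the exact ground truth for censored-mass tests
        cutoff <- acc[need]
        n_rejected <- n_rejected + sum(!keep[seq_len(cutoff)])
        out <- c(out, draw[acc[seq_len(need)]])
      } else {
        n_rejected <- n_rejected + sum(!keep)
        out <- c(out, draw[acc])
      }
    }
    structure(out, n_rejected = n_rejected)
  })
}

#' Configuration for current-trace synthesis
#'
#' Describes a synthetic nanopore recording: a Gaussian-noise baseline on
#' which rectangular blockade events (spike-like at short dwells, as for
#' structured ssRNA translocations) are superimposed at Poisson-process
#' start times, thinned to enforce non-overlap, with log-normal dwell
#' times.
#'
#' @param baseline_nA Open-pore baseline current, nA.
#' @param noise_sigma_nA Gaussian noise standard deviation, nA.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param duration_s Recording length, seconds.
#' @param event_rate_hz Mean event arrival rate, Hz. The non-overlap
#'   regime requires `event_rate_hz * dwell_median_s` well below 1; a
#'   warning is raised above 0.2.
#' @param dwell_median_s Median dwell time, seconds (log-normal).
#' @param dwell_sigma_log Log-scale standard deviation of dwell times.
#' @param seed RNG seed.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(baseline_nA = 10, noise_sigma_nA = 0.015,
                             sampling_rate_hz = 5000, duration_s = 10,
                             event_rate_hz = 10, dwell_median_s = 0.002,
                             dwell_sigma_log = 0.3, seed = 1) {
  for (nm in c("baseline_nA", "noise_sigma_nA", "sampling_rate_hz",
               "duration_s", "event_rate_hz", "dwell_median_s",
               "dwell_sigma_log")) {
    stop_if_not_scalar_pos(get(nm), nm, strict = nm != "noise_sigma_nA")
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (event_rate_hz * dwell_median_s > 0.2) {
    warning("event_rate_hz * dwell_median_s > 0.2: event overlap likely; ",
            "thinning will distort the effective rate", call. = FALSE)
  }
  structure(list(baseline_nA = baseline_nA, noise_sigma_nA = noise_sigma_nA,
                 sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 event_rate_hz = event_rate_hz,
                 dwell_median_s = dwell_median_s,
                 dwell_sigma_log = dwell_sigma_log,
                 seed = as.integer(seed)),
            class = "trace_sim_config")
}

#' Synthesize a current trace with injected blockade events
#'
#' Builds a Gaussian-white-noise trace around the open-pore baseline and
#' injects one rectangular current dip per supplied peak current, at
#' Poisson-process start times thinned to keep events non-overlapping
#' (separated by at least one sample), with log-normal dwell times. Event
#' boundaries are quantized to whole samples; the returned ledger records
#' the exact injected (post-quantization) start, dwell and depth of every
#' event, so detection recall, precision and feature errors can be scored
#' against ground truth.
#'
#' @param peaks Numeric vector of event depths (peak blockade currents),
#'   nA, >= 0; one event is injected per element, in order.
#' @param cfg A [trace_sim_config()].
#' @return List of class `trace_sim` with `trace` (a [pd_trace()]) and
#'   `events` (data frame `start_s`, `dwell_s`, `depth_nA` — the
#'   ground-truth ledger).
#' @export
simulate_trace <- function(peaks, cfg) {
  stopifnot(inherits(cfg, "trace_sim_config"), is.numeric(peaks))
  if (any(peaks < 0)) stop("'peaks' must be >= 0", call. = FALSE)
  fs <- cfg$sampling_rate_hz
  n_samp <- round(cfg$duration_s * fs)
  if (n_samp < 2) stop("duration too short", call. = FALSE)

  with_seed(cfg$seed, {
    x <- cfg$baseline_nA +
      if (cfg$noise_sigma_nA > 0) stats::rnorm(n_samp, 0, cfg$noise_sigma_nA)
      else numeric(n_samp)

    n_ev <- length(peaks)
    start_idx <- integer(n_ev)
    len_smp <- integer(n_ev)
    t_free <- 1L  # first sample index available for the next event
    t_arr <- 0    # Poisson-process arrival clock, seconds
    for (i in seq_len(n_ev)) {
      dwell <- stats::rlnorm(1, log(cfg$dwell_median_s), cfg$dwell_sigma_log)
      k <- max(1L, round(dwell * fs))
      repeat {
        t_arr <- t_arr + stats::rexp(1, cfg$event_rate_hz)
        cand <- round(t_arr * fs) + 1L
        if (cand < t_free) next     # thinned: would overlap the previous event
        if (cand + k - 1L > n_samp) {
          stop(sprintf(
            "duration %.3g s too short to place %d events (placed %d)",
            cfg$duration_s, n_ev, i - 1L), call. = FALSE)
        }
        break
      }
      start_idx[i] <- cand
      len_smp[i] <- k
      t_free <- cand + k + 5L       # >= 5 clean samples between events, so
    }                               # hysteresis runs of neighbours never fuse
    for (i in seq_len(n_ev)) {
      idx <- start_idx[i]:(start_idx[i] + len_smp[i] - 1L)
      x[idx] <- x[idx] - peaks[i]
    }
    ledger <- data.frame(start_s = (start_idx - 1L) / fs,
                         dwell_s = len_smp / fs,
                         depth_nA = as.numeric(peaks))
    structure(list(
      trace = pd_trace(x, sampling_rate = fs, meta = list(
        simulated = "true",
        noise_sigma_nA = format_full(cfg$noise_sigma_nA))),
      events = ledger
    ), class = "trace_sim")
  })
}
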