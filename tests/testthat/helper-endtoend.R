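# Build a 3-condition x 4-timepoint synthetic degradation experiment as raw
# trace files plus a manifest. The full-length fraction decays as
# w(t) = 0.85 * exp(-k t) with programmed rate constants in ratio 3:1:0.5;
# peak currents are drawn from the mixture at w(t) (full population,
# threshold 0) and small fragments are lost to the detection floor of the
# synthesized traces, exercising the sub-threshold accounting end to end.
build_endtoend_experiment <- function(seed,
                                      dir = file.path(tempdir(),
                                                      paste0("e2e", seed))) {
  sub_seed <- function(i) (seed %% 100000L) * 10000L + i
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k_true <- c(fast = 0.03, mid = 0.01, slow = 0.005)
  times <- c(0, 20, 60, 120)
  w0 <- 0.85
  thr <- 0.09
  rows <- list()
  i <- 0L
  for (cond in names(k_true)) {
    for (t in times) {
      i <- i + 1L
      w_t <- w0 * exp(-k_true[[cond]] * t)
      peaks <- simulate_peak_currents(
        mixture_params(w_t, 0.9, 0.12, 0.25), 1800, threshold = 0,
        seed = sub_seed(i))
      sim <- simulate_trace(peaks, trace_sim_config(
        baseline_nA = 10, noise_sigma_nA = 0.012, sampling_rate_hz = 2500,
        duration_s = 280, event_rate_hz = 10, dwell_median_s = 0.004,
        dwell_sigma_log = 0.25, seed = sub_seed(500L + i)))
      path <- file.path(dir, sprintf("%s_t%03d.trace.csv", cond, t))
      write_trace(sim$trace, path)
      rows[[i]] <- data.frame(condition = cond, time_min = t, path = path,
                              threshold_nA = thr)
    }
  }
  list(manifest = do.call(rbind, rows), k_true = k_true,
       w0 = w0, times = times, threshold_nA = thr)
}
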