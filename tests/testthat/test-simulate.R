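test_that("zero cleavage rate leaves every molecule intact", {
  cfg <- fragmentation_config(per_bond_rate = 0, time_min = 60,
                              n_molecules = 200, seed = 1)
  sim <- simulate_fragments(cfg)
  expect_true(all(sim$intact))
  expect_true(all(sim$lengths == 3600))
  expect_equal(length(sim$lengths), 200)
})

test_that("intact fraction matches the Poisson zero class and nucleotides are conserved", {
  # expected cuts per molecule = 0.6 -> intact fraction exp(-0.6) = 0.5488
  L <- 3600
  n <- 10000
  cfg <- fragmentation_config(full_length_nt = L,
                              per_bond_rate = 0.6 / (L - 1), time_min = 1,
                              n_molecules = n, seed = 42)
  sim <- simulate_fragments(cfg)
  p <- exp(-0.6)
  expect_lt(abs(mean(sim$intact) - p), 3 * sqrt(p * (1 - p) / n))
  expect_identical(sum(as.numeric(sim$lengths)), n * L)

  # mean cuts per molecule within 3 SE of the Poisson mean
  expect_lt(abs(mean(sim$n_cuts) - 0.6), 3 * sqrt(0.6 / n))
  # intact flag is exactly the zero-cut class
  expect_identical(sim$intact, sim$n_cuts == 0L)
})

test_that("fragmentation is reproducible bit-for-bit from config + seed", {
  cfg <- fragmentation_config(per_bond_rate = 1e-4, time_min = 10,
                              n_molecules = 500, seed = 9)
  s1 <- simulate_fragments(cfg)
  s2 <- simulate_fragments(cfg)
  expect_identical(s1$lengths, s2$lengths)
  expect_identical(s1$intact, s2$intact)
})

test_that("length-to-current mapping obeys its closed forms", {
  expect_equal(length_to_peak_current(3600, i_full_nA = 0.9), 0.9)
  expect_equal(length_to_peak_current(1800, i_full_nA = 0.9, alpha = 1), 0.45)
  expect_equal(length_to_peak_current(900, i_full_nA = 1, alpha = 2,
                                      full_length_nt = 3600), 1 / 16)
  expect_error(length_to_peak_current(c(100, 0)), ">= 1")
})

test_that("exponential fragment lengths map to exponential peak currents", {
  set.seed(13)
  lengths <- rexp(1500, 1 / 400) + 1
  peaks <- length_to_peak_current(lengths, i_full_nA = 1, alpha = 1,
                                  scatter_sigma_nA = 0.003,
                                  full_length_nt = 3600, seed = 14)
  ks <- suppressWarnings(
    ks.test(peaks - 1 / 3600, "pexp", rate = 3600 / 400))
  expect_gt(ks$p.value, 0.01)
})

test_that("mixture sampler honours the component structure and rejection accounting", {
  # pure Gaussian: sample mean within 3 sigma/sqrt(n) of mu
  g <- mixture_params(1, 0.9, 0.1, 0.25)
  x <- simulate_peak_currents(g, 4000, threshold = 0, seed = 3)
  expect_lt(abs(mean(x) - 0.9), 3 * 0.1 / sqrt(4000))
  expect_identical(attr(x, "n_rejected"), 0L)

  # pure exponential with threshold = beta: rejected fraction ~ 1 - 1/e
  e <- mixture_params(0, 0.9, 0.1, 0.2)
  x <- simulate_peak_currents(e, 4000, threshold = 0.2, seed = 4)
  expect_true(all(x >= 0.2))
  nrej <- attr(x, "n_rejected")
  total <- 4000 + nrej
  p <- 1 - exp(-1)
  expect_lt(abs(nrej / total - p), 3 * sqrt(p * (1 - p) / total))

  expect_error(simulate_peak_currents(g, 0, seed = 1), "positive integer")
  expect_error(simulate_peak_currents(e, 10, threshold = 1.2, seed = 1),
               "acceptance")
})

test_that("trace synthesis is reproducible and its ledger matches detection exactly", {
  cfg <- trace_sim_config(duration_s = 6, event_rate_hz = 10, seed = 5)
  peaks <- simulate_peak_currents(mixture_params(0.7, 0.9, 0.12, 0.25),
                                  40, threshold = 0.08, seed = 6)
  s1 <- simulate_trace(peaks, cfg)
  s2 <- simulate_trace(peaks, cfg)
  expect_identical(s1$trace$samples, s2$trace$samples)
  expect_identical(s1$events, s2$events)
  expect_equal(nrow(s1$events), 40)

  # single injected event, zero noise: depth/dwell/ECD recovered exactly
  cfg0 <- trace_sim_config(noise_sigma_nA = 0, duration_s = 2,
                           event_rate_hz = 2, seed = 8)
  s0 <- simulate_trace(0.8, cfg0)
  ev <- detect_events(s0$trace)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_current_nA, 0.8)
  expect_equal(ev$dwell_s, s0$events$dwell_s)
  expect_equal(ev$start_s, s0$events$start_s)
  expect_equal(ev$ecd_pC, 0.8 * s0$events$dwell_s * 1000)
})

test_that("a pure-noise trace yields (almost) no detections at 5 sigma", {
  cfg <- trace_sim_config(noise_sigma_nA = 0.02, sampling_rate_hz = 25000,
                          duration_s = 8, seed = 15)
  sim <- simulate_trace(numeric(0), cfg)
  ev <- detect_events(sim$trace)
  expect_lte(nrow(ev), 1)  # expected false positives < 1 per 1e6 samples
})

test_that("too short a duration to place the requested events is an error", {
  cfg <- trace_sim_config(duration_s = 0.05, event_rate_hz = 5, seed = 2)
  expect_error(simulate_trace(rep(0.5, 50), cfg), "too short")
})

test_that("simulated intact-fraction decay closes the loop with the kinetics fit", {
  L <- 3600
  rate <- 0.02 / (L - 1)  # molecular rate constant k = 0.02 per minute
  times <- c(0, 15, 30, 60)
  hl_truth <- log(2) / 0.02
  hl_err <- vapply(1:10, function(s) {
    fr <- vapply(times, function(t) {
      cfg <- fragmentation_config(full_length_nt = L, per_bond_rate = rate,
                                  time_min = t, n_molecules = 2000,
                                  seed = 1000 * s + t)
      mean(simulate_fragments(cfg)$intact)
    }, numeric(1))
    fit <- fit_decay(times, fr)
    abs(fit$half_life_min - hl_truth) / hl_truth
  }, numeric(1))
  expect_lte(median(hl_err), 0.10)
})
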