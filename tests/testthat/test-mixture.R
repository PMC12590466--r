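test_that("mixture density matches closed forms at the component extremes", {
  # pure Gaussian at its mode: 1 / (sigma * sqrt(2*pi)); truncation
  # correction < 1e-10 when mu/sigma > 6
  p <- mixture_params(1, 0.9, 0.1, 0.25)
  expect_equal(mixture_pdf(0.9, p), 1 / (0.1 * sqrt(2 * pi)),
               tolerance = 1e-9)
  # pure exponential at the origin: 1/beta
  p <- mixture_params(0, 0.9, 0.1, 0.5)
  expect_equal(mixture_pdf(0, p), 2.0)
})

test_that("mixture density equals the hand-evaluated two-term closed form", {
  p <- mixture_params(0.5, 1.0, 0.2, 1/3)
  xs <- c(0, 0.1, 0.5, 1.0, 2.5)
  expect_equal(mixture_pdf(xs, p),
               mixture_pdf_oracle(xs, 0.5, 1.0, 0.2, 1/3),
               tolerance = 1e-12)
})

test_that("mixture parameter validation rejects out-of-bounds values", {
  expect_error(mixture_params(1.2, 1, 0.1, 0.2), "'w'")
  expect_error(mixture_params(0.5, -1, 0.1, 0.2), "mu")
  expect_error(mixture_params(0.5, 1, 0, 0.2), "sigma")
  expect_error(mixture_pdf(-0.1, mixture_params(0.5, 1, 0.1, 0.2)), ">= 0")
})

test_that("density integrates to 1 over [0, Inf) for random valid parameters", {
  set.seed(101)
  for (rep in 1:50) {
    p <- mixture_params(runif(1), runif(1, 0.05, 2), runif(1, 0.01, 0.5),
                        runif(1, 0.01, 1))
    expect_lt(abs(mixture_quadrature(p) - 1), 1e-6)
  }
})

test_that("log-likelihood equals the brute-force per-point sum", {
  p <- mixture_params(0.6, 0.9, 0.12, 0.25)
  x <- simulate_peak_currents(p, 50, threshold = 0, seed = 5)
  brute <- 0
  for (xi in x) brute <- brute + log(mixture_pdf_oracle(xi, 0.6, 0.9, 0.12, 0.25))
  expect_equal(mixture_loglik(x, p), brute, tolerance = 1e-10)

  # paper and truncated conventions agree exactly at threshold 0
  expect_identical(mixture_loglik(x, p, threshold = 0, mode = "paper"),
                   mixture_loglik(x, p, threshold = 0, mode = "truncated"))

  # truncated subtracts the log survival mass per observation
  thr <- 0.05
  xt <- x[x >= thr]
  expect_equal(
    mixture_loglik(xt, p, threshold = thr, mode = "truncated"),
    mixture_loglik(xt, p, threshold = thr, mode = "paper") -
      length(xt) * log(1 - mixture_cdf(thr, p)),
    tolerance = 1e-12)

  expect_error(mixture_loglik(c(0.01, 0.5), p, threshold = 0.05),
               "inconsistent")
})

test_that("single point at the Gaussian mode gives the mode log-density", {
  p <- mixture_params(1, 0.9, 0.1, 0.25)
  expect_equal(mixture_loglik(0.9, p), log(mixture_pdf(0.9, p)))
})

test_that("pure-component samples are recognised by the fit", {
  g <- mixture_params(1, 0.9, 0.1, 0.25)
  x <- simulate_peak_currents(g, 5000, threshold = 0, seed = 31)
  fit <- fit_mixture(x, threshold = 0, seed = 31)
  expect_gte(fit$full_length_fraction, 0.97)

  e <- mixture_params(0, 0.9, 0.1, 0.2)
  x <- simulate_peak_currents(e, 5000, threshold = 0, seed = 32)
  fit <- fit_mixture(x, threshold = 0, seed = 32)
  expect_lte(fit$full_length_fraction, 0.03)
  expect_true(fit$boundary || fit$full_length_fraction > 0)
})

test_that("fit refuses fewer than 20 events and inconsistent thresholds", {
  x <- rexp(10, 5)
  expect_error(fit_mixture(x, threshold = 0), "at least 20")
  p <- mixture_params(0.6, 0.9, 0.12, 0.25)
  x <- simulate_peak_currents(p, 30, threshold = 0, seed = 1)
  expect_error(fit_mixture(x, threshold = max(x) / 2), ">= threshold")
})

test_that("defaulted detection threshold is announced, never silent", {
  p <- mixture_params(0.6, 0.9, 0.12, 0.25)
  x <- simulate_peak_currents(p, 100, threshold = 0.05, seed = 2)
  expect_message(fit <- fit_mixture(x, seed = 2), "0.99")
  expect_equal(fit$detection_threshold_nA, 0.99 * min(x))
})

test_that("fitted log-likelihood dominates the data-driven start and a parameter grid", {
  p <- mixture_params(0.6, 0.9, 0.12, 0.25)
  for (s in 1:3) {
    x <- simulate_peak_currents(p, 200, threshold = 0, seed = 40 + s)
    fit <- fit_mixture(x, threshold = 0, seed = s)
    init <- poredeg:::mixture_init(x)
    ll_init <- mixture_loglik(
      x, mixture_params(init[["w"]], init[["mu"]], init[["sigma"]],
                        init[["beta"]]))
    expect_gte(fit$loglik, ll_init)
    g <- default_grid()
    best <- grid_best_loglik(x, g$w, g$mu, g$sigma, g$beta)
    expect_gte(fit$loglik, best)
  }
})

test_that("truncated mode recovers the true weight under 30% fragment censoring", {
  # threshold chosen so 30% of the exponential component lies below it
  truth <- mixture_params(0.65, 0.9, 0.12, 0.25)
  thr <- -0.25 * log(0.7)
  w_hat <- vapply(1:8, function(s) {
    x <- simulate_peak_currents(truth, 2000, threshold = thr, seed = 500 + s)
    fit_mixture(x, threshold = thr, mode = "truncated",
                seed = s)$full_length_fraction
  }, numeric(1))
  se <- sd(w_hat) / sqrt(length(w_hat))
  expect_lte(abs(mean(w_hat) - 0.65), 3 * se)
})

test_that("paper and truncated fits coincide at threshold zero", {
  truth <- mixture_params(0.65, 0.9, 0.12, 0.25)
  x <- simulate_peak_currents(truth, 2000, threshold = 0, seed = 77)
  f1 <- fit_mixture(x, threshold = 0, mode = "paper", seed = 7)
  f2 <- fit_mixture(x, threshold = 0, mode = "truncated", seed = 7)
  expect_lte(abs(f1$full_length_fraction - f2$full_length_fraction), 0.01)
})

test_that("sub-threshold mass is the model CDF at the threshold, zero at zero", {
  truth <- mixture_params(0.65, 0.9, 0.12, 0.25)
  thr <- 0.05
  x <- simulate_peak_currents(truth, 1000, threshold = thr, seed = 9)
  fit <- fit_mixture(x, threshold = thr, mode = "truncated", seed = 9)
  expect_equal(fit$subthreshold_mass, mixture_cdf(thr, fit$params))
  x0 <- simulate_peak_currents(truth, 1000, threshold = 0, seed = 10)
  fit0 <- fit_mixture(x0, threshold = 0, seed = 10)
  expect_identical(fit0$subthreshold_mass, 0)
})

test_that("increasing fragment proportion decreases the fitted full-length fraction", {
  ws <- c(0.8, 0.5, 0.2)
  med_w <- vapply(ws, function(w) {
    truth <- mixture_params(w, 0.9, 0.12, 0.25)
    fits <- vapply(1:5, function(s) {
      x <- simulate_peak_currents(truth, 1200, threshold = 0.05,
                                  seed = 1000 * s + round(100 * w))
      fit_mixture(x, threshold = 0.05, seed = s)$full_length_fraction
    }, numeric(1))
    median(fits)
  }, numeric(1))
  expect_true(all(diff(med_w) < 0))
})

test_that("density curves sum to the mixture and shrink at mu as w falls", {
  grid <- seq(0, 2, length.out = 400)
  p <- mixture_params(0.6, 0.9, 0.12, 0.25)
  cur <- mixture_density_curves(p, grid)
  expect_equal(cur$total, mixture_pdf(grid, p), tolerance = 1e-12)
  expect_equal(cur$gaussian + cur$exponential, cur$total, tolerance = 1e-15)

  # area under the total curve is 1 (trapezoid, grid covering the support)
  wide <- seq(0, 6, length.out = 4000)
  tot <- mixture_density_curves(p, wide)$total
  area <- sum(diff(wide) * (tot[-1] + tot[-length(tot)]) / 2)
  expect_lt(abs(area - 1), 1e-3)

  # w = 1: no exponential contribution anywhere
  cur1 <- mixture_density_curves(mixture_params(1, 0.9, 0.12, 0.25), grid)
  expect_true(all(cur1$exponential == 0))

  # total density at mu strictly decreasing along the degradation sequence
  at_mu <- vapply(c(0.9, 0.5, 0.1), function(w) {
    mixture_density_curves(mixture_params(w, 0.9, 0.12, 0.25),
                           c(0.89, 0.9, 0.91))$total[2]
  }, numeric(1))
  expect_true(all(diff(at_mu) < 0))

  expect_error(mixture_density_curves(p, c(1, 0.5)), "sorted")
})
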