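# Shared fixture builders. Everything is generated in code, seeded.

# write a two-column trace file and return its path
write_trace_file <- function(time, current, header = character(),
                             delim = ",", eol = "\n") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  rows <- paste(format(time, digits = 17), format(current, digits = 17),
                sep = delim)
  con <- file(path, "wb")
  writeLines(c(header, rows), con, sep = eol)
  close(con)
  path
}

# constant-baseline trace with one rectangular dip, no noise
rect_pulse_trace <- function(baseline = 5, depth = 1.2, fs = 10000,
                             n = 2000, dip_start = 1000, dip_len = 20) {
  x <- rep(baseline, n)
  x[dip_start:(dip_start + dip_len - 1)] <- baseline - depth
  pd_trace(x, sampling_rate = fs)
}

# closed-form mixture density, written independently of mixture_pdf():
# direct two-term evaluation used as the hand oracle
mixture_pdf_oracle <- function(x, w, mu, sigma, beta) {
  gauss <- exp(-(x - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  gauss <- gauss / (1 - pnorm(-mu / sigma))
  w * gauss + (1 - w) * (1 / beta) * exp(-x / beta)
}

# piecewise quadrature of the mixture density over [0, Inf): splits at the
# Gaussian bump so narrow spikes are never missed
mixture_quadrature <- function(params) {
  f <- function(x) mixture_pdf(x, params)
  a <- max(0, params$mu - 8 * params$sigma)
  b <- params$mu + 8 * params$sigma
  stats::integrate(f, 0, a, rel.tol = 1e-10, abs.tol = 1e-12)$value +
    stats::integrate(f, a, b, rel.tol = 1e-10, abs.tol = 1e-12)$value +
    stats::integrate(f, b, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# exhaustive log-likelihood maximization over a bounded parameter grid
# covering the fit's admissible region (resolved peak: mu >= 3*sigma);
# independent of the optimizer under test
grid_best_loglik <- function(x, w_grid, mu_grid, sigma_grid, beta_grid,
                             threshold = 0, mode = "paper") {
  n <- length(x)
  musig <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  musig <- musig[musig$mu >= 3 * musig$sigma, , drop = FALSE]
  rownames(musig) <- NULL
  G <- matrix(0, nrow(musig), n)
  for (i in seq_len(nrow(musig))) {
    G[i, ] <- dnorm(x, musig$mu[i], musig$sigma[i]) /
      pnorm(0, musig$mu[i], musig$sigma[i], lower.tail = FALSE)
  }
  best <- -Inf
  for (beta in beta_grid) {
    Eb <- matrix(dexp(x, rate = 1 / beta), nrow(musig), n, byrow = TRUE)
    for (w in w_grid) {
      ll <- rowSums(log(w * G + (1 - w) * Eb))
      if (mode == "truncated" && threshold > 0) {
        surv <- vapply(seq_len(nrow(musig)), function(i) {
          p <- mixture_params(w, musig$mu[i], musig$sigma[i], beta)
          1 - mixture_cdf(threshold, p)
        }, numeric(1))
        ll <- ll - n * log(surv)
      }
      m <- max(ll)
      if (m > best) best <- m
    }
  }
  best
}

default_grid <- function() {
  list(w = seq(0.025, 0.975, length.out = 20),
       mu = seq(0.3, 1.5, length.out = 20),
       sigma = seq(0.03, 0.5, length.out = 20),
       beta = seq(0.05, 1.0, length.out = 20))
}

# match detected events to an injected ground-truth ledger by time overlap
match_events <- function(detected, ledger) {
  d_start <- detected$start_s
  d_end <- detected$start_s + detected$dwell_s
  hit <- vapply(seq_len(nrow(ledger)), function(i) {
    s <- ledger$start_s[i]
    e <- s + ledger$dwell_s[i]
    j <- which(d_start < e & d_end > s)
    if (length(j)) j[[1]] else NA_integer_
  }, integer(1))
  list(recall = mean(!is.na(hit)),
       precision = length(unique(hit[!is.na(hit)])) / max(nrow(detected), 1L),
       matched = hit)
}
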