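#' Fit exponential decay of the full-length fraction over time
#'
#' Nonlinear least squares of `f(t) = A * exp(-k * t)` to full-length
#' fractions measured at a series of incubation times, giving the
#' first-order degradation rate constant `k` (per minute) and the derived
#' half-life `ln(2) / k`. The amplitude `A` is free by default because
#' even untreated samples carry a subpopulation of short species, so the
#' fraction at `t = 0` is below 1; `model = "anchored"` instead fixes `A`
#' to the observed `t = 0` fraction for sensitivity analysis.
#'
#' Initialization comes from a log-linear regression on the points with
#' positive fraction; the optimizer (Levenberg-Marquardt via
#' \pkg{minpack.lm}) is bounded so that `k >= 0` and `0 < A <= 1`. When
#' per-point uncertainties are supplied the fit is inverse-variance
#' weighted; otherwise it is plain (unweighted) least squares.
#'
#' Degenerate inputs: if all fractions are equal and nonzero the fit is
#' the flat line `A = f`, `k = 0`, half-life infinite, flagged via
#' `k_zero = TRUE` (not an error).
#'
#' @param times Incubation times, minutes, non-negative, strictly
#'   increasing; at least 2 distinct timepoints (3+ recommended).
#' @param fractions Full-length fractions in `[0, 1]`, one per time
#'   (typically `full_length_fraction` from [fit_mixture()]); at least one
#'   must be positive.
#' @param se Optional per-point standard errors (> 0) for weighted least
#'   squares.
#' @param model `"free_amplitude"` (default) or `"anchored"` (requires an
#'   observation at `t = 0`).
#' @param condition Optional condition label carried into the result.
#' @return An object of class `decay_fit`: list with `A`, `k` (per
#'   minute), `half_life_min` (`= log(2)/k`, `Inf` when `k = 0`), `rss`,
#'   `cov` (covariance of the fitted parameters, `NA` if unavailable),
#'   `model`, `k_zero` flag, `condition`, `n`.
#' @examples
#' fit <- fit_decay(c(0, 30), c(1, 0.5))
#' fit$half_life_min  # 30
#' @export
fit_decay <- function(times, fractions, se = NULL,
                      model = c("free_amplitude", "anchored"),
                      condition = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(times), is.numeric(fractions))
  if (length(times) != length(fractions)) {
    stop("'times' and 'fractions' must have equal length", call. = FALSE)
  }
  if (length(unique(times)) < 2) {
    stop("need at least 2 distinct timepoints", call. = FALSE)
  }
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(fractions < 0) || any(fractions > 1)) {
    stop("'fractions' must lie in [0, 1]", call. = FALSE)
  }
  if (all(fractions == 0)) {
    stop("at least one fraction must be positive", call. = FALSE)
  }
  w <- NULL
  if (!is.null(se)) {
    stopifnot(is.numeric(se), length(se) == length(times), all(se > 0))
    w <- 1 / se^2
  }

  mk_fit <- function(A, k, rss, cov, k_zero = FALSE) {
    structure(list(A = A, k = k,
                   half_life_min = if (k == 0) Inf else log(2) / k,
                   rss = rss, cov = cov, model = model,
                   k_zero = k_zero, condition = condition,
                   n = length(times)),
              class = "decay_fit")
  }

  # flat-line degenerate case: all fractions identical and nonzero
  if (length(unique(fractions)) == 1L) {
    return(mk_fit(A = fractions[[1]], k = 0, rss = 0,
                  cov = matrix(NA_real_, 2, 2,
                               dimnames = list(c("A", "k"), c("A", "k"))),
                  k_zero = TRUE))
  }

  pos <- fractions > 0
  ll <- stats::lm(log(fractions[pos]) ~ times[pos])
  k0 <- max(-unname(stats::coef(ll)[2]), 1e-8)
  A0 <- min(max(exp(unname(stats::coef(ll)[1])), 1e-6), 1)

  df <- data.frame(t = times, f = fractions)
  if (!is.null(w)) df$.w <- w
  nls_args <- function(...) {
    args <- list(..., data = df,
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(w)) args$weights <- quote(.w)
    do.call(minpack.lm::nlsLM, args)
  }
  fit <- if (model == "free_amplitude") {
    nls_args(f ~ A * exp(-k * t),
             start = list(A = A0, k = k0),
             lower = c(A = 1e-12, k = 0), upper = c(A = 1, k = Inf))
  } else {
    A_anchor <- fractions[times == 0]
    if (!length(A_anchor)) {
      stop("model = 'anchored' requires an observation at t = 0",
           call. = FALSE)
    }
    A_anchor <- A_anchor[[1]]
    if (A_anchor <= 0) {
      stop("anchored amplitude must be positive", call. = FALSE)
    }
    df$A_anchor <- A_anchor
    nls_args(f ~ A_anchor * exp(-k * t),
             start = list(k = k0),
             lower = c(k = 0), upper = c(k = Inf))
  }
  cf <- stats::coef(fit)
  A_hat <- if (model == "free_amplitude") unname(cf["A"]) else fractions[times == 0][[1]]
  k_hat <- unname(cf["k"])
  cov <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, length(cf), length(cf),
           dimnames = list(names(cf), names(cf)))
  })
  rss <- sum(stats::resid(fit)^2)
  mk_fit(A = A_hat, k = k_hat, rss = rss, cov = cov, k_zero = k_hat == 0)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit>%s model=%s  A=%.4f  k=%.6g /min  half-life=%s  rss=%.4g\n",
    if (!is.null(x$condition)) paste0(" [", x$condition, "]") else "",
    x$model, x$A, x$k,
    if (is.infinite(x$half_life_min)) "Inf (no decay)"
    else sprintf("%.4g min", x$half_life_min),
    x$rss))
  invisible(x)
}

#' Compare degradation kinetics across conditions
#'
#' Orders a set of per-condition decay fits by rate constant (fastest
#' degradation first) and reports each condition's half-life and its rate
#' fold-change relative to the slowest condition
#' (`fold_change = k / min(k)`).
#'
#' @param fits A named list of [fit_decay()] results (names are condition
#'   labels), or an unnamed list of fits that carry their own `condition`.
#' @return Data frame with columns `condition`, `k_per_min`,
#'   `half_life_min`, `fold_change`, sorted by `k_per_min` descending.
#' @export
compare_conditions <- function(fits) {
  stopifnot(is.list(fits))
  if (length(fits) < 2) {
    stop("need at least 2 conditions to compare", call. = FALSE)
  }
  labels <- names(fits)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(fits, function(f) f$condition %||% NA_character_,
                     character(1))
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop("every fit needs a condition label", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate condition labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  for (f in fits) stopifnot(inherits(f, "decay_fit"))
  k <- vapply(fits, `[[`, numeric(1), "k")
  hl <- vapply(fits, `[[`, numeric(1), "half_life_min")
  out <- data.frame(condition = labels, k_per_min = k, half_life_min = hl,
                    fold_change = k / min(k), row.names = NULL)
  out <- out[order(-out$k_per_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}
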