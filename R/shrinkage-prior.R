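#' Rough per-feature standard deviation from non-PMVs
#'
#' Maximises the truncated-normal likelihood of the log non-PMV observations,
#' `prod phi((log y - mu)/sigma)/sigma / [1 - Phi((lam - mu)/sigma)]`, over
#' `sigma` with `mu` fixed at the sample mean of the log non-PMVs. This rough
#' estimate feeds the hyperparameter fit only; model inference uses the
#' shrunken posterior-mode estimate instead.
#'
#' @param feature_values Non-negative abundances for one feature (>= 2
#'   non-PMVs required).
#' @param lam Log-scale detection limit (may be `-Inf`, in which case the
#'   estimate is the divide-by-n maximum-likelihood standard deviation).
#' @return A list with `sigma_hat`, `converged`, and `n_nonpmv_used`.
#' @export
rough_sigma <- function(feature_values, lam) {
  ly <- log(feature_values[feature_values > 0])
  n <- length(ly)
  if (n < 2L) stop("at least 2 non-PMV observations required")
  mu <- mean(ly)
  resid2 <- sum((ly - mu)^2)
  obj <- function(logsig) {
    sig <- exp(logsig)
    sum(stats::dnorm((ly - mu) / sig, log = TRUE)) - n * logsig -
      n * stats::pnorm((lam - mu) / sig, lower.tail = FALSE, log.p = TRUE)
  }
  opt <- try(stats::optimize(obj, c(log(1e-3), log(1e3)), maximum = TRUE,
    tol = 1e-8), silent = TRUE)
  mle_sd <- sqrt(resid2 / n)
  if (inherits(opt, "try-error") || !is.finite(opt$objective)) {
    return(list(sigma_hat = max(mle_sd, 1e-3), converged = FALSE,
      n_nonpmv_used = n))
  }
  list(sigma_hat = exp(opt$maximum), converged = TRUE, n_nonpmv_used = n)
}

#' Select features for hyperparameter estimation
#'
#' Uses features with at least 10 non-PMV observations; when fewer than 30
#' such features exist, falls back to the 30 features with the smallest PMV
#' proportions (ties broken by original feature order). With fewer than 30
#' features in total, all are returned with a warning.
#'
#' @param x An abundance matrix.
#' @return Character vector of feature ids.
#' @export
select_prior_features <- function(x) {
  if (nrow(x) == 0L) stop("empty abundance matrix")
  n_nonpmv <- rowSums(x > 0)
  rich <- rownames(x)[n_nonpmv >= 10]
  if (length(rich) >= 30L) return(rich)
  if (nrow(x) < 30L) {
    warning("fewer than 30 features available for hyperparameter estimation; using all ",
      nrow(x))
    return(rownames(x))
  }
  pmv_frac <- 1 - n_nonpmv / ncol(x)
  rownames(x)[order(pmv_frac)][seq_len(30L)]
}

#' Fit the inverse-gamma variance prior by the method of moments
#'
#' The shared prior is `sigma^2 ~ Inv-Gamma(d0/2, d0 s0^2 / 2)`. With `m` and
#' `v` the sample mean and variance of the squared rough estimates
#' `sigma_hat^2`, the moment solution is `d0 = 2 m^2 / v + 4` and
#' `s0 = sqrt(m (d0 - 2) / d0)`; the fitted prior then reproduces `m` and `v`
#' exactly as its implied mean and variance of `sigma^2`.
#'
#' @param sigma_hats Vector of rough standard-deviation estimates (>= 2, with
#'   positive spread).
#' @return An object of class `dasev_prior`: a list with `d0`, `s0`,
#'   `n_features_used`.
#' @export
estimate_hyperparameters <- function(sigma_hats) {
  if (length(sigma_hats) < 2L) stop("need at least 2 rough estimates")
  if (any(sigma_hats <= 0)) stop("rough estimates must be positive")
  s2 <- sigma_hats^2
  m <- mean(s2)
  v <- stats::var(s2)
  if (!is.finite(v) || v <= 0) stop("degenerate variance spread")
  d0 <- 2 * m^2 / v + 4
  s0 <- sqrt(m * (d0 - 2) / d0)
  structure(list(d0 = d0, s0 = s0, n_features_used = length(sigma_hats)),
    class = "dasev_prior")
}

#' @export
print.dasev_prior <- function(x, ...) {
  cat("Inverse-gamma variance prior: d0 =", format(x$d0, digits = 5),
    ", s0 =", format(x$s0, digits = 5),
    " (fitted on", x$n_features_used, "features)\n")
  invisible(x)
}

#' Log-density of the inverse-gamma variance prior
#'
#' `pi(sigma^2) = (d0 s0^2/2)^(d0/2) sigma^(-2(1 + d0/2))
#'  exp(-d0 s0^2 / (2 sigma^2)) / Gamma(d0/2)`.
#'
#' @param sigma_sq Variance value(s), > 0.
#' @param hp A `dasev_prior` object (or list with `d0`, `s0`).
#' @return Log prior density.
#' @export
log_prior <- function(sigma_sq, hp) {
  if (any(sigma_sq <= 0)) stop("sigma_sq must be positive")
  a <- hp$d0 / 2
  b <- hp$d0 * hp$s0^2 / 2
  a * log(b) - lgamma(a) - (a + 1) * log(sigma_sq) - b / sigma_sq
}

# Prior mode of sigma^2: argmax of log_prior.
prior_mode <- function(hp) hp$d0 * hp$s0^2 / (hp$d0 + 2)

#' Estimate the variance prior from an abundance matrix
#'
#' Convenience wrapper: selects the hyperparameter feature set, computes rough
#' per-feature standard deviations at the per-feature detection limits, and
#' fits the inverse-gamma prior.
#'
#' @param x An abundance matrix.
#' @param epsilon Detection-limit offset, see [compute_detection_limit()].
#' @return A `dasev_prior` object.
#' @export
estimate_prior <- function(x, epsilon = 0.1) {
  ids <- select_prior_features(x)
  ids <- ids[rowSums(x[ids, , drop = FALSE] > 0) >= 2]
  sh <- vapply(ids, function(k) {
    lam <- compute_detection_limit(x[k, ], epsilon)
    rough_sigma(x[k, ], lam)$sigma_hat
  }, numeric(1L))
  estimate_hyperparameters(sh)
}
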