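#' @keywords internal
"_PACKAGE"

# Linear predictors are clamped before exponentiation so the logistic link
# stays inside (0, 1) in double precision even near separation.
clamp_eta <- function(eta, clamp = 30) pmin(pmax(eta, -clamp), clamp)

#' Evaluate the link models for one feature
#'
#' The zero-inflation probability follows a logistic regression,
#' `p_i = logit^-1(X_i' gamma)`, and the log-abundance mean a linear
#' regression, `mu_i = X_i' beta`, on the same design.
#'
#' @param gamma,beta Coefficient vectors, one entry per design column.
#' @param design Numeric design matrix (samples x coefficients).
#' @param clamp Clamp on the logistic linear predictor.
#' @return A list with numeric vectors `p` (in (0,1)) and `mu`.
#' @export
link_eval <- function(gamma, beta, design, clamp = 30) {
  if (length(gamma) != ncol(design) || length(beta) != ncol(design)) {
    stop("coefficient length does not match design columns")
  }
  list(
    p = stats::plogis(clamp_eta(drop(design %*% gamma), clamp)),
    mu = drop(design %*% beta)
  )
}

#' Mixture log-density of one observation
#'
#' The observed abundance is zero (a PMV) with probability
#' `p + (1 - p) * Phi((lam - mu) / sigma)` — a biological zero, or a
#' lognormal draw censored below the detection limit — and otherwise has the
#' lognormal log-density evaluated on the log scale,
#' `log(1 - p) + log phi((log y - mu) / sigma) - log sigma`. The constant
#' `1/y` Jacobian of the log transform is omitted throughout: it is free of
#' all parameters, so it cancels in every maximisation and likelihood ratio.
#'
#' @param y Non-negative observation(s).
#' @param p Zero-inflation probability in (0,1).
#' @param mu Log-scale mean.
#' @param sigma Log-scale standard deviation (> 0).
#' @param lam Log-scale detection limit.
#' @return Log-density value(s).
#' @export
log_density <- function(y, p, mu, sigma, lam) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(y < 0)) stop("negative abundance")
  out <- numeric(length(y))
  z <- y == 0
  if (any(z)) {
    out[z] <- log(pmv_probability(rep_len(p, length(y))[z],
      rep_len(mu, length(y))[z], sigma, lam))
  }
  if (any(!z)) {
    pp <- rep_len(p, length(y))[!z]
    mm <- rep_len(mu, length(y))[!z]
    out[!z] <- log1p(-pp) +
      stats::dnorm((log(y[!z]) - mm) / sigma, log = TRUE) - log(sigma)
  }
  out
}

#' Total probability of observing a zero
#'
#' Combines the biological point mass with the censored share of the
#' lognormal component: `p + (1 - p) * Phi((lam - mu) / sigma)`.
#'
#' @inheritParams log_density
#' @return Probability in `[0, 1]`.
#' @export
pmv_probability <- function(p, mu, sigma, lam) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  p + (1 - p) * stats::pnorm((lam - mu) / sigma)
}

#' Per-feature log-likelihood
#'
#' Sums the mixture log-density over samples, with per-sample `p_i`, `mu_i`
#' from the link models.
#'
#' @param gamma,beta,sigma Feature parameters.
#' @param design Design matrix (samples x coefficients).
#' @param feature_values Non-negative abundances, one per sample.
#' @param lam Log-scale detection limit.
#' @param clamp Clamp on the logistic linear predictor.
#' @return The log-likelihood (a scalar).
#' @export
feature_loglik <- function(gamma, beta, sigma, design, feature_values, lam,
                           clamp = 30) {
  lk <- link_eval(gamma, beta, design, clamp)
  ll <- sum(log_density(feature_values, lk$p, lk$mu, sigma, lam))
  if (!is.finite(ll)) {
    stop("non-finite log-likelihood at gamma=(", paste(signif(gamma, 6), collapse = ","),
      "), beta=(", paste(signif(beta, 6), collapse = ","), "), sigma=", signif(sigma, 6))
  }
  ll
}

# Objective factory for the theta = (gamma, beta) maximisation with sigma
# fixed: returns negative log-likelihood and gradient closures sharing one
# computation pass (BFGS evaluates both at the same point). `fixed` indexes
# theta coordinates pinned at zero (null-constrained fits).
LOG_SQRT_2PI <- 0.5 * log(2 * pi)

make_theta_objective <- function(X, feature_values, sigma, lam, clamp,
                                 fixed = integer()) {
  d <- ncol(X)
  free <- setdiff(seq_len(2L * d), fixed)
  is_pmv <- feature_values == 0
  Xz <- X[is_pmv, , drop = FALSE]
  Xnz <- X[!is_pmv, , drop = FALSE]
  logy_nz <- log(feature_values[!is_pmv])
  n_z <- nrow(Xz)
  n_nz <- nrow(Xnz)
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  compute <- function(theta_free) {
    theta <- numeric(2L * d)
    theta[free] <- theta_free
    gamma <- theta[seq_len(d)]
    beta <- theta[d + seq_len(d)]
    ll <- 0
    dldeta_z <- NULL; dldmu_z <- NULL; dldeta_nz <- NULL; dldmu_nz <- NULL
    if (n_z) {
      eta <- Xz %*% gamma
      eta[eta > clamp] <- clamp; eta[eta < -clamp] <- -clamp
      p <- 1 / (1 + exp(-eta))
      a <- (lam - Xz %*% beta) / sigma
      Phi <- stats::pnorm(a)
      D <- p + (1 - p) * Phi
      ll <- ll + sum(log(D))
      dldeta_z <- p * (1 - p) * (1 - Phi) / D
      dldmu_z <- -(1 - p) * exp(-0.5 * a * a - LOG_SQRT_2PI) / (sigma * D)
    }
    if (n_nz) {
      eta <- Xnz %*% gamma
      eta[eta > clamp] <- clamp; eta[eta < -clamp] <- -clamp
      p <- 1 / (1 + exp(-eta))
      z <- (logy_nz - Xnz %*% beta) / sigma
      ll <- ll + sum(log1p(-p)) - 0.5 * sum(z * z) -
        n_nz * (LOG_SQRT_2PI + log(sigma))
      dldeta_nz <- -p
      dldmu_nz <- z / sigma
    }
    g <- numeric(2L * d)
    if (n_z) {
      g[seq_len(d)] <- g[seq_len(d)] + crossprod(Xz, dldeta_z)
      g[d + seq_len(d)] <- g[d + seq_len(d)] + crossprod(Xz, dldmu_z)
    }
    if (n_nz) {
      g[seq_len(d)] <- g[seq_len(d)] + crossprod(Xnz, dldeta_nz)
      g[d + seq_len(d)] <- g[d + seq_len(d)] + crossprod(Xnz, dldmu_nz)
    }
    g[!is.finite(g)] <- 0
    cache$par <- theta_free
    cache$value <- if (is.finite(ll)) -ll else 1e10
    cache$grad <- -g[free]
  }
  list(
    fn = function(par) {
      if (is.null(cache$par) || !identical(par, cache$par)) compute(par)
      cache$value
    },
    gr = function(par) {
      if (is.null(cache$par) || !identical(par, cache$par)) compute(par)
      cache$grad
    },
    free = free
  )
}
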