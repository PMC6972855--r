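#' Likelihood ratio test for one feature
#'
#' Fits the unconstrained model, freezes the variance at the resulting
#' shrunken estimate `sigma_tilde`, refits the coefficients under the null
#' constraint with the variance held fixed, and forms
#' `2 * (loglik_full - loglik_null)` against a chi-squared reference. The
#' variance is deliberately not re-estimated under the null: evaluating both
#' likelihoods at the same `sigma_tilde` keeps the models exactly nested, so
#' the statistic is non-negative up to optimiser noise.
#'
#' Hypotheses, for the `j`-th covariate (a non-intercept design column):
#' `"M"` — no effect on the non-zero mean (`beta_j = 0`, 1 df); `"P"` — no
#' effect on the zero proportion (`gamma_j = 0`, 1 df); `"B"` — neither
#' effect (`beta_j = gamma_j = 0`, 2 df).
#'
#' @param feature_values Non-negative abundances.
#' @param design Design matrix.
#' @param hp A `dasev_prior` (dasev mode) or `NULL` (tlk mode).
#' @param lam Log-scale detection limit.
#' @param hypothesis One of `"M"`, `"P"`, `"B"`.
#' @param j Covariate column index in the design (default 2, the group
#'   indicator).
#' @param config A [fit_config()] list.
#' @return A one-row tibble: `hypothesis`, `covariate`, `gamma_j`, `beta_j`,
#'   `sigma_tilde`, `lrt_stat`, `df`, `p_value`, `converged`.
#' @export
lrt_feature <- function(feature_values, design, hp = NULL, lam,
                        hypothesis = c("M", "P", "B"), j = 2L,
                        config = fit_config()) {
  hypothesis <- match.arg(hypothesis)
  d <- ncol(design)
  if (j <= 1L || j > d) stop("`j` must index a non-intercept design column")
  full <- fit_feature(feature_values, design, hp, lam, config)
  fixed <- switch(hypothesis,
    M = d + j,
    P = j,
    B = c(j, d + j))
  null <- maximize_theta(feature_values, design, full$sigma_tilde, lam,
    init = c(full$gamma, full$beta), fixed = fixed, config = config)
  full_gamma <- full$gamma
  full_beta <- full$beta
  full_ll <- full$loglik
  if (null$loglik > full_ll) {
    # the null iterate is feasible for the full model: restart the full
    # maximisation from it so the nesting guarantee is restored
    refit <- maximize_theta(feature_values, design, full$sigma_tilde, lam,
      init = c(null$gamma, null$beta), config = config)
    if (refit$loglik > full_ll) {
      full_gamma <- refit$gamma
      full_beta <- refit$beta
      full_ll <- refit$loglik
    }
  }
  lrt <- 2 * (full_ll - null$loglik)
  if (lrt < -1e-8) {
    stop("negative likelihood ratio statistic (", signif(lrt, 4),
      "): null fit exceeded the full fit, optimiser failure")
  }
  lrt <- max(lrt, 0)
  df <- if (hypothesis == "B") 2L else 1L
  tibble::tibble(
    hypothesis = hypothesis, covariate = j,
    gamma_j = full_gamma[j], beta_j = full_beta[j],
    sigma_tilde = full$sigma_tilde,
    lrt_stat = lrt, df = df,
    p_value = stats::pchisq(lrt, df, lower.tail = FALSE),
    converged = full$converged && null$converged
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up q-values, `q_(i) = min_{k >= i} m p_(k) / k` capped at 1
#' and mapped back to input order.
#'
#' @param p_values Vector of p-values in `[0, 1]` (no missing values).
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values)) stop("missing p-values must be excluded upstream")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Differential abundance analysis of an abundance matrix
#'
#' The full pipeline: feature filtering, per-feature detection limits, prior
#' hyperparameter estimation (dasev mode), per-feature likelihood ratio
#' tests, and Benjamini-Hochberg adjustment across tested features. Features
#' whose fit fails are reported with `NA` p-values and excluded from the
#' adjustment (the effective number of tests is the count of finite
#' p-values); the batch never aborts on a single feature.
#'
#' @param x An abundance matrix (see [abundance_matrix()]).
#' @param design A design matrix from [build_design()], or a two-level group
#'   vector aligned with the columns of `x`.
#' @param hypothesis `"M"` (non-zero mean), `"P"` (zero proportion), or
#'   `"B"` (both).
#' @param mode `"dasev"` or `"tlk"`.
#' @param j Covariate column tested (default 2, the group indicator).
#' @param min_nonpmv,require_mixed_per_group Filtering rules, see
#'   [filter_features()].
#' @param epsilon Detection-limit offset.
#' @param config Optional [fit_config()]; its `mode` is overridden by `mode`.
#' @return A tibble of class `dasev_results`, one row per kept feature:
#'   `feature_id`, `gamma_j`, `beta_j` (the log-scale mean effect),
#'   `fold_change` (`exp(beta_j)`), `sigma_tilde`, `lrt_stat`, `df`,
#'   `p_value`, `q_value`, `converged`. Attributes carry the prior, mode,
#'   hypothesis and the filter report.
#' @export
run_analysis <- function(x, design, hypothesis = c("M", "P", "B"),
                         mode = c("dasev", "tlk"), j = 2L, min_nonpmv = 3,
                         require_mixed_per_group = TRUE, epsilon = 0.1,
                         config = NULL) {
  hypothesis <- match.arg(hypothesis)
  mode <- match.arg(mode)
  if (!is.matrix(design)) {
    design <- cbind(intercept = 1, group = design_group(design))
  }
  if (is.null(config)) config <- fit_config(mode = mode)
  config$mode <- mode
  flt <- filter_features(x, design, min_nonpmv, require_mixed_per_group)
  kept <- flt$kept_ids
  if (length(kept) == 0L) {
    warning("no features pass the filters")
    out <- tibble::tibble(feature_id = character(), gamma_j = numeric(),
      beta_j = numeric(), fold_change = numeric(), sigma_tilde = numeric(),
      lrt_stat = numeric(), df = integer(), p_value = numeric(),
      q_value = numeric(), converged = logical())
    return(as_dasev_results(out, NULL, mode, hypothesis, flt, design))
  }
  hp <- if (mode == "dasev") estimate_prior(x, epsilon) else NULL
  rows <- purrr::map(kept, function(k) {
    y <- x[k, ]
    lam <- compute_detection_limit(y, epsilon)
    res <- try(lrt_feature(y, design, hp, lam, hypothesis, j, config),
      silent = TRUE)
    if (inherits(res, "try-error")) {
      return(tibble::tibble(feature_id = k, gamma_j = NA_real_,
        beta_j = NA_real_, sigma_tilde = NA_real_, lrt_stat = NA_real_,
        df = NA_integer_, p_value = NA_real_, converged = FALSE))
    }
    tibble::tibble(feature_id = k, gamma_j = res$gamma_j,
      beta_j = res$beta_j, sigma_tilde = res$sigma_tilde,
      lrt_stat = res$lrt_stat, df = res$df, p_value = res$p_value,
      converged = res$converged)
  })
  out <- dplyr::bind_rows(rows)
  out$fold_change <- exp(out$beta_j)
  out$q_value <- NA_real_
  ok <- is.finite(out$p_value)
  if (any(!ok)) {
    warning(sum(!ok), " feature(s) failed to fit; excluded from FDR adjustment")
  }
  out$q_value[ok] <- bh_adjust(out$p_value[ok])
  out <- dplyr::select(out, "feature_id", "gamma_j", "beta_j", "fold_change",
    "sigma_tilde", "lrt_stat", "df", "p_value", "q_value", "converged")
  as_dasev_results(out, hp, mode, hypothesis, flt, design)
}

as_dasev_results <- function(out, hp, mode, hypothesis, flt, design) {
  structure(out,
    class = c("dasev_results", class(out)),
    prior = hp, mode = mode, hypothesis = hypothesis,
    filter_report = flt$report,
    n_per_group = as.vector(table(design[, "group"])))
}

#' One-row summary of a differential abundance analysis
#'
#' @param x A `dasev_results` tibble.
#' @param fdr Significance threshold on q-values (default 0.05).
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `hypothesis`, `n_tested`, `n_failed`,
#'   `n_significant`, `fdr_threshold`, and the prior hyperparameters
#'   (`NA` in tlk mode).
#' @export
glance.dasev_results <- function(x, fdr = 0.05, ...) {
  hp <- attr(x, "prior")
  tibble::tibble(
    mode = attr(x, "mode"), hypothesis = attr(x, "hypothesis"),
    n_tested = sum(is.finite(x$p_value)),
    n_failed = sum(!is.finite(x$p_value)),
    n_significant = sum(x$q_value <= fdr, na.rm = TRUE),
    fdr_threshold = fdr,
    d0 = if (is.null(hp)) NA_real_ else hp$d0,
    s0 = if (is.null(hp)) NA_real_ else hp$s0
  )
}
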