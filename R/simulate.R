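#' Synthetic parameter pool for simulation studies
#'
#' Generates per-feature parameter triples (log-scale mean, biological-zero
#' proportion, detection limit) plus an independent variance pool, emulating
#' the parameter ensemble of a large zero-heavy MS cohort: zero
#' proportions are strongly right-shifted (mean ~0.80, spanning roughly
#' 0.006-0.999), means decrease with the zero proportion, detection limits
#' sit far enough below the means that induced technical-zero fractions are
#' mostly below 5% with a pool mean near 1.6%, and variances are drawn from a
#' moderate-spread inverse-gamma independently of the triples. Entries whose
#' mean falls below the detection limit are excluded.
#'
#' @param n_entries Number of pool entries (>= 100).
#' @param seed Integer seed.
#' @return A tibble of class `dasev_pool` with columns `mu`, `p_bpmv`,
#'   `lambda`, `sigma` (the variance pool, aligned by row but drawn
#'   independently).
#' @export
synthetic_parameter_pool <- function(n_entries = 5000, seed = 1) {
  if (n_entries < 100) stop("pool needs at least 100 entries")
  set.seed(seed)
  n <- 0L
  out <- NULL
  while (n < n_entries) {
    m <- ceiling(1.1 * (n_entries - n))
    # most features are zero-dominated; a small component of abundant,
    # almost-always-detected compounds carries the low end of the range
    low <- stats::runif(m) < 0.05
    p <- ifelse(low, stats::rbeta(m, 0.8, 2.5), stats::rbeta(m, 2.1, 0.47))
    p <- pmin(pmax(p, 0.002), 0.9995)
    mu <- 7 - 3 * p + stats::rnorm(m, 0, 0.8)
    sigma <- sqrt(1 / stats::rgamma(m, shape = 3, rate = 2))
    depth <- stats::rlnorm(m, log(1.6), 0.5)
    lambda <- mu - depth * sigma
    keep <- mu >= lambda
    chunk <- tibble::tibble(mu = mu[keep], p_bpmv = p[keep],
      lambda = lambda[keep], sigma = sigma[keep])
    out <- if (is.null(out)) chunk else dplyr::bind_rows(out, chunk)
    n <- nrow(out)
  }
  out <- out[seq_len(n_entries), ]
  class(out) <- c("dasev_pool", class(out))
  out
}

#' Simulate one feature from the mixture model
#'
#' Per sample: with probability `p_bpmv` emit a biological zero; otherwise
#' draw a log-abundance `z ~ Normal(mu, sigma^2)` and emit zero if
#' `z <= lambda` (a technical zero below the detection limit), else
#' `exp(z)`.
#'
#' @param mu Log-scale mean.
#' @param p_bpmv Biological-zero probability.
#' @param sigma Log-scale standard deviation.
#' @param lambda Log-scale detection limit.
#' @param n Number of samples.
#' @return Numeric vector of `n` non-negative abundances.
#' @export
simulate_feature <- function(mu, p_bpmv, sigma, lambda, n) {
  bp <- stats::runif(n) < p_bpmv
  z <- stats::rnorm(n, mu, sigma)
  ifelse(bp | z <= lambda, 0, exp(z))
}

#' Scenario configuration for simulated differential abundance studies
#'
#' @param n_features Number of features per dataset.
#' @param de_fraction Fraction of features made differentially abundant.
#' @param fold_change Ratio-scale effect size (the log-scale shift is
#'   `log(fold_change)`).
#' @param direction_split Fraction of DE features shifted up in the case
#'   group (the rest are shifted down).
#' @param n_per_group Samples per group.
#' @param n_replicates Number of replicate datasets.
#' @param seed Master seed; per-replicate streams derive from it.
#' @param effect_target `"mean"` (shift the non-zero mean), `"proportion"`
#'   (shift the zero-proportion logit), or `"both"`.
#' @param dissonant_fraction For `"both"`: fraction of DE features whose
#'   zero-proportion shift opposes the mean shift's abundance direction.
#' @return A list of class `dasev_scenario`.
#' @export
scenario_config <- function(n_features = 5000, de_fraction = 0.10,
                            fold_change = 2.0, direction_split = 0.5,
                            n_per_group = 100, n_replicates = 100, seed = 1,
                            effect_target = c("mean", "proportion", "both"),
                            dissonant_fraction = 0.5) {
  effect_target <- match.arg(effect_target)
  stopifnot(de_fraction >= 0, de_fraction <= 1, fold_change > 0,
    n_per_group >= 2, n_features >= 1)
  structure(list(n_features = n_features, de_fraction = de_fraction,
    fold_change = fold_change, direction_split = direction_split,
    n_per_group = n_per_group, n_replicates = n_replicates, seed = seed,
    effect_target = effect_target,
    dissonant_fraction = dissonant_fraction), class = "dasev_scenario")
}

# Deterministic per-replicate seed stream below 2^31.
derive_seed <- function(master, rep) {
  (as.numeric(master) * 48271 + rep * 7919) %% 2147483647
}

#' Simulate a two-group dataset with known differential abundance truth
#'
#' Control-group parameters are resampled (with replacement) from the pool;
#' a `de_fraction` share of features receives a `fold_change` effect in the
#' case group — an additive `log(fold_change)` shift of the non-zero mean,
#' a matching shift of the zero-proportion logit, or both — split between
#' up- and down-shifted features by `direction_split`.
#'
#' @param pool A `dasev_pool` tibble.
#' @param config A [scenario_config()] list.
#' @param rep Replicate index (seeds the replicate's stream).
#' @return A list with `matrix` (an abundance matrix, case and control
#'   samples column-bound) , `design` (from [build_design()]), `samples`
#'   (the sample table), and `truth`, a tibble with per-feature `is_de`,
#'   `direction`, and the generating parameters of both groups.
#' @export
simulate_dataset <- function(pool, config = scenario_config(), rep = 1L) {
  set.seed(derive_seed(config$seed, rep))
  K <- config$n_features
  n <- config$n_per_group
  idx <- sample.int(nrow(pool), K, replace = TRUE)
  mu0 <- pool$mu[idx]; p0 <- pool$p_bpmv[idx]
  lam <- pool$lambda[idx]
  sigma <- pool$sigma[sample.int(nrow(pool), K, replace = TRUE)]
  n_de <- round(config$de_fraction * K)
  is_de <- rep(FALSE, K)
  direction <- rep(0L, K)
  if (n_de >= 1) {
    de_idx <- sample.int(K, n_de)
    n_up <- round(config$direction_split * n_de)
    direction[de_idx] <- c(rep(1L, n_up), rep(-1L, n_de - n_up))
    is_de[de_idx] <- TRUE
  } else if (config$de_fraction > 0) {
    warning("de_fraction * n_features < 1: no DE features generated")
  }
  shift <- direction * log(config$fold_change)
  mu1 <- mu0
  p1 <- p0
  if (config$effect_target %in% c("mean", "both")) mu1 <- mu0 + shift
  if (config$effect_target %in% c("proportion", "both")) {
    prop_sign <- -direction   # consonant: higher abundance, fewer zeros
    if (config$effect_target == "both" && n_de >= 1) {
      dis <- stats::runif(K) < config$dissonant_fraction
      prop_sign[is_de & dis] <- -prop_sign[is_de & dis]
    }
    p1 <- stats::plogis(stats::qlogis(p0) + prop_sign * log(config$fold_change))
  }
  sim_group <- function(muv, pv) {
    vapply(seq_len(K), function(k) {
      simulate_feature(muv[k], pv[k], sigma[k], lam[k], n)
    }, numeric(n))
  }
  y0 <- t(sim_group(mu0, p0))
  y1 <- t(sim_group(mu1, p1))
  mat <- cbind(y0, y1)
  rownames(mat) <- paste0("feature_", seq_len(K))
  colnames(mat) <- c(paste0("ctrl_", seq_len(n)), paste0("case_", seq_len(n)))
  samples <- tibble::tibble(
    sample_id = colnames(mat),
    group = rep(c("control", "case"), each = n)
  )
  design <- build_design(samples, reference = "control")
  truth <- tibble::tibble(
    feature_id = rownames(mat), is_de = is_de, direction = direction,
    mu_control = mu0, mu_case = mu1, p_control = p0, p_case = p1,
    sigma = sigma, lambda = lam
  )
  list(matrix = abundance_matrix(mat), design = design, samples = samples,
    truth = truth)
}

#' True positive rate among top-ranked features
#'
#' Ranks features by ascending p-value (ties broken by larger likelihood
#' ratio statistic, then feature id) and reports, for each `k`, the fraction
#' of the top `k` features that are truly differentially abundant.
#'
#' @param results A `dasev_results` tibble.
#' @param truth The `truth` tibble from [simulate_dataset()].
#' @param max_k Largest rank cutoff.
#' @return A tibble with columns `k` and `tpr`.
#' @export
tpr_curve <- function(results, truth, max_k = nrow(results)) {
  res <- dplyr::inner_join(
    tibble::as_tibble(results)[, c("feature_id", "p_value", "lrt_stat")],
    truth[, c("feature_id", "is_de")], by = "feature_id")
  res <- res[is.finite(res$p_value), ]
  ord <- order(res$p_value, -res$lrt_stat, res$feature_id)
  hits <- cumsum(res$is_de[ord])
  k <- seq_len(min(max_k, nrow(res)))
  tibble::tibble(k = k, tpr = hits[k] / k)
}

#' Observed false discovery proportion at a nominal threshold
#'
#' Selects features with `q_value <= nominal` and reports true/false positive
#' counts and the observed false discovery proportion. An empty selection is
#' reported as zero with `empty_selection = TRUE`.
#'
#' @param results A `dasev_results` tibble.
#' @param truth The `truth` tibble from [simulate_dataset()].
#' @param nominal Nominal FDR threshold.
#' @return A one-row tibble: `nominal`, `n_selected`, `tp`, `fp`,
#'   `observed_fdr`, `empty_selection`.
#' @export
observed_fdr <- function(results, truth, nominal = 0.05) {
  res <- dplyr::inner_join(
    tibble::as_tibble(results)[, c("feature_id", "q_value")],
    truth[, c("feature_id", "is_de")], by = "feature_id")
  sel <- !is.na(res$q_value) & res$q_value <= nominal
  tp <- sum(res$is_de[sel])
  fp <- sum(!res$is_de[sel])
  tibble::tibble(nominal = nominal, n_selected = tp + fp, tp = tp, fp = fp,
    observed_fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
    empty_selection = tp + fp == 0)
}

#' Replicated simulation study comparing shrinkage and unshrunk fits
#'
#' Simulates `config$n_replicates` datasets, analyses each with both the
#' empirical-Bayes (`dasev`) and unshrunk (`tlk`) fits, and collects ranking
#' and FDR metrics plus variance-recovery summaries per replicate.
#'
#' @param pool A `dasev_pool` tibble (defaults to a fresh pool seeded from
#'   `config$seed`).
#' @param config A [scenario_config()] list.
#' @param top_k Rank cutoff for the true-positive-rate summary.
#' @param nominal Nominal FDR thresholds to evaluate.
#' @param hypothesis Hypothesis tested per feature.
#' @return A tibble of class `dasev_study`, one row per replicate x mode:
#'   `replicate`, `mode`, `n_tested`, `tpr_top_k`, per-threshold observed
#'   FDR columns, and `frac_extreme_var` (share of features whose
#'   variance-estimate-to-truth ratio falls outside `[0.1, 10]`).
#' @export
run_scenario_study <- function(pool = NULL, config = scenario_config(),
                               top_k = 150, nominal = c(0.01, 0.05, 0.10),
                               hypothesis = "M") {
  if (is.null(pool)) pool <- synthetic_parameter_pool(seed = config$seed)
  rows <- purrr::map(seq_len(config$n_replicates), function(r) {
    sim <- simulate_dataset(pool, config, rep = r)
    purrr::map(c("dasev", "tlk"), function(mode) {
      res <- run_analysis(sim$matrix, sim$design, hypothesis = hypothesis,
        mode = mode)
      tc <- tpr_curve(res, sim$truth, max_k = top_k)
      fdrs <- purrr::map(nominal, function(a) observed_fdr(res, sim$truth, a))
      vr <- dplyr::inner_join(tibble::as_tibble(res)[, c("feature_id", "sigma_tilde")],
        sim$truth[, c("feature_id", "sigma")], by = "feature_id")
      ratio <- (vr$sigma_tilde / vr$sigma)^2
      row <- tibble::tibble(
        replicate = r, mode = mode,
        n_tested = sum(is.finite(res$p_value)),
        tpr_top_k = tc$tpr[min(top_k, nrow(tc))],
        frac_extreme_var = mean(ratio > 10 | ratio < 0.1, na.rm = TRUE)
      )
      for (i in seq_along(nominal)) {
        row[[paste0("fdr_at_", nominal[i] * 100)]] <- fdrs[[i]]$observed_fdr
        row[[paste0("tp_at_", nominal[i] * 100)]] <- fdrs[[i]]$tp
        row[[paste0("fp_at_", nominal[i] * 100)]] <- fdrs[[i]]$fp
      }
      row
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("dasev_study", class(out))
  attr(out, "config") <- config
  attr(out, "top_k") <- top_k
  out
}
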