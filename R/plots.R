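#' Volcano plot of a differential abundance analysis
#'
#' Log fold change (natural log of the mean effect, converted to log2 for
#' the axis) against `-log10` p-value, coloured by significance at `fdr`.
#'
#' @param object A `dasev_results` tibble.
#' @param fdr Significance threshold on q-values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dasev_results <- function(object, fdr = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$p_value), ]
  df$significant <- !is.na(df$q_value) & df$q_value <= fdr
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$beta_j / log(2),
    y = -log10(pmax(.data$p_value, 1e-300)),
    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
      `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "log2 fold change (non-zero mean)",
      y = "-log10 p-value",
      colour = paste0("q <= ", fdr)) +
    ggplot2::theme_minimal()
}

#' True-positive-rate curves of a simulation study
#'
#' @param object A `dasev_study` tibble from [run_scenario_study()].
#' @param ... Unused.
#' @return A ggplot object: per-mode distribution of the top-k true positive
#'   rate across replicates.
#' @export
autoplot.dasev_study <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$tpr_top_k,
    fill = .data$mode)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL,
      y = paste0("TPR among top ", attr(object, "top_k"), " features")) +
    ggplot2::theme_minimal()
}

#' Compare variance estimates between two analyses
#'
#' Scatter of per-feature variance estimates (`sigma_tilde^2`) from two
#' result tables over the same features, on log axes with the identity line;
#' the classic picture of shrinkage pulling extreme unshrunk estimates
#' towards the ensemble.
#'
#' @param x,y Two `dasev_results` tibbles over the same features (e.g. dasev
#'   and tlk modes).
#' @param labels Axis labels.
#' @return A ggplot object.
#' @export
plot_variance_comparison <- function(x, y,
    labels = c(attr(x, "mode"), attr(y, "mode"))) {
  df <- dplyr::inner_join(
    tibble::as_tibble(x)[, c("feature_id", "sigma_tilde")],
    tibble::as_tibble(y)[, c("feature_id", "sigma_tilde")],
    by = "feature_id", suffix = c("_x", "_y"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma_tilde_x^2,
    y = .data$sigma_tilde_y^2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste("variance,", labels[1]),
      y = paste("variance,", labels[2])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
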