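#' Histogram of cross-validated test AUC values
#'
#' @param object A `tos_evaluation`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tos_evaluation <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_auc, linetype = 2) +
    ggplot2::labs(
      x = "test AUC", y = "folds",
      title = sprintf("Cross-validated ranking performance (%s)",
                      paste(object$features, collapse = "+")),
      subtitle = sprintf("mean %.3f, sd %.3f over %d x %d folds",
                         object$mean_auc, object$sd_auc,
                         object$config$n_repeats, object$config$n_folds)
    ) +
    ggplot2::theme_minimal()
}

#' Perturbation profile plot
#'
#' Node perturbation scores against their Monte-Carlo p-values, with the
#' significant neighborhood highlighted.
#'
#' @param object A [perturbation_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perturbation_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = -log10(.data$p_value),
                                   colour = .data$in_neighborhood)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "perturbation score S", y = "-log10 p",
                  colour = "in neighborhood",
                  title = attr(object, "drug_id") %||% "perturbation profile") +
    ggplot2::theme_minimal()
}

#' Score distributions by combination class
#'
#' Boxplots of a score column stratified by label — the summary view used
#' to compare beneficial, detrimental and random combinations.
#'
#' @param scored Tibble from [score_combinations()] with a `label` column.
#' @param measure Score column to plot.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(scored, measure = "tos") {
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$label,
                                       y = .data[[measure]],
                                       fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_minimal()
}
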