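#' Tidy a logistic combiner
#'
#' @param x A `tos_model`.
#' @param ... Unused.
#' @return Tibble with one row per term: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
tidy.tos_model <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    statistic = cf[, "z value"],
    p_value = cf[, "Pr(>|z|)"]
  )
}

#' One-row summary of a logistic combiner
#'
#' @param x A `tos_model`.
#' @param ... Unused.
#' @return Tibble: `null_deviance`, `deviance`, `aic`, `n`, `converged`.
#' @export
glance.tos_model <- function(x, ...) {
  f <- x$fit
  tibble(
    null_deviance = f$null.deviance,
    deviance = f$deviance,
    aic = f$aic,
    n = length(f$y),
    converged = f$converged
  )
}

#' Tidy a cross-validation report
#'
#' @param x A `tos_evaluation`.
#' @param ... Unused.
#' @return The per-fold AUC tibble (`repeat_id`, `fold`, `auc`, `n_test`).
#' @export
tidy.tos_evaluation <- function(x, ...) x$folds

#' One-row summary of a cross-validation report
#'
#' @param x A `tos_evaluation`.
#' @param ... Unused.
#' @return Tibble: `mean_auc`, `sd_auc`, `n_folds`, `n_repeats`,
#'   `features`, `seed`.
#' @export
glance.tos_evaluation <- function(x, ...) {
  tibble(
    mean_auc = x$mean_auc,
    sd_auc = x$sd_auc,
    n_folds = x$config$n_folds,
    n_repeats = x$config$n_repeats,
    features = paste(x$features, collapse = "+"),
    seed = x$config$random_seed
  )
}

#' Export an evaluation report
#'
#' Writes the per-fold AUC table as TSV and the one-row summary as JSON
#' next to it.
#'
#' @param report A `tos_evaluation`.
#' @param path Output TSV path; the JSON summary gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(report, path) {
  readr::write_tsv(tidy(report), path, progress = FALSE)
  summary_path <- sub("\\.[^.]*$", ".json", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, ".json")
  g <- glance(report)
  json <- sprintf(
    '{"mean_auc": %.10g, "sd_auc": %.10g, "n_folds": %d, "n_repeats": %d, "features": "%s", "seed": %d}',
    g$mean_auc, g$sd_auc, g$n_folds, g$n_repeats, g$features, g$seed)
  writeLines(json, summary_path)
  invisible(path)
}
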