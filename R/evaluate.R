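#' Fit the logistic score combiner
#'
#' Combines interaction measures (any subset of TOS, GO, ATC, each in
#' \[0, 1\]) into a single score by maximum-likelihood logistic regression:
#' `M = 1 / (1 + exp(-(beta0 + sum_i beta_i m_i)))`, so positively weighted
#' evidence increases the combined score. Positive examples are known
#' combinations, negatives random drug pairs.
#'
#' @param rows Tibble with a binary `label` column (1/TRUE = positive) and
#'   one numeric column per measure.
#' @param features Character vector naming the measure columns to combine.
#' @return A `tos_model` wrapping the `glm` fit; supports [predict()],
#'   [tidy()] and [glance()]. Perfect separation yields a
#'   converged-with-warning fit, not an error.
#' @export
fit_logistic <- function(rows, features = intersect(c("tos", "go", "atc"),
                                                    names(rows))) {
  rows <- as_tibble(rows)
  if (!"label" %in% names(rows)) abort("Rows need a 'label' column.")
  if (length(features) == 0) abort("No feature columns to combine.")
  y <- as.integer(as.logical(rows$label))
  if (length(unique(y)) < 2) abort("Both classes must be present to fit.")
  X <- rows[features]
  if (anyNA(X)) abort("Missing feature values; assemble rows completely first.")
  fit <- glm(y ~ ., data = cbind(y = y, X), family = binomial())
  structure(list(fit = fit, features = features), class = "tos_model")
}

#' @export
print.tos_model <- function(x, ...) {
  cat("<tos_model> logistic combiner of:", paste(x$features, collapse = ", "), "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' Combined score for new combinations
#'
#' @param object A `tos_model`.
#' @param newdata Tibble carrying the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of combined scores in (0, 1).
#' @export
predict.tos_model <- function(object, newdata, ...) {
  unname(predict(object$fit, newdata = as_tibble(newdata)[object$features],
                 type = "response"))
}

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive is scored above a randomly chosen negative, with ties credited
#' one half. Equals all-pairs enumeration exactly.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Binary labels (1/TRUE = positive).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.5, 0.9, 0.5, 0.1), c(1, 1, 0, 0))  # 0.875
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present for ROC analysis.")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Repeated cross-validated ranking evaluation
#'
#' The evaluation protocol for a candidate score: in each repeat a fresh
#' negative set is drawn, the pooled positive + negative rows are split
#' into stratified folds, a logistic combiner is fitted on the training
#' folds, and the test-fold AUC is recorded. Reported are all per-fold AUC
#' values plus their mean and standard deviation. Fully seeded: repeats get
#' independent seeds derived from `config$random_seed` via a counter.
#'
#' @param positives Tibble of positive rows carrying the feature columns, or
#'   a function `(seed) -> tibble` called once per repeat (used e.g. for
#'   label-permutation controls, where both classes must be redrawn
#'   together; the repeat seed it receives matches the one passed to
#'   `negative_resampler`).
#' @param negative_resampler Function `(seed) -> tibble` returning a fresh
#'   negative set with the same feature columns.
#' @param features Measure columns to combine (single feature = ranking by
#'   that measure through a monotone logistic transform).
#' @param config A [run_config()]; uses `n_folds`, `n_repeats`,
#'   `random_seed`.
#' @return A `tos_evaluation` object: `folds` tibble (`repeat_id`, `fold`,
#'   `auc`, `n_test`), `mean_auc`, `sd_auc`, `coefficients` tibble, the
#'   feature names and a config echo. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
cross_validate <- function(positives, negative_resampler,
                           features = c("tos"), config = run_config()) {
  stopifnot(config$n_folds >= 2)
  if (!is.function(positives)) positives <- as_tibble(positives)
  set.seed(config$random_seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, config$n_repeats)

  fold_rows <- list()
  coef_rows <- list()
  for (r in seq_len(config$n_repeats)) {
    pos_r <- if (is.function(positives)) {
      as_tibble(positives(repeat_seeds[r]))
    } else {
      positives
    }
    negatives <- as_tibble(negative_resampler(repeat_seeds[r]))
    rows <- bind_rows(
      mutate(pos_r[features], label = 1L),
      mutate(negatives[features], label = 0L)
    )
    set.seed(repeat_seeds[r])
    fold <- stratified_folds(rows$label, config$n_folds)
    for (f in seq_len(config$n_folds)) {
      test <- rows[fold == f, , drop = FALSE]
      train <- rows[fold != f, , drop = FALSE]
      attempt <- 0L
      while ((length(unique(train$label)) < 2 ||
              length(unique(test$label)) < 2) && attempt < 1L) {
        fold <- stratified_folds(rows$label, config$n_folds)
        test <- rows[fold == f, , drop = FALSE]
        train <- rows[fold != f, , drop = FALSE]
        attempt <- attempt + 1L
      }
      if (length(unique(train$label)) < 2 || length(unique(test$label)) < 2) {
        abort("A fold lost one of the classes even after resplitting.")
      }
      model <- suppressWarnings(fit_logistic(train, features))
      auc <- roc_auc(predict(model, test), test$label)
      fold_rows[[length(fold_rows) + 1L]] <-
        tibble(repeat_id = r, fold = f, auc = auc, n_test = nrow(test))
      cf <- stats::coef(model$fit)
      coef_rows[[length(coef_rows) + 1L]] <-
        tibble(repeat_id = r, fold = f,
               term = names(cf), estimate = unname(cf))
    }
  }
  folds <- bind_rows(fold_rows)
  structure(
    list(folds = folds,
         mean_auc = mean(folds$auc),
         sd_auc = sd(folds$auc),
         coefficients = bind_rows(coef_rows),
         features = features,
         config = config),
    class = "tos_evaluation"
  )
}

#' @export
print.tos_evaluation <- function(x, ...) {
  cat(sprintf(
    "<tos_evaluation> %s | %d folds x %d repeats | test AUC %.3f +/- %.3f\n",
    paste(x$features, collapse = "+"),
    x$config$n_folds, x$config$n_repeats, x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Rank candidate combinations
#'
#' Orders candidates by a fitted combined score (when a `tos_model` is
#' given) or by a single measure column, descending; ties are broken by the
#' canonical combination id so the order is deterministic.
#'
#' @param candidates Scored combination tibble (from
#'   [score_combinations()]).
#' @param model Optional `tos_model`; when `NULL`, `measure` is used
#'   directly.
#' @param measure Column to rank by when no model is supplied.
#' @return `candidates` with `combined` (if a model was used) and `rank`,
#'   sorted best-first.
#' @export
rank_candidates <- function(candidates, model = NULL, measure = "tos") {
  candidates <- as_tibble(candidates)
  if (!"combination" %in% names(candidates)) {
    candidates$combination <- map_chr(candidates$drug_ids,
                                      \(v) paste(sort(v), collapse = "+"))
  }
  score <- if (!is.null(model)) {
    candidates$combined <- predict(model, candidates)
    # order on the linear predictor: the same ranking as the response but
    # immune to probability saturation under near-separation
    unname(predict(model$fit,
                   newdata = as_tibble(candidates)[model$features],
                   type = "link"))
  } else {
    candidates[[measure]]
  }
  out <- candidates[order(-score, candidates$combination), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties; two-sided p-value via the
#' t approximation (exact permutation below n = 10 when there are no
#' ties).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return One-row tibble `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Constant vector: rank correlation undefined.")
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman",
             exact = length(x) < 10 && !has_ties)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares the score distributions of two groups (e.g. TOS of beneficial
#' vs. detrimental combinations) with midranks for ties.
#'
#' @param a,b Non-empty numeric vectors.
#' @return One-row tibble `statistic` (Mann-Whitney W for `a`), `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("Both samples must be non-empty.")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Derive RECIST summary outcomes
#'
#' Adds the standard derived endpoints to a clinical outcome table:
#' overall response `OR = CR + PR` and confirmed clinical benefit
#' `CCB = CR + PR + SD` (left missing when `SD` is missing). All inputs are
#' percentages of patients.
#'
#' @param outcomes Tibble with numeric columns `CR`, `PR` and optionally
#'   `SD` (case-insensitive).
#' @return `outcomes` with columns `OR` and `CCB` added.
#' @export
#' @examples
#' derive_outcomes(tibble::tibble(CR = 10, PR = 20, SD = 15))
derive_outcomes <- function(outcomes) {
  outcomes <- as_tibble(outcomes)
  nm <- names(outcomes)
  pick <- function(key) {
    hit <- which(toupper(nm) == key)
    if (length(hit) == 0) NULL else outcomes[[hit[1]]]
  }
  cr <- pick("CR"); pr <- pick("PR"); sd_ <- pick("SD")
  if (is.null(cr) || is.null(pr)) abort("Columns CR and PR are required.")
  vals <- c(cr, pr, sd_)
  if (any(vals < 0, na.rm = TRUE)) abort("Negative percentages are not allowed.")
  outcomes$OR <- cr + pr
  outcomes$CCB <- if (is.null(sd_)) NA_real_ else cr + pr + sd_
  outcomes
}
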