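test_that("ROC AUC equals all-pairs enumeration with tie credit", {
  expect_equal(roc_auc(c(0.5, 0.9, 0.5, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  # label inversion complements the AUC
  s <- c(0.2, 0.8, 0.5, 0.6, 0.3)
  y <- c(0, 1, 0, 1, 1)
  expect_equal(roc_auc(s, y), 1 - roc_auc(s, 1 - y))
  expect_error(roc_auc(1:3, c(1, 1, 1)), "Both classes")

  set.seed(7)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    labels <- stats::rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("hand-rolled AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    scores <- stats::runif(80)
    labels <- stats::rbinom(80, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("the logistic combiner recovers signs and is invariant to duplication", {
  rows <- tibble::tibble(tos = c(rep(1, 10), rep(0, 10)),
                         label = c(rep(1, 10), rep(0, 10)))
  m <- suppressWarnings(fit_logistic(rows))  # separable: warning allowed
  expect_gt(tidy(m)$estimate[tidy(m)$term == "tos"], 0)
  p <- predict(m, tibble::tibble(tos = c(0.1, 0.5, 0.9)))
  expect_true(all(diff(p) > 0))            # monotone increasing in the feature
  expect_true(all(p > 0 & p < 1))

  noisy <- tibble::tibble(
    tos = c(0.8, 0.7, 0.35, 0.9, 0.2, 0.65, 0.1, 0.4),
    label = c(1, 1, 1, 1, 0, 0, 0, 0)
  )
  m1 <- fit_logistic(noisy)
  m2 <- fit_logistic(dplyr::bind_rows(noisy, noisy))
  expect_equal(stats::coef(m1$fit), stats::coef(m2$fit), tolerance = 1e-6)

  expect_error(fit_logistic(dplyr::mutate(noisy, label = 1)), "Both classes")
  expect_error(fit_logistic(dplyr::select(noisy, -label)), "label")
})

test_that("candidate ranking is descending with deterministic tie-breaks", {
  cand <- tibble::tibble(
    drug_ids = list(c("b", "a"), c("c", "a"), c("d", "a")),
    tos = c(0.5, 0.9, 0.5)
  )
  r <- rank_candidates(cand)
  expect_equal(r$combination, c("a+c", "a+b", "a+d"))  # ties by id order
  expect_equal(r$rank, 1:3)

  # a positive single-feature logistic model ranks exactly like the feature
  rows <- tibble::tibble(tos = stats::runif(40),
                         label = as.integer(stats::runif(40) < 0.5))
  rows$label[which.max(rows$tos)] <- 1L
  rows$label[which.min(rows$tos)] <- 0L
  m <- fit_logistic(rows)
  if (tidy(m)$estimate[2] > 0) {
    expect_equal(rank_candidates(cand, model = m)$combination,
                 rank_candidates(cand)$combination)
  }
})

test_that("cross-validation is seeded, sized and calibrated under the null", {
  set.seed(1)
  positives <- tibble::tibble(tos = stats::runif(20, 0.8, 1))
  resampler <- function(seed) {
    set.seed(seed)
    tibble::tibble(tos = stats::runif(40, 0, 0.2))
  }
  cfg <- run_config(n_folds = 5, n_repeats = 4, random_seed = 123)
  rep1 <- cross_validate(positives, resampler, config = cfg)
  expect_equal(nrow(rep1$folds), 20L)          # n_folds x n_repeats
  expect_equal(rep1$mean_auc, 1)               # perfectly separable
  rep2 <- cross_validate(positives, resampler, config = cfg)
  expect_equal(tidy(rep1), tidy(rep2))         # same seed, identical report
  g <- glance(rep1)
  expect_equal(g$n_folds, 5L)
  expect_equal(g$n_repeats, 4L)

  # label-permuted data: mean test AUC within 0.5 +/- 0.03 at 100 x 5 folds,
  # with a fresh permutation per repeat (as with fresh negatives per round)
  set.seed(2)
  all_rows <- tibble::tibble(tos = stats::runif(120),
                             label = rep(c(1L, 0L), c(20, 100)))
  permuted <- function(seed) {
    set.seed(seed + 1L)
    dplyr::mutate(all_rows, label = sample(.data$label))
  }
  null_cfg <- run_config(n_folds = 5, n_repeats = 100, random_seed = 99)
  null_rep <- cross_validate(
    function(seed) dplyr::filter(permuted(seed), .data$label == 1L)["tos"],
    function(seed) dplyr::filter(permuted(seed), .data$label == 0L)["tos"],
    config = null_cfg)
  expect_lt(abs(null_rep$mean_auc - 0.5), 0.03)
})

test_that("Spearman correlation matches hand-ranked examples", {
  r <- spearman_cor(1:6, c(2, 4, 6, 8, 10, 12))
  expect_equal(r$rho, 1)
  r2 <- spearman_cor(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r2$rho, -0.5)   # 1 - 6*6/(3*8)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  x <- stats::runif(15); y <- stats::runif(15)
  expect_equal(spearman_cor(x, y)$rho, -spearman_cor(x, -y)$rho)  # antisymmetry
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "Constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("Wilcoxon rank-sum behaves at the null, under separation, and symmetrically", {
  same <- c(1, 2, 3, 4, 5)
  expect_gt(wilcoxon_rank_sum(same, same)$p_value, 0.9)
  a <- 1:10; b <- 101:110
  w <- wilcoxon_rank_sum(a, b)
  expect_equal(w$statistic, 0)             # minimal Mann-Whitney statistic
  expect_equal(w$p_value, 2 / choose(20, 10))  # exact enumeration: 2 extreme tables
  expect_lt(w$p_value, 0.001)
  expect_equal(wilcoxon_rank_sum(b, a)$p_value, w$p_value)
  expect_error(wilcoxon_rank_sum(numeric(), a), "non-empty")
})

test_that("RECIST outcome arithmetic derives OR and CCB", {
  out <- derive_outcomes(tibble::tibble(CR = 10, PR = 20, SD = 15))
  expect_equal(out$OR, 30)
  expect_equal(out$CCB, 45)
  out2 <- derive_outcomes(tibble::tibble(cr = 10, pr = 20))  # case-insensitive
  expect_equal(out2$OR, 30)
  expect_true(is.na(out2$CCB))                 # SD missing -> CCB missing
  expect_error(derive_outcomes(tibble::tibble(CR = -1, PR = 2)), "Negative")
  expect_error(derive_outcomes(tibble::tibble(CR = 1)), "required")
})
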