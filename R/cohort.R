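#' Flag a pair with identical network targets
#'
#' Combinations whose components hit exactly the same target set are
#' "trivial": their TOS is 1 by construction, so they are excluded from
#' positive and negative statistics and characterized separately.
#'
#' @param targets_i,targets_j Character vectors of network-mapped targets.
#' @return `TRUE` iff the target sets are set-equal.
#' @export
flag_identical_targets <- function(targets_i, targets_j) {
  setequal(targets_i, targets_j)
}

#' Flag a structurally similar pair
#'
#' Pairs of structurally near-identical molecules (Tanimoto coefficient of
#' their extended fingerprints strictly above the cutoff, default 0.85) are
#' the second class of trivial combinations. Fingerprint computation is a
#' pluggable backend: the `tanimoto` argument accepts either a precomputed
#' value or a lookup table read by [read_tanimoto_table()]. If no value is
#' available the pair passes (cannot be excluded) with a warning.
#'
#' @param drug_i,drug_j Drug ids.
#' @param tanimoto A single numeric Tanimoto value, or a tibble
#'   (`drug_a`, `drug_b`, `tanimoto`), or `NULL`.
#' @param cutoff Strict exclusion threshold.
#' @return `TRUE` iff tanimoto > cutoff.
#' @export
flag_structurally_similar <- function(drug_i, drug_j, tanimoto = NULL,
                                      cutoff = 0.85) {
  value <- NA_real_
  if (is.numeric(tanimoto) && length(tanimoto) == 1) {
    value <- tanimoto
  } else if (is.data.frame(tanimoto)) {
    a <- min(drug_i, drug_j)
    b <- max(drug_i, drug_j)
    hit <- tanimoto$tanimoto[tanimoto$drug_a == a & tanimoto$drug_b == b]
    if (length(hit) > 0) value <- hit[1]
  }
  if (is.na(value)) {
    warn(sprintf("No Tanimoto value for pair %s/%s; pair not excluded.",
                 drug_i, drug_j))
    return(FALSE)
  }
  value > cutoff
}

#' Flag trivial pairs in a combination table
#'
#' Applies [flag_identical_targets()] and [flag_structurally_similar()] to
#' every pairwise combination.
#'
#' @param combinations Tibble with `drug_ids` list-column.
#' @param drugs Drug registry with `drug_id`, `targets`.
#' @param tanimoto Optional Tanimoto lookup tibble.
#' @param cutoff Tanimoto cutoff.
#' @return `combinations` with logical columns `identical_targets`,
#'   `structurally_similar`, `trivial`.
#' @export
flag_trivial <- function(combinations, drugs, tanimoto = NULL, cutoff = 0.85) {
  tset <- setNames(drugs$targets, drugs$drug_id)
  combinations <- as_tibble(combinations)
  combinations$identical_targets <- map_lgl(combinations$drug_ids, function(ids) {
    any(map_lgl(utils::combn(ids, 2, simplify = FALSE),
                \(p) flag_identical_targets(tset[[p[1]]], tset[[p[2]]])))
  })
  combinations$structurally_similar <- map_lgl(combinations$drug_ids, function(ids) {
    if (is.null(tanimoto)) return(FALSE)
    any(map_lgl(utils::combn(ids, 2, simplify = FALSE),
                \(p) flag_structurally_similar(p[1], p[2], tanimoto, cutoff)))
  })
  combinations$trivial <- combinations$identical_targets |
    combinations$structurally_similar
  combinations
}

#' Generate random drugs from the druggable target pool
#'
#' A random drug is a set of randomly selected targets — drawn from the
#' pool of proteins targeted by at least one known drug — annotated with one
#' randomly selected ATC code. For each requested cardinality, `per_count`
#' random drugs are generated (targets sampled without replacement within a
#' drug), so the target-size spectrum of the random cohort mirrors the
#' requested spectrum exactly.
#'
#' @param target_pool Character vector: the union of known-drug targets.
#' @param cardinalities Integer vector of target-set sizes; one batch of
#'   `per_count` drugs is generated per element (pass the observed sizes of
#'   the known drugs, with duplicates, to copy their spectrum).
#' @param per_count Random drugs per cardinality entry (default 25).
#' @param atc_pool Character vector of ATC codes to draw the annotation
#'   from; may be empty.
#' @param seed Integer seed.
#' @param prefix Id prefix for the synthetic drugs.
#' @return Drug registry tibble (`drug_id`, `targets`, `n_targets`,
#'   `atc_codes`, `go_terms`).
#' @export
make_random_drugs <- function(target_pool, cardinalities, per_count = 25L,
                              atc_pool = character(), seed = 1L,
                              prefix = "RND") {
  target_pool <- unique(target_pool)
  cardinalities <- as.integer(cardinalities)
  if (any(cardinalities > length(target_pool))) {
    abort("Requested cardinality exceeds the target pool size.")
  }
  if (any(cardinalities < 1)) abort("Cardinalities must be positive.")
  set.seed(seed)
  sizes <- rep(cardinalities, each = per_count)
  targets <- map(sizes, \(k) sort(sample(target_pool, k)))
  atc <- if (length(atc_pool) > 0) {
    map(seq_along(sizes), \(i) sample(atc_pool, 1L))
  } else {
    rep(list(character()), length(sizes))
  }
  tibble(
    drug_id = sprintf("%s%04d", prefix, seq_along(sizes)),
    targets = targets,
    n_targets = sizes,
    atc_codes = atc,
    go_terms = rep(list(character()), length(sizes))
  )
}

#' All-pairs candidate generator (FDA-pair strategy)
#'
#' Enumerates every unordered pair of registry drugs and removes pairs that
#' appear in any supplied labeled list — the alternative negative-set
#' strategy built from approved drugs rather than random ones.
#'
#' @param drugs Drug registry tibble.
#' @param exclude Optional combination tibble(s) whose pairs are removed.
#' @return Combination tibble with `drug_ids`, `combination`, `label`
#'   (`"fda_pair"`), `source`.
#' @export
all_pairs <- function(drugs, exclude = NULL) {
  ids <- sort(drugs$drug_id)
  if (length(ids) < 2) abort("Need at least two drugs.")
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  out <- tibble(
    drug_ids = pairs,
    combination = map_chr(pairs, paste, collapse = "+"),
    label = "fda_pair",
    source = "all_pairs"
  )
  if (!is.null(exclude)) {
    if (is.data.frame(exclude)) exclude <- list(exclude)
    known <- unlist(map(exclude, \(x)
      map_chr(x$drug_ids, \(v) paste(sort(v), collapse = "+"))))
    out <- filter(out, !.data$combination %in% known)
  }
  out
}

#' Draw a random-negative combination set
#'
#' Samples `ratio` negatives per positive, uniformly without replacement
#' from a candidate pool, excluding trivial pairs and any combination that
#' appears in a positive/detrimental list. Each repeat of the evaluation
#' harness calls this with a fresh seed to get a new negative set.
#'
#' @param positives Combination tibble of positive records.
#' @param pool Combination tibble of candidate negatives (e.g. random-drug
#'   pairs, or [all_pairs()] output), optionally carrying a `trivial`
#'   column from [flag_trivial()].
#' @param ratio Negatives per positive (default 5).
#' @param seed Integer seed.
#' @return Combination tibble with `label = "random_negative"`.
#' @export
build_negative_set <- function(positives, pool, ratio = 5L, seed = 1L) {
  pool <- as_tibble(pool)
  if (!"combination" %in% names(pool)) {
    pool$combination <- map_chr(pool$drug_ids, \(v) paste(sort(v), collapse = "+"))
  }
  known <- map_chr(positives$drug_ids, \(v) paste(sort(v), collapse = "+"))
  pool <- filter(pool, !.data$combination %in% known)
  if ("trivial" %in% names(pool)) pool <- filter(pool, !.data$trivial)
  n_needed <- as.integer(ratio) * nrow(positives)
  if (nrow(pool) < n_needed) {
    abort(sprintf("Negative pool too small: need %d, have %d.",
                  n_needed, nrow(pool)))
  }
  set.seed(seed)
  picked <- pool[sample.int(nrow(pool), n_needed), , drop = FALSE]
  picked$label <- "random_negative"
  if (!"source" %in% names(picked)) picked$source <- "random"
  arrange(picked, .data$combination)
}
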