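#' Binary GO-term vectors for a drug cohort
#'
#' Builds one binary vector per drug over the cohort's shared GO-term
#' universe: entry i is 1 if term i is annotated to (any of) the drug's
#' targets. Pooling over all targets means multi-target drugs simply
#' accumulate the terms of every target.
#'
#' @param drugs Drug registry tibble with `drug_id` and `go_terms`
#'   list-column (see [build_drugs()]).
#' @param universe Optional character vector fixing the term universe;
#'   defaults to the union of all terms in the cohort.
#' @return Binary integer matrix, rows named by drug, columns by GO term.
#' @export
go_vectors <- function(drugs, universe = NULL) {
  if (is.null(universe)) {
    universe <- sort(unique(unlist(drugs$go_terms, use.names = FALSE)))
  }
  m <- matrix(0L, nrow = nrow(drugs), ncol = length(universe),
              dimnames = list(drugs$drug_id, universe))
  for (r in seq_len(nrow(drugs))) {
    m[r, intersect(drugs$go_terms[[r]], universe)] <- 1L
  }
  m
}

#' GO cosine similarity between two drugs
#'
#' Cosine of two binary GO vectors on a shared universe: 0 if no terms are
#' shared, 1.0 if the annotated term sets are identical. Padding the
#' universe with terms absent from both drugs does not change the value.
#'
#' @param gi,gj Binary numeric vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' go_similarity(c(1, 1, 0), c(0, 1, 1))  # 0.5
go_similarity <- function(gi, gj) {
  stopifnot(length(gi) == length(gj))
  ni <- sqrt(sum(gi^2))
  nj <- sqrt(sum(gj^2))
  if (ni == 0 || nj == 0) {
    warn("GO vector with no annotated terms; similarity defined as 0.")
    return(0)
  }
  sum(gi * gj) / (ni * nj)
}

atc_prefixes <- function(code) {
  # ATC levels occupy characters 1, 1-3, 1-4, 1-5, 1-7
  vapply(c(1L, 3L, 4L, 5L, 7L), \(k) substr(code, 1L, k), character(1))
}

#' ATC code forest with information content
#'
#' Treats the 5-level ATC classification as a forest of trees rooted at the
#' 14 anatomical main groups. The information content of a code level c is
#' `IC(c) = -log p(c)`, with `p(c)` estimated as the fraction of all
#' drug-code annotations in the corpus whose code passes through c
#' (multiplicities counted). IC is 0 for a level carried by every
#' annotation and grows toward the leaves.
#'
#' @param drugs Either a drug registry tibble with `drug_id` and `atc_codes`
#'   list-column, or a character vector of 7-character ATC codes.
#' @return An `atc_forest` object: `codes` (named list per drug, when drug
#'   ids were available), `ic` (named numeric over all observed level
#'   prefixes), `n_annotations`.
#' @export
atc_forest <- function(drugs) {
  if (is.character(drugs)) {
    codes <- as.list(drugs)
    names(codes) <- paste0("code", seq_along(drugs))
  } else {
    stopifnot(all(c("drug_id", "atc_codes") %in% names(drugs)))
    codes <- setNames(drugs$atc_codes, drugs$drug_id)
  }
  flat <- unlist(codes, use.names = FALSE)
  if (length(flat) == 0) abort("No ATC annotations in the corpus.")
  prefixes <- unlist(lapply(flat, atc_prefixes), use.names = FALSE)
  counts <- table(prefixes)
  ic <- -log(as.numeric(counts) / length(flat))
  names(ic) <- names(counts)
  structure(
    list(codes = codes, ic = ic, n_annotations = length(flat)),
    class = "atc_forest"
  )
}

#' Information content of an ATC code level
#'
#' @param forest An [atc_forest()].
#' @param prefix A level prefix present in the corpus (1, 3, 4, 5 or 7
#'   characters).
#' @return `-log p(prefix)`, a non-negative number.
#' @export
#' @examples
#' f <- atc_forest(c("L01XC03", "L01XA01", "N02BA01", "N02BE01"))
#' information_content(f, "L01X")  # log 2
information_content <- function(forest, prefix) {
  stopifnot(inherits(forest, "atc_forest"))
  if (!prefix %in% names(forest$ic)) {
    abort(sprintf("ATC level '%s' not present in the corpus.", prefix))
  }
  unname(forest$ic[prefix])
}

mica_ic <- function(forest, code_i, code_j) {
  shared <- atc_prefixes(code_i) == atc_prefixes(code_j)
  if (!any(shared)) return(NA_real_)
  deepest <- atc_prefixes(code_i)[max(which(shared))]
  unname(forest$ic[deepest])
}

#' ATC Resnik similarity between two drugs
#'
#' For each pair of codes across the two drugs, the Resnik similarity is
#' the information content of the most informative common ancestor (the
#' longest shared ATC prefix), normalized by the IC of the more specific of
#' the two codes so that the similarity is 1.0 when the drugs share an
#' identical full 7-character code and 0 when they share no prefix at any
#' level. The drug-level similarity is the maximum over all code pairs.
#'
#' @param forest An [atc_forest()] built on the cohort.
#' @param drug_i,drug_j Drug ids present in the forest, or character vectors
#'   of ATC codes.
#' @return Similarity in \[0, 1\].
#' @export
atc_similarity <- function(forest, drug_i, drug_j) {
  stopifnot(inherits(forest, "atc_forest"))
  codes_of <- function(d) {
    if (length(d) == 1 && d %in% names(forest$codes)) forest$codes[[d]] else d
  }
  ci <- codes_of(drug_i)
  cj <- codes_of(drug_j)
  if (length(ci) == 0 || length(cj) == 0) {
    warn("Drug with no ATC codes; similarity defined as 0.")
    return(0)
  }
  best <- 0
  for (a in ci) {
    for (b in cj) {
      ic_anc <- mica_ic(forest, a, b)
      if (is.na(ic_anc)) next
      denom <- max(information_content(forest, a), information_content(forest, b))
      sim <- if (denom == 0) 1 else ic_anc / denom
      best <- max(best, sim)
    }
  }
  best
}
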