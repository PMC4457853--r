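#' Pairwise Target Overlap Score
#'
#' The TOS of two drugs is the Jaccard coefficient of their perturbation
#' neighborhoods: the number of jointly perturbed nodes divided by the
#' number of all perturbed nodes. It is 1.00 for drugs whose neighborhoods
#' coincide and 0.00 for drugs that do not significantly perturb any node in
#' common. When both neighborhoods are empty the score is defined as 0 (no
#' evidence of joint perturbation) and a warning is raised.
#'
#' @param nb_i,nb_j Character vectors: the two perturbation neighborhoods,
#'   computed on the same network.
#' @return One-row tibble `tos`, `intersection_size`, `union_size`.
#' @export
#' @examples
#' tos_pair(c("a", "b", "c"), c("b", "c", "d"))$tos  # 0.5
tos_pair <- function(nb_i, nb_j) {
  nb_i <- unique(nb_i)
  nb_j <- unique(nb_j)
  inter <- length(intersect(nb_i, nb_j))
  uni <- length(union(nb_i, nb_j))
  if (uni == 0) {
    warn("Both neighborhoods are empty; TOS defined as 0.")
    return(tibble(tos = 0, intersection_size = 0L, union_size = 0L))
  }
  tibble(tos = inter / uni, intersection_size = inter, union_size = uni)
}

#' Generalized Target Overlap Score for multi-drug regimens
#'
#' For M >= 2 drugs, the numerator counts the nodes significantly perturbed
#' by at least two of the drugs (the union of all pairwise neighborhood
#' intersections) and the denominator is the size of the whole affected
#' subnetwork (the union of all neighborhoods). With M = 2 this reduces to
#' [tos_pair()].
#'
#' @param neighborhoods List of M >= 2 character vectors.
#' @return One-row tibble `tos`, `intersection_size` (nodes hit by >= 2
#'   drugs), `union_size`.
#' @export
#' @examples
#' tos_general(list(c("1", "2"), c("2", "3"), c("3", "4")))$tos  # 0.5
tos_general <- function(neighborhoods) {
  M <- length(neighborhoods)
  if (M < 2) abort("At least two neighborhoods are required.")
  neighborhoods <- map(neighborhoods, unique)
  all_nodes <- unlist(neighborhoods, use.names = FALSE)
  uni <- length(unique(all_nodes))
  if (uni == 0) {
    warn("All neighborhoods are empty; TOS defined as 0.")
    return(tibble(tos = 0, intersection_size = 0L, union_size = 0L))
  }
  multiplicity <- table(all_nodes)
  inter <- sum(multiplicity >= 2)
  tibble(tos = inter / uni, intersection_size = as.integer(inter),
         union_size = uni)
}

#' Score a list of drug combinations
#'
#' Computes the (generalized) TOS for every combination and, when the drug
#' registry carries annotations, the GO cosine similarity and the
#' ATC Resnik similarity. For regimens of more than two drugs the auxiliary
#' similarities are the minimum over component pairs (the weakest link);
#' pairwise combinations get the plain pairwise values.
#'
#' @param combinations Tibble with a `drug_ids` list-column (and optional
#'   `combination`, `label`, `source` columns, which are carried through).
#' @param profiles Profile table from [perturbation_profiles()].
#' @param drugs Optional drug registry for GO/ATC annotation similarities.
#' @param go_universe,atc_forest Optional precomputed [go_vectors()] matrix
#'   and [atc_forest()]; built from `drugs` when omitted.
#' @return The `combinations` tibble with added numeric columns `tos`,
#'   `intersection_size`, `union_size` and, if annotations are available,
#'   `go` and `atc`.
#' @export
score_combinations <- function(combinations, profiles, drugs = NULL,
                               go_universe = NULL, atc_forest = NULL) {
  combinations <- as_tibble(combinations)
  if (!"drug_ids" %in% names(combinations)) {
    abort("Combinations need a 'drug_ids' list-column.")
  }
  nb <- setNames(profiles$neighborhood, profiles$drug_id)
  missing_ids <- setdiff(unique(unlist(combinations$drug_ids)), names(nb))
  if (length(missing_ids) > 0) {
    abort(paste0("No profile for drug(s): ", paste(missing_ids, collapse = ", ")))
  }

  res <- map(combinations$drug_ids, function(ids) {
    sets <- nb[ids]
    if (length(ids) == 2) tos_pair(sets[[1]], sets[[2]]) else tos_general(sets)
  }) |> bind_rows()

  out <- combinations
  if (!"combination" %in% names(out)) {
    out$combination <- map_chr(out$drug_ids, \(v) paste(sort(v), collapse = "+"))
  }
  out$tos <- res$tos
  out$intersection_size <- res$intersection_size
  out$union_size <- res$union_size

  if (!is.null(drugs)) {
    if (is.null(go_universe)) go_universe <- go_vectors(drugs)
    if (is.null(atc_forest)) atc_forest <- atc_forest(drugs)
    out$go <- map_dbl(out$drug_ids, \(ids)
      min(pair_values(ids, \(a, b) go_similarity(go_universe[a, ], go_universe[b, ]))))
    out$atc <- map_dbl(out$drug_ids, \(ids)
      min(pair_values(ids, \(a, b) atc_similarity(atc_forest, a, b))))
  }
  out
}

pair_values <- function(ids, f) {
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  map_dbl(pairs, \(p) f(p[1], p[2]))
}
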