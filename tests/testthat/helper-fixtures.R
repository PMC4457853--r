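# Shared fixtures: tiny deterministic networks and an independent
# eigendecomposition oracle for the matrix exponential.

two_node_network <- function(w = 1) {
  as_interaction_network(
    tibble::tibble(node_a = "P1", node_b = "P2", score = w))
}

path3_network <- function() {
  # P1 - P2 - P3 with unit weights
  as_interaction_network(tibble::tibble(
    node_a = c("P1", "P2"), node_b = c("P2", "P3"), score = c(1, 1)))
}

complete_network <- function(n, w = 0.5) {
  ids <- sprintf("P%d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  as_interaction_network(tibble::tibble(
    node_a = pairs[, 1], node_b = pairs[, 2], score = w))
}

# Erdos-Renyi-style random edge table (connected not guaranteed; fine for
# kernel algebra tests)
random_edges <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("V%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  tibble::tibble(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
                 score = stats::runif(sum(keep), 0.2, 1))
}

# independent oracle: matrix exponential through a symmetric
# eigendecomposition, never through expm()
eigen_expm <- function(M) {
  e <- eigen(as.matrix(M), symmetric = TRUE)
  e$vectors %*% diag(exp(e$values), nrow = nrow(M)) %*% t(e$vectors)
}

kernel_oracle <- function(network, mu, alpha) {
  L <- as.matrix(regularized_laplacian(network, mu))
  eigen_expm(-alpha * L)
}

# brute-force AUC: all-pairs enumeration with half credit for ties
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force generalized overlap: nodes covered by >= 2 sets over the union
tos_general_bruteforce <- function(sets) {
  sets <- lapply(sets, unique)
  uni <- unique(unlist(sets))
  if (length(uni) == 0) return(0)
  hits <- vapply(uni, function(v)
    sum(vapply(sets, function(s) v %in% s, logical(1))), numeric(1))
  sum(hits >= 2) / length(uni)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
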