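#' Regularized graph Laplacian
#'
#' Computes `L_mu = mu * G - A`, where `A` is the symmetric weighted
#' adjacency matrix of the network and `G` the diagonal matrix of weighted
#' degrees `g_i = sum_j A_ij`. With `mu = 1` and unit weights this is the
#' classical combinatorial Laplacian; with `mu < 1` the matrix may be
#' indefinite, which is expected and harmless for the diffusion kernel.
#'
#' @param network An `interaction_network`.
#' @param mu Positive regularization parameter.
#' @return A sparse symmetric matrix with the network's node names.
#' @export
#' @examples
#' net <- as_interaction_network(
#'   tibble::tibble(node_a = "P1", node_b = "P2", score = 1))
#' regularized_laplacian(net, mu = 0.1)
regularized_laplacian <- function(network, mu) {
  stopifnot(inherits(network, "interaction_network"), mu > 0)
  A <- network$A
  if (!Matrix::isSymmetric(A)) abort("Adjacency matrix must be symmetric.")
  L <- Matrix::Diagonal(x = mu * network$degree) - A
  dimnames(L) <- dimnames(A)
  L
}

#' Regularized Laplacian exponential diffusion kernel
#'
#' Computes `K = expm(-alpha * L_mu)`, the graph kernel that propagates a
#' perturbation placed on a drug's targets across the network. At
#' `alpha = 0` the kernel is the identity (no propagation). Networks up to
#' `dense_cutoff` nodes are exponentiated densely; larger networks keep only
#' `L_mu` and evaluate the exponential's action on each perturbation vector
#' on demand, with the same accuracy per applied vector.
#'
#' @param network An `interaction_network`.
#' @param mu Positive regularization parameter (default 0.1).
#' @param alpha Non-negative diffusion strength (default 0.005).
#' @param dense_cutoff Node count above which the kernel matrix is not
#'   materialized.
#' @return A `diffusion_kernel` object (`nodes`, `mu`, `alpha`, `L`, and `K`
#'   when dense).
#' @export
diffusion_kernel <- function(network, mu = 0.1, alpha = 0.005,
                             dense_cutoff = 500L) {
  stopifnot(inherits(network, "interaction_network"))
  if (alpha < 0) abort("alpha must be non-negative.")
  L <- regularized_laplacian(network, mu)
  n <- length(network$nodes)
  K <- NULL
  if (n <= dense_cutoff) {
    if (alpha == 0) {
      K <- diag(n)
    } else {
      K <- as.matrix(Matrix::expm(-alpha * L))
    }
    dimnames(K) <- list(network$nodes, network$nodes)
  }
  structure(
    list(nodes = network$nodes, mu = mu, alpha = alpha, L = L, K = K),
    class = "diffusion_kernel"
  )
}

#' @export
print.diffusion_kernel <- function(x, ...) {
  cat(sprintf("<diffusion_kernel> %d nodes, mu = %g, alpha = %g (%s)\n",
              length(x$nodes), x$mu, x$alpha,
              if (is.null(x$K)) "action-on-vector" else "dense"))
  invisible(x)
}

# e^{-alpha L} %*% V by scaling + truncated Taylor; used when K is not dense.
expm_action <- function(L, alpha, V) {
  if (alpha == 0) return(as.matrix(V))
  s <- max(1L, ceiling(alpha * Matrix::norm(L, "1")))
  B <- (-alpha / s) * L
  W <- as.matrix(V)
  for (step in seq_len(s)) {
    term <- W
    acc <- W
    for (k in 1:60) {
      term <- as.matrix(B %*% term) / k
      acc <- acc + term
      if (max(abs(term)) < 1e-16 * max(abs(acc))) break
    }
    W <- acc
  }
  W
}

# K %*% V for a column matrix of indicator vectors
kernel_apply <- function(kernel, V) {
  if (!is.null(kernel$K)) {
    out <- kernel$K %*% as.matrix(V)
  } else {
    out <- expm_action(kernel$L, kernel$alpha, V)
  }
  out <- as.matrix(out)
  rownames(out) <- kernel$nodes
  out
}

target_indicator <- function(kernel, targets) {
  idx <- match(targets, kernel$nodes)
  if (anyNA(idx)) {
    abort(paste0("Targets not in network: ",
                 paste(targets[is.na(idx)], collapse = ", ")))
  }
  p0 <- numeric(length(kernel$nodes))
  p0[idx] <- 1
  p0
}

#' Perturbation score vector of a drug
#'
#' Places a unit perturbation on each target node (binary indicator `p0`)
#' and propagates it with the diffusion kernel: `S = K p0`. The j-th entry
#' measures how strongly the drug's perturbation reaches protein j.
#'
#' @param kernel A [diffusion_kernel()].
#' @param targets Character vector of target node ids (non-empty, all in the
#'   network).
#' @return Tibble with columns `node`, `score` in network node order.
#' @export
perturbation_scores <- function(kernel, targets) {
  if (length(targets) == 0) abort("Target set is empty; drug should have been filtered.")
  S <- kernel_apply(kernel, target_indicator(kernel, targets))[, 1]
  tibble(node = kernel$nodes, score = unname(S))
}

#' Monte-Carlo node p-values for a drug's perturbation
#'
#' Estimates, for every node, how surprising its observed perturbation score
#' is under random drugs of the same target-set size. Each of
#' `n_permutations` replicates draws a random target set (uniformly over
#' network nodes, or from a degree-matched pool) and re-runs the diffusion;
#' the one-sided upper-tail p-value uses the add-one estimator
#' `p_j = (1 + #\{S_j^rep >= S_j^obs\}) / (n_permutations + 1)`, which can
#' never be exactly zero.
#'
#' @param kernel A [diffusion_kernel()].
#' @param targets Character vector of target nodes.
#' @param n_permutations Number of Monte-Carlo replicates.
#' @param sampling `"uniform"` (default) or `"degree_matched"` (replicate
#'   targets drawn from decile-of-degree bins matching the observed
#'   targets).
#' @param seed Integer seed; identical inputs and seed give identical
#'   p-values.
#' @param degree_bins Number of quantile bins for degree-matched sampling.
#' @return Tibble `node`, `score`, `p_value`.
#' @export
monte_carlo_pvalues <- function(kernel, targets, n_permutations = 10000L,
                                sampling = c("uniform", "degree_matched"),
                                seed = 1L, degree_bins = 10L) {
  sampling <- match.arg(sampling)
  n <- length(kernel$nodes)
  m <- length(targets)
  if (m == 0) abort("Target set is empty.")
  if (m > n) abort("More targets than network nodes.")
  obs <- perturbation_scores(kernel, targets)

  set.seed(seed)
  R <- as.integer(n_permutations)
  if (sampling == "uniform") {
    draw_idx <- replicate(R, sample.int(n, m), simplify = FALSE)
  } else {
    # weighted degree recovered from L: diag(L) = mu * g
    deg <- Matrix::diag(kernel$L) / kernel$mu
    brks <- unique(quantile(deg, probs = seq(0, 1, length.out = degree_bins + 1)))
    bin <- cut(deg, breaks = brks, include.lowest = TRUE, labels = FALSE)
    pool <- split(seq_len(n), bin)
    tbin <- bin[match(targets, kernel$nodes)]
    need <- table(tbin)
    short <- names(need)[map_int(names(need), \(b) length(pool[[b]])) < as.integer(need)]
    if (length(short) > 0) {
      abort("Degree-matched pool too small for the requested target cardinality.")
    }
    draw_idx <- replicate(R, {
      unlist(lapply(names(need), \(b) {
        p <- pool[[b]]
        p[sample.int(length(p), need[[b]])]
      }), use.names = FALSE)
    }, simplify = FALSE)
  }

  P0 <- Matrix::sparseMatrix(
    i = unlist(draw_idx, use.names = FALSE),
    j = rep(seq_len(R), each = m),
    x = 1, dims = c(n, R)
  )
  S_null <- kernel_apply(kernel, P0)
  # scores equal up to float jitter count as exceedances, so exchangeable
  # nodes (e.g. on a vertex-transitive graph) get identical p-values
  thr <- obs$score - (1e-9 * abs(obs$score) + 1e-12)
  exceed <- Matrix::rowSums(S_null >= thr)
  mutate(obs, p_value = (1 + exceed) / (R + 1))
}

#' Perturbation profile of a drug
#'
#' Runs [perturbation_scores()] and [monte_carlo_pvalues()] and marks the
#' perturbation neighborhood: the nodes with `p_value < p_threshold`
#' (strict). Drug targets receive no special treatment — they belong to the
#' neighborhood only if their own p-value clears the threshold.
#'
#' @inheritParams monte_carlo_pvalues
#' @param p_threshold Significance level in (0, 1).
#' @param drug_id Optional identifier stored on the result.
#' @return A tibble of class `perturbation_profile` with columns `node`,
#'   `score`, `p_value`, `in_neighborhood`.
#' @export
perturbation_profile <- function(kernel, targets, n_permutations = 10000L,
                                 p_threshold = 0.05,
                                 sampling = c("uniform", "degree_matched"),
                                 seed = 1L, drug_id = NULL) {
  if (p_threshold <= 0 || p_threshold >= 1) abort("p_threshold must be in (0, 1).")
  prof <- monte_carlo_pvalues(kernel, targets, n_permutations = n_permutations,
                              sampling = match.arg(sampling), seed = seed) |>
    mutate(in_neighborhood = .data$p_value < p_threshold)
  class(prof) <- c("perturbation_profile", class(prof))
  attr(prof, "drug_id") <- drug_id
  attr(prof, "targets") <- sort(targets)
  prof
}

#' Extract the perturbation neighborhood
#'
#' @param profile A [perturbation_profile()] (or any tibble with `node` and
#'   `p_value`).
#' @param p_threshold Significance level in (0, 1); membership is strict
#'   (`p < threshold`), so a p-value exactly at the threshold is excluded.
#' @return Character vector of node ids (possibly empty), sorted.
#' @export
neighborhood <- function(profile, p_threshold = 0.05) {
  if (p_threshold <= 0 || p_threshold >= 1) abort("p_threshold must be in (0, 1).")
  sort(profile$node[profile$p_value < p_threshold])
}

#' Perturbation profiles for a drug registry
#'
#' Computes one perturbation neighborhood per drug. All drugs share the same
#' Monte-Carlo seed, so two drugs with identical target sets get identical
#' replicate draws and hence identical neighborhoods.
#'
#' @param drugs Drug registry tibble (see [build_drugs()]) with `drug_id`
#'   and `targets` columns.
#' @param kernel A [diffusion_kernel()].
#' @param config A [run_config()] supplying `n_permutations`, `p_threshold`
#'   and `random_seed`.
#' @param sampling Null-model sampling scheme, see [monte_carlo_pvalues()].
#' @return Tibble `drug_id`, `n_targets`, `neighborhood` (list-column of
#'   node-id vectors), `profile` (list-column of profile tibbles).
#' @export
perturbation_profiles <- function(drugs, kernel, config = run_config(),
                                  sampling = "uniform") {
  profs <- map2(drugs$drug_id, drugs$targets, function(id, ts) {
    perturbation_profile(kernel, ts,
                         n_permutations = config$n_permutations,
                         p_threshold = config$p_threshold,
                         sampling = sampling,
                         seed = config$random_seed, drug_id = id)
  })
  tibble(
    drug_id = drugs$drug_id,
    n_targets = lengths(drugs$targets),
    neighborhood = map(profs, \(p) p$node[p$in_neighborhood]),
    profile = profs
  )
}

#' Write a perturbation profile as tab-separated text
#'
#' Columns: node, score, p_value, in_neighborhood.
#'
#' @param profile A [perturbation_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path, progress = FALSE)
  invisible(path)
}
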