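#' Run configuration
#'
#' Collects the tunable parameters of the TOS pipeline in one validated list.
#' Defaults are the study conditions used throughout the package: diffusion
#' kernel regularization `mu = 0.1` and diffusion strength `alpha = 0.005`,
#' 10,000 Monte-Carlo permutations with significance threshold `p < 0.05`,
#' promiscuity cutoff of 45 targets, Tanimoto cutoff 0.85 for structurally
#' trivial pairs, a 5:1 negative:positive ratio, and 5-fold cross-validation
#' repeated 100 times.
#'
#' @param mu Regularization of the graph Laplacian (`L_mu = mu * G - A`);
#'   must be positive.
#' @param alpha Diffusion strength in the kernel `K = expm(-alpha * L_mu)`;
#'   must be non-negative.
#' @param n_permutations Number of Monte-Carlo replicates for node p-values.
#' @param p_threshold Significance level defining the perturbation
#'   neighborhood (strict `<`), in (0, 1).
#' @param max_targets Drugs with more than this many targets are excluded
#'   (filters promiscuous pseudo-drugs such as ions and cofactors).
#' @param tanimoto_cutoff Pairs with Tanimoto similarity strictly above this
#'   are flagged as structurally trivial.
#' @param neg_pos_ratio Number of random-negative combinations drawn per
#'   positive in evaluation.
#' @param n_folds Cross-validation folds.
#' @param n_repeats Cross-validation repeats (fresh negatives per repeat).
#' @param random_seed Master seed for all stochastic steps.
#'
#' @return A named list of class `netos_config`.
#' @export
#' @examples
#' cfg <- run_config(n_permutations = 1000)
#' cfg$mu
run_config <- function(mu = 0.1,
                       alpha = 0.005,
                       n_permutations = 10000L,
                       p_threshold = 0.05,
                       max_targets = 45L,
                       tanimoto_cutoff = 0.85,
                       neg_pos_ratio = 5L,
                       n_folds = 5L,
                       n_repeats = 100L,
                       random_seed = 1L) {
  stopifnot(
    is.numeric(mu), length(mu) == 1L, mu > 0,
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
    n_permutations >= 1L,
    is.numeric(p_threshold), p_threshold > 0, p_threshold < 1,
    max_targets >= 1L, tanimoto_cutoff >= 0,
    neg_pos_ratio >= 1L, n_folds >= 2L, n_repeats >= 1L
  )
  structure(
    list(
      mu = mu, alpha = alpha,
      n_permutations = as.integer(n_permutations),
      p_threshold = p_threshold,
      max_targets = as.integer(max_targets),
      tanimoto_cutoff = tanimoto_cutoff,
      neg_pos_ratio = as.integer(neg_pos_ratio),
      n_folds = as.integer(n_folds),
      n_repeats = as.integer(n_repeats),
      random_seed = as.integer(random_seed)
    ),
    class = "netos_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file is a single YAML document whose keys mirror the arguments of
#' [run_config()]. Keys given in `...` override file values (mirroring
#' CLI-flag-over-file precedence).
#'
#' @param path Path to a YAML file.
#' @param ... Named overrides passed to [run_config()].
#' @return A `netos_config` list.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown configuration keys: ", paste(bad, collapse = ", ")))
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' @export
print.netos_config <- function(x, ...) {
  cat("<netos_config>\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# filter-step logging goes to stderr so stdout stays clean for piped output
log_filter <- function(step, n_removed, n_kept) {
  inform(sprintf("[netos] %s: removed %d, kept %d", step, n_removed, n_kept),
         class = "netos_filter_log")
}
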