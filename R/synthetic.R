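#' Specification of a synthetic study
#'
#' Parameters of the planted-partition generator that stands in for the
#' protein-interaction network, drug-target, annotation and combination
#' data of a real study. Positive drug pairs share a network module with
#' probability `overlap_strength`; negatives pair drugs independently, so
#' at strength 0 positives and negatives are statistically identical.
#'
#' @param n_nodes Total network nodes.
#' @param n_modules Number of planted modules.
#' @param module_size Nodes per module (`n_modules * module_size <=
#'   n_nodes`; leftover nodes are unassigned background).
#' @param p_in,p_out Edge probabilities within / between modules
#'   (`p_in > p_out`).
#' @param weight_range Interval in (0, 1\] for uniform edge confidence
#'   scores.
#' @param n_drugs Number of known drugs.
#' @param targets_per_drug Length-2 integer range of targets per drug.
#' @param overlap_strength Probability in \[0, 1\] that a positive pair is
#'   drawn from one module.
#' @param seed Integer seed.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes = 300L, n_modules = 15L, module_size = 20L,
                           p_in = 0.35, p_out = 0.01,
                           weight_range = c(0.3, 0.9),
                           n_drugs = 40L, targets_per_drug = c(3L, 6L),
                           overlap_strength = 0.9, seed = 1L) {
  stopifnot(
    n_nodes >= 2, n_modules >= 1, module_size >= 2,
    n_modules * module_size <= n_nodes,
    p_in > p_out, p_in <= 1, p_out >= 0,
    length(weight_range) == 2, weight_range[1] > 0, weight_range[2] <= 1,
    weight_range[1] <= weight_range[2],
    n_drugs >= 2, length(targets_per_drug) == 2,
    targets_per_drug[1] >= 1, targets_per_drug[2] >= targets_per_drug[1],
    overlap_strength >= 0, overlap_strength <= 1
  )
  if (targets_per_drug[2] > module_size) {
    abort("targets_per_drug may not exceed module_size.")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), n_modules = as.integer(n_modules),
         module_size = as.integer(module_size), p_in = p_in, p_out = p_out,
         weight_range = weight_range, n_drugs = as.integer(n_drugs),
         targets_per_drug = as.integer(targets_per_drug),
         overlap_strength = overlap_strength, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

node_ids <- function(n) sprintf("N%04d", seq_len(n))

module_assignment <- function(spec) {
  # first module_size*n_modules nodes belong to modules, the rest to background 0
  mods <- rep(0L, spec$n_nodes)
  mods[seq_len(spec$n_modules * spec$module_size)] <-
    rep(seq_len(spec$n_modules), each = spec$module_size)
  setNames(mods, node_ids(spec$n_nodes))
}

#' Generate a planted-partition interaction network
#'
#' Nodes are partitioned into modules; node pairs inside one module are
#' connected with probability `p_in`, all other pairs with `p_out`, and
#' edge confidences are uniform on `weight_range`. Draws are re-sampled
#' (up to 100 attempts) until the network is connected, so diffusion can
#' reach every node. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return An `interaction_network`; the module assignment is attached as
#'   attribute `"modules"` (named integer vector, 0 = background).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ids <- node_ids(spec$n_nodes)
  mods <- module_assignment(spec)
  pairs <- which(upper.tri(matrix(0, spec$n_nodes, spec$n_nodes)), arr.ind = TRUE)
  same <- mods[pairs[, 1]] == mods[pairs[, 2]] & mods[pairs[, 1]] != 0L
  prob <- ifelse(same, spec$p_in, spec$p_out)

  set.seed(spec$seed)
  for (attempt in 1:100) {
    keep <- runif(nrow(pairs)) < prob
    if (!any(keep)) next
    w <- runif(sum(keep), spec$weight_range[1], spec$weight_range[2])
    edges <- tibble(
      node_a = ids[pairs[keep, 1]],
      node_b = ids[pairs[keep, 2]],
      score = w
    ) |> arrange(.data$node_a, .data$node_b)
    g <- igraph::graph_from_data_frame(edges[1:2], directed = FALSE,
                                       vertices = ids)
    # p_out = 0 cannot connect modules; accept the block-diagonal draw
    if (spec$p_out == 0 || igraph::is_connected(g)) {
      net <- as_interaction_network(edges)
      attr(net, "modules") <- mods
      return(net)
    }
  }
  abort("Could not generate a connected network in 100 attempts; raise p_out.")
}

module_atc_code <- function(module, index) {
  # modules map to distinct subtrees: same module shares a level-4 prefix,
  # different modules differ at the first or second level
  l1 <- LETTERS[((module - 1L) %% 14L) + 1L]
  sprintf("%s%02d%s%s%02d", l1, ((module - 1L) %/% 14L) + 1L,
          LETTERS[((module - 1L) %% 26L) + 1L], "X", index)
}

module_go_terms <- function(module, n_terms = 6L) {
  sprintf("GO:%07d", module * 100L + seq_len(n_terms))
}

#' Generate a labeled synthetic drug cohort
#'
#' Creates a drug registry, module-aligned annotations and a labeled set of
#' combinations on a generated network:
#' * every drug (known or random) is assigned a home module and draws each
#'   of its targets from that module with probability
#'   `spec$overlap_strength`, otherwise uniformly from all nodes;
#' * positive pairs are two known drugs sharing a home module; components
#'   of negative-pool pairs draw their homes independently, so at strength
#'   0 positives and negatives are statistically identical and at strength
#'   1 every positive pair targets one module;
#' * each protein carries a subset of its module's GO terms, pooled per
#'   drug, and each drug an ATC code from the subtree of its *modal target
#'   module* — the annotations are aligned with what the drug actually
#'   hits, not with its latent home.
#'
#' @param spec A [synthetic_spec()].
#' @param network Network from [generate_network()] (carrying the module
#'   attribute).
#' @param n_positives Number of positive pairs to label.
#' @param n_random_drugs Size of the random-drug registry feeding the
#'   negative pool (all pairs of random drugs).
#' @return List with `drugs` (known + random registry), `positives`,
#'   `negative_pool` (combination tibbles), `cardinalities` (target-size
#'   spectrum of the known drugs).
#' @export
generate_cohort <- function(spec, network, n_positives = 30L,
                            n_random_drugs = 60L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mods <- attr(network, "modules")
  if (is.null(mods)) abort("Network lacks a module assignment; use generate_network().")
  members <- split(names(mods), mods)
  all_ids <- names(mods)

  set.seed(spec$seed + 1L)

  draw_targets <- function(home, k) {
    pool <- members[[as.character(home)]]
    ts <- character(0)
    while (length(ts) < k) {
      cand <- if (runif(1) < spec$overlap_strength) sample(pool, 1L)
              else sample(all_ids, 1L)
      ts <- union(ts, cand)
    }
    sort(ts)
  }
  modal_module <- function(ts) {
    m <- mods[ts]
    m <- m[m != 0L]
    if (length(m) == 0) return(sample.int(spec$n_modules, 1L))
    as.integer(names(which.max(table(m))))
  }

  go_by_protein <- map(seq_len(spec$n_modules), function(m) {
    terms <- module_go_terms(m)
    setNames(map(members[[as.character(m)]],
                 \(p) sort(sample(terms, 3L))), members[[as.character(m)]])
  })
  go_by_protein <- do.call(c, go_by_protein)

  make_registry <- function(n, homes, prefix) {
    sizes <- sample(seq(spec$targets_per_drug[1], spec$targets_per_drug[2]),
                    n, replace = TRUE)
    targets <- map2(homes, sizes, draw_targets)
    modal <- map_int(targets, modal_module)
    tibble(
      drug_id = sprintf("%s%04d", prefix, seq_len(n)),
      targets = targets,
      n_targets = lengths(targets),
      atc_codes = map2(modal, seq_len(n),
                       \(m, i) module_atc_code(m, ((i - 1L) %% 99L) + 1L)),
      go_terms = map(targets, \(ts)
        sort(unique(unlist(go_by_protein[ts], use.names = FALSE)))),
      module = homes
    )
  }

  known <- make_registry(spec$n_drugs,
                         sample.int(spec$n_modules, spec$n_drugs, replace = TRUE),
                         "DRG")

  # positive pairs: two known drugs with the same home module
  by_module <- split(known$drug_id, known$module)
  rich <- by_module[lengths(by_module) >= 2]
  if (length(rich) == 0) {
    abort("No module holds two drugs; increase n_drugs or lower n_modules.")
  }
  pos <- vector("list", n_positives)
  seen <- character()
  i <- 1L
  guard <- 0L
  while (i <= n_positives) {
    guard <- guard + 1L
    if (guard > 50L * n_positives) abort("Could not assemble enough distinct positive pairs.")
    pair <- sort(sample(rich[[sample.int(length(rich), 1L)]], 2L))
    key <- paste(pair, collapse = "+")
    if (key %in% seen) next
    seen <- c(seen, key)
    pos[[i]] <- pair
    i <- i + 1L
  }
  positives <- tibble(
    drug_ids = pos,
    combination = map_chr(pos, paste, collapse = "+"),
    label = "beneficial",
    source = "synthetic"
  )

  random_drugs <- make_registry(
    n_random_drugs,
    sample.int(spec$n_modules, n_random_drugs, replace = TRUE),
    "RND")
  negative_pool <- all_pairs(select(random_drugs, -"module"),
                             exclude = positives)
  negative_pool$source <- "random"

  drugs <- bind_rows(select(known, -"module"), select(random_drugs, -"module"))
  list(drugs = drugs, positives = positives, negative_pool = negative_pool,
       cardinalities = sort(known$n_targets))
}

#' Write a synthetic study to disk in the package's file dialects
#'
#' Emits the exact formats the readers accept: a STRING-style edge list, a
#' STITCH-style drug-target table (evidence scores set so every association
#' passes the default filter), ATC and GO annotation tables and a labeled
#' combination list. Everything round-trips through [load_network()],
#' [load_drugs()] and [read_combinations()].
#'
#' @param network An `interaction_network`.
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_study <- function(network, cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    network = file.path(dir, "network.tsv"),
    targets = file.path(dir, "drug_targets.tsv"),
    atc = file.path(dir, "atc_codes.tsv"),
    go = file.path(dir, "go_terms.tsv"),
    combinations = file.path(dir, "combinations.tsv")
  )
  readr::write_tsv(network$edges, paths["network"], progress = FALSE)

  assoc <- tidyr::unnest(select(cohort$drugs, "drug_id", "targets"),
                         cols = "targets") |>
    mutate(protein_id = .data$targets,
           experimental_score = 0.9, database_score = NA_real_,
           combined_score = 0.95) |>
    select("drug_id", "protein_id", "experimental_score",
           "database_score", "combined_score")
  readr::write_tsv(assoc, paths["targets"], progress = FALSE)

  atc <- tidyr::unnest(
    tibble(drug_id = cohort$drugs$drug_id, atc_code = cohort$drugs$atc_codes),
    cols = "atc_code")
  readr::write_tsv(atc, paths["atc"], progress = FALSE)

  go <- tidyr::unnest(
    tibble(drug_id = cohort$drugs$drug_id, go_term = cohort$drugs$go_terms),
    cols = "go_term")
  readr::write_tsv(go, paths["go"], progress = FALSE)

  write_combinations(cohort$positives, paths["combinations"])
  invisible(paths)
}
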