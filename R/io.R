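#' Read a STRING-style weighted edge list
#'
#' Parses a delimited text file with at least three columns: two node
#' identifiers and a confidence score. Scores may be on the unit scale or on
#' the STRING/STITCH integer milli-scale (0-1000); if any score exceeds 1 the
#' whole file is treated as 0-1000 and rescaled by 1/1000, so loading a file
#' already on the unit scale is a no-op. Self-pairs are dropped (and logged)
#' and duplicate undirected pairs are collapsed to a single edge keeping the
#' maximum score.
#'
#' @param path Path to a whitespace- or tab-delimited edge list. A header row
#'   is detected by a non-numeric third field and skipped.
#' @return A tibble with columns `node_a`, `node_b`, `score` (all scores in
#'   \[0, 1\], `node_a < node_b` lexicographically, one row per undirected
#'   edge).
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("P1\tP2\t900", "P2\tP3\t700"), f)
#' read_network_table(f)
read_network_table <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) abort("Empty edge list file.")
  fields <- strsplit(lines, "[\t ]+")

  # header: first row whose third field is not a number
  first <- fields[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  if (has_header) {
    fields <- fields[-1]
    lineno <- lineno[-1]
    if (length(fields) == 0) abort("Edge list contains a header but no data rows.")
  }

  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("Malformed edge list row at line %d: fewer than 3 fields.",
                  lineno[which(nf < 3)[1]]))
  }
  a <- map_chr(fields, 1)
  b <- map_chr(fields, 2)
  s <- suppressWarnings(as.numeric(map_chr(fields, 3)))
  if (anyNA(s)) {
    abort(sprintf("Malformed edge list row at line %d: non-numeric score.",
                  lineno[which(is.na(s))[1]]))
  }
  if (any(s < 0)) {
    abort(sprintf("Malformed edge list row at line %d: negative score.",
                  lineno[which(s < 0)[1]]))
  }
  if (any(s > 1)) s <- s / 1000  # milli-score file

  self <- a == b
  if (any(self)) {
    log_filter("self-pair edges", sum(self), sum(!self))
    a <- a[!self]; b <- b[!self]; s <- s[!self]
  }
  if (length(a) == 0) abort("No edges left after removing self-pairs.")

  lo <- pmin(a, b)
  hi <- pmax(a, b)
  tibble(node_a = lo, node_b = hi, score = s) |>
    group_by(.data$node_a, .data$node_b) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    arrange(.data$node_a, .data$node_b)
}

#' Build an interaction network from an edge table
#'
#' Converts an edge tibble (as returned by [read_network_table()] or
#' [generate_network()]) into an `interaction_network`: a symmetric
#' non-negative weighted adjacency matrix `A` with zero diagonal plus the
#' weighted-degree vector `g_i = sum_j A_ij`. Node order is deterministic
#' (sorted identifiers).
#'
#' @param edges Tibble/data frame with columns `node_a`, `node_b`, `score`.
#' @param min_score Edges with `score < min_score` are dropped before
#'   assembly.
#' @return An `interaction_network` object with elements `nodes` (character),
#'   `A` (sparse symmetric `dgCMatrix`), `degree` (named numeric), and the
#'   edge tibble.
#' @export
as_interaction_network <- function(edges, min_score = 0) {
  stopifnot(all(c("node_a", "node_b", "score") %in% names(edges)))
  edges <- as_tibble(edges)
  if (any(edges$score < 0 | edges$score > 1)) {
    abort("Edge scores must lie in [0, 1]; use read_network_table() to rescale.")
  }
  n_before <- nrow(edges)
  edges <- filter(edges, .data$score >= min_score)
  if (n_before > nrow(edges)) {
    log_filter(sprintf("edges below min_score=%g", min_score),
               n_before - nrow(edges), nrow(edges))
  }
  if (nrow(edges) == 0) abort("Network is empty after score filtering.")

  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  i <- match(edges$node_a, nodes)
  j <- match(edges$node_b, nodes)
  A <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = rep(edges$score, 2L),
    dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes)
  )
  structure(
    list(nodes = nodes, A = A,
         degree = setNames(Matrix::rowSums(A), nodes),
         edges = edges),
    class = "interaction_network"
  )
}

#' Load an interaction network from file
#'
#' Convenience wrapper: [read_network_table()] followed by
#' [as_interaction_network()].
#'
#' @inheritParams read_network_table
#' @inheritParams as_interaction_network
#' @return An `interaction_network`.
#' @export
load_network <- function(path, min_score = 0) {
  as_interaction_network(read_network_table(path), min_score = min_score)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges, mean weighted degree %.3f\n",
              length(x$nodes), nrow(x$edges), mean(x$degree)))
  invisible(x)
}

#' Read a STITCH-style drug-target association table
#'
#' Expects a delimited file with a header naming at least `drug_id` and
#' `protein_id`; optional numeric columns `experimental_score`,
#' `database_score` and `combined_score` carry the evidence channels. Scores
#' above 1 are interpreted as the 0-1000 integer scale and rescaled.
#'
#' @param path Path to a tab- or comma-delimited file.
#' @return Tibble with columns `drug_id`, `protein_id`,
#'   `experimental_score`, `database_score`, `combined_score` (missing
#'   channels filled with `NA`).
#' @export
read_drug_target_table <- function(path) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  need <- c("drug_id", "protein_id")
  if (!all(need %in% names(tbl))) {
    abort("Drug-target table must have columns 'drug_id' and 'protein_id'.")
  }
  for (col in c("experimental_score", "database_score", "combined_score")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
    tbl[[col]] <- as.numeric(tbl[[col]])
    if (any(tbl[[col]] > 1, na.rm = TRUE)) tbl[[col]] <- tbl[[col]] / 1000
  }
  tbl |>
    mutate(drug_id = as.character(.data$drug_id),
           protein_id = as.character(.data$protein_id)) |>
    select("drug_id", "protein_id", "experimental_score",
           "database_score", "combined_score")
}

#' Filter drug-target associations by evidence, promiscuity and network
#'
#' Applies, in order: the evidence rule — an association is retained iff
#' (experimental score >= 0.800 OR database score >= 0.800) AND combined
#' score >= 0.900; restriction of targets to nodes of `network` when one is
#' supplied; exclusion of drugs with more than `max_targets` targets
#' (promiscuous molecules such as ions); exclusion of drugs left with no
#' targets. Every step logs counts removed.
#'
#' Associations with no evidence channels at all (`NA` in all three score
#' columns) are treated as pre-curated and kept.
#'
#' @param associations Tibble from [read_drug_target_table()].
#' @param config A [run_config()] (uses `max_targets`).
#' @param network Optional `interaction_network`; targets outside it are
#'   dropped.
#' @return Filtered association tibble.
#' @export
filter_drug_targets <- function(associations, config = run_config(),
                                network = NULL) {
  tbl <- as_tibble(associations)
  n0 <- nrow(tbl)

  curated <- is.na(tbl$experimental_score) & is.na(tbl$database_score) &
    is.na(tbl$combined_score)
  channel_ok <- (!is.na(tbl$experimental_score) & tbl$experimental_score >= 0.800) |
    (!is.na(tbl$database_score) & tbl$database_score >= 0.800)
  combined_ok <- !is.na(tbl$combined_score) & tbl$combined_score >= 0.900
  tbl <- tbl[curated | (channel_ok & combined_ok), , drop = FALSE]
  log_filter("evidence rule", n0 - nrow(tbl), nrow(tbl))

  if (!is.null(network)) {
    n1 <- nrow(tbl)
    tbl <- filter(tbl, .data$protein_id %in% network$nodes)
    log_filter("targets outside network", n1 - nrow(tbl), nrow(tbl))
  }

  counts <- table(tbl$drug_id)
  promiscuous <- names(counts)[counts > config$max_targets]
  if (length(promiscuous) > 0) {
    n2 <- nrow(tbl)
    tbl <- filter(tbl, !.data$drug_id %in% promiscuous)
    log_filter(sprintf("drugs with > %d targets (%d drugs)",
                       config$max_targets, length(promiscuous)),
               n2 - nrow(tbl), nrow(tbl))
  }
  if (nrow(tbl) == 0) abort("No drug-target associations left after filtering.")
  tbl
}

#' Assemble a drug registry
#'
#' Collapses a (filtered) association table into one row per drug with its
#' target set as a list-column, joining optional ATC codes and GO-term
#' annotations. GO annotations may be given per drug or per protein; per
#' protein they are pooled over each drug's targets.
#'
#' @param associations Tibble with `drug_id`, `protein_id`.
#' @param atc Optional two-column tibble (`drug_id`, `atc_code`).
#' @param go Optional two-column tibble: either (`drug_id`, `go_term`) or
#'   (`protein_id`, `go_term`).
#' @return Tibble with columns `drug_id`, `targets` (list of character),
#'   `n_targets`, `atc_codes` (list), `go_terms` (list).
#' @export
build_drugs <- function(associations, atc = NULL, go = NULL) {
  drugs <- as_tibble(associations) |>
    group_by(.data$drug_id) |>
    summarise(targets = list(sort(unique(.data$protein_id))), .groups = "drop") |>
    mutate(n_targets = lengths(.data$targets))

  if (!is.null(atc)) {
    stopifnot(all(c("drug_id", "atc_code") %in% names(atc)))
    extra <- setdiff(unique(atc$drug_id), drugs$drug_id)
    if (length(extra) > 0) {
      warn(sprintf("%d drug(s) in ATC metadata absent from target table; skipped.",
                   length(extra)))
    }
    atc_sets <- atc |>
      group_by(.data$drug_id) |>
      summarise(atc_codes = list(sort(unique(.data$atc_code))), .groups = "drop")
    drugs <- left_join(drugs, atc_sets, by = "drug_id")
  } else {
    drugs$atc_codes <- list(character())
  }
  drugs$atc_codes <- map(drugs$atc_codes, \(x) x %||% character())

  if (!is.null(go)) {
    if ("drug_id" %in% names(go)) {
      stopifnot("go_term" %in% names(go))
      extra <- setdiff(unique(go$drug_id), drugs$drug_id)
      if (length(extra) > 0) {
        warn(sprintf("%d drug(s) in GO metadata absent from target table; skipped.",
                     length(extra)))
      }
      go_sets <- go |>
        group_by(.data$drug_id) |>
        summarise(go_terms = list(sort(unique(.data$go_term))), .groups = "drop")
      drugs <- left_join(drugs, go_sets, by = "drug_id")
    } else {
      stopifnot(all(c("protein_id", "go_term") %in% names(go)))
      by_protein <- split(go$go_term, go$protein_id)
      drugs$go_terms <- map(drugs$targets, \(ts)
        sort(unique(unlist(by_protein[ts], use.names = FALSE))))
    }
  } else {
    drugs$go_terms <- list(character())
  }
  drugs$go_terms <- map(drugs$go_terms, \(x) x %||% character())
  drugs
}

#' Load, filter and assemble drugs from files
#'
#' @param target_path Path to a drug-target table
#'   ([read_drug_target_table()]).
#' @param config A [run_config()].
#' @param network Optional `interaction_network` restricting targets.
#' @param atc_path Optional path to a two-column (`drug_id`, `atc_code`)
#'   table.
#' @param go_path Optional path to a two-column (`drug_id`|`protein_id`,
#'   `go_term`) table.
#' @return Drug registry tibble (see [build_drugs()]).
#' @export
load_drugs <- function(target_path, config = run_config(), network = NULL,
                       atc_path = NULL, go_path = NULL) {
  assoc <- read_drug_target_table(target_path) |>
    filter_drug_targets(config = config, network = network)
  atc <- if (!is.null(atc_path)) read_two_column(atc_path, c("drug_id", "atc_code"))
  go <- if (!is.null(go_path)) read_annotation_table(go_path)
  build_drugs(assoc, atc = atc, go = go)
}

#' Read a two-column annotation table (GO dialect)
#'
#' Accepts a delimited file whose header names either (`drug_id`, `go_term`)
#' or (`protein_id`, `go_term`); a headerless two-column file is read as
#' (`drug_id`, `go_term`).
#'
#' @param path File path.
#' @return Two-column tibble.
#' @export
read_annotation_table <- function(path) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (!"go_term" %in% names(tbl)) {
    if (ncol(tbl) != 2) abort("Annotation table must have two columns.")
    tbl <- setNames(tbl, c("drug_id", "go_term"))
  }
  mutate(tbl, across(dplyr::everything(), as.character))
}

read_two_column <- function(path, cols) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (!all(cols %in% names(tbl))) {
    if (ncol(tbl) == length(cols)) tbl <- setNames(tbl, cols)
    else abort(paste0("Expected columns: ", paste(cols, collapse = ", ")))
  }
  mutate(tbl[cols], across(dplyr::everything(), as.character))
}

#' Read a precomputed pairwise Tanimoto table
#'
#' Three columns: two drug identifiers and the Tanimoto coefficient of their
#' fingerprints, one row per unordered pair.
#'
#' @param path File path (header optional).
#' @return Tibble `drug_a`, `drug_b`, `tanimoto` with `drug_a < drug_b`.
#' @export
read_tanimoto_table <- function(path) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE,
                           col_names = FALSE)
  if (is.na(suppressWarnings(as.numeric(tbl[[3]][1])))) tbl <- tbl[-1, ]
  tibble(
    drug_a = pmin(as.character(tbl[[1]]), as.character(tbl[[2]])),
    drug_b = pmax(as.character(tbl[[1]]), as.character(tbl[[2]])),
    tanimoto = as.numeric(tbl[[3]])
  )
}

#' Read a labeled combination list
#'
#' Delimited file with header: columns `drug_id_1`, `drug_id_2` (and
#' optionally `drug_id_3`, ...), `label`, `source`. Missing higher-order
#' components are left empty/NA for pairs.
#'
#' @param path File path.
#' @return Tibble with `drug_ids` (list-column of sorted component ids),
#'   `combination` (ids joined by `+`), `label`, `source`.
#' @export
read_combinations <- function(path) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  id_cols <- grep("^drug_id_", names(tbl), value = TRUE)
  if (length(id_cols) < 2 || !all(c("label", "source") %in% names(tbl))) {
    abort("Combination list needs drug_id_1, drug_id_2[, ...], label, source columns.")
  }
  ids <- map(seq_len(nrow(tbl)), function(r) {
    v <- as.character(unlist(tbl[r, id_cols]))
    sort(v[!is.na(v) & nzchar(v)])
  })
  tibble(
    drug_ids = ids,
    combination = map_chr(ids, paste, collapse = "+"),
    label = as.character(tbl$label),
    source = as.character(tbl$source)
  )
}

#' Write a labeled combination list
#'
#' Inverse of [read_combinations()].
#'
#' @param combinations Tibble with `drug_ids` list-column, `label`, `source`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_combinations <- function(combinations, path) {
  k <- max(lengths(combinations$drug_ids))
  mat <- t(vapply(combinations$drug_ids,
                  \(v) c(sort(v), rep(NA_character_, k - length(v))),
                  character(k)))
  out <- as_tibble(mat, .name_repair = \(x) paste0("drug_id_", seq_along(x)))
  out$label <- combinations$label
  out$source <- combinations$source
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write scored combinations to a delimited file
#'
#' One row per pair/regimen: component ids joined by `+` in sorted order,
#' then whichever score columns are present (`tos`, `go`, `atc`,
#' `combined`). Values round-trip exactly through [read_scores()] (full
#' double precision).
#'
#' @param records Tibble with a `combination` character column (or `drug_ids`
#'   list-column) and numeric score columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(records, path) {
  if (nrow(records) == 0) abort("No records to write.")
  records <- as_tibble(records)
  if (!"combination" %in% names(records)) {
    if (!"drug_ids" %in% names(records)) {
      abort("Records need a 'combination' or 'drug_ids' column.")
    }
    records$combination <- map_chr(records$drug_ids, \(v) paste(sort(v), collapse = "+"))
  }
  score_cols <- intersect(c("tos", "go", "atc", "combined"), names(records))
  out <- records[c("combination", score_cols)]
  lines <- c(
    paste(names(out), collapse = "\t"),
    do.call(paste, c(lapply(out, \(col) {
      if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
    }), sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a score table written by [write_scores()]
#'
#' @param path File path.
#' @return Tibble with `combination` and numeric score columns.
#' @export
read_scores <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}
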