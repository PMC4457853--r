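test_that("edge lists load with milli-score rescaling, self-pair and duplicate handling", {
  f <- withr::local_tempfile()
  writeLines(c("protein1\tprotein2\tcombined_score",
               "P1\tP2\t700",
               "P2\tP1\t650",   # duplicate undirected pair, lower score
               "P1\tP1\t900",   # self pair
               "P2\tP3\t400"), f)
  tbl <- quiet(read_network_table(f))
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$score[tbl$node_a == "P1" & tbl$node_b == "P2"], 0.700)
  expect_false(any(tbl$node_a == tbl$node_b))

  # already on the unit scale: loading changes nothing (idempotent rescale)
  g <- withr::local_tempfile()
  readr::write_tsv(tbl, g)
  expect_equal(quiet(read_network_table(g)), tbl)
})

test_that("malformed edge rows are reported with their line number", {
  f <- withr::local_tempfile()
  writeLines(c("P1\tP2\t700", "P3\tP4", "P4\tP5\t100"), f)
  expect_error(read_network_table(f), "line 2")
  writeLines(c("P1\tP2\t700", "P4\tP5\tbroken"), f)
  expect_error(read_network_table(f), "line 2")
})

test_that("network assembly is symmetric, filtered, and deterministic", {
  edges <- tibble::tibble(node_a = c("B", "A", "A"), node_b = c("C", "B", "C"),
                          score = c(0.9, 0.5, 0.2))
  net <- quiet(as_interaction_network(edges, min_score = 0.4))
  expect_equal(net$nodes, c("A", "B", "C"))          # sorted, deterministic
  expect_true(Matrix::isSymmetric(net$A))
  expect_equal(unname(Matrix::diag(net$A)), rep(0, 3))
  expect_equal(unname(net$degree), unname(Matrix::rowSums(net$A)))
  expect_equal(nrow(net$edges), 2L)                  # 0.2 edge dropped
  expect_identical(net, quiet(as_interaction_network(edges, min_score = 0.4)))
  expect_error(quiet(as_interaction_network(edges, min_score = 0.95)), "empty")
})

test_that("evidence, promiscuity and no-target filters follow the retention rules", {
  assoc <- tibble::tibble(
    drug_id = c("d1", "d1", "d2", "d3", "d4"),
    protein_id = c("P1", "P2", "P3", "P4", "P9"),
    experimental_score = c(NA, 0.9, NA, 0.85, NA),
    database_score = c(0.85, NA, 0.85, NA, 0.7),
    combined_score = c(0.95, 0.95, 0.85, 0.92, 0.95)
  )
  kept <- quiet(filter_drug_targets(assoc, run_config()))
  # d1/P1: db 0.85 + combined 0.95 -> retained; d1/P2 exp channel -> retained
  # d2: combined below 0.900 -> dropped; d4: no channel >= 0.800 -> dropped
  expect_setequal(paste(kept$drug_id, kept$protein_id),
                  c("d1 P1", "d1 P2", "d3 P4"))

  # promiscuity: a drug with 46 targets is excluded at max_targets = 45
  big <- tibble::tibble(
    drug_id = c(rep("big", 46), "ok"),
    protein_id = c(sprintf("T%02d", 1:46), "T01"),
    experimental_score = 0.9, database_score = NA_real_, combined_score = 0.95
  )
  expect_equal(unique(quiet(filter_drug_targets(big, run_config()))$drug_id), "ok")

  # no-target exclusion via network restriction
  net <- two_node_network()
  off <- tibble::tibble(drug_id = c("d1", "d5"), protein_id = c("P1", "Q7"),
                        experimental_score = 0.9, database_score = NA_real_,
                        combined_score = 0.95)
  kept2 <- quiet(filter_drug_targets(off, run_config(), network = net))
  expect_equal(kept2$drug_id, "d1")

  # fully curated rows (no evidence channels) pass through
  cur <- tibble::tibble(drug_id = "d9", protein_id = "P9",
                        experimental_score = NA_real_,
                        database_score = NA_real_, combined_score = NA_real_)
  expect_equal(nrow(quiet(filter_drug_targets(cur, run_config()))), 1L)
})

test_that("drug registry assembly pools annotations and warns on orphans", {
  assoc <- tibble::tibble(drug_id = c("d1", "d1", "d2"),
                          protein_id = c("P1", "P2", "P2"))
  atc <- tibble::tibble(drug_id = c("d1", "ghost"), atc_code = c("L01XC03", "A01AA01"))
  go <- tibble::tibble(protein_id = c("P1", "P2", "P2"),
                       go_term = c("GO:1", "GO:2", "GO:3"))
  expect_warning(drugs <- build_drugs(assoc, atc = atc, go = go), "absent")
  expect_equal(drugs$targets[[1]], c("P1", "P2"))
  expect_equal(drugs$go_terms[[1]], c("GO:1", "GO:2", "GO:3"))  # pooled over targets
  expect_equal(drugs$go_terms[[2]], c("GO:2", "GO:3"))
  expect_equal(drugs$atc_codes[[2]], character())
})

test_that("score files round-trip exactly with canonical regimen ids", {
  rec <- tibble::tibble(
    drug_ids = list(c("b", "a"), c("c", "a", "b")),
    tos = c(1 / 3, 0.123456789012345),
    go = c(0.5, 0.25), atc = c(0, 1)
  )
  f <- withr::local_tempfile()
  write_scores(rec, f)
  back <- read_scores(f)
  expect_equal(back$combination, c("a+b", "a+b+c"))
  expect_identical(back$tos, rec$tos)  # exact round trip
  expect_identical(back$go, rec$go)
  expect_error(write_scores(rec[0, ], f), "No records")
})

test_that("combination lists round-trip through their file dialect", {
  combos <- tibble::tibble(
    drug_ids = list(c("d2", "d1"), c("d3", "d1", "d2")),
    combination = c("d1+d2", "d1+d2+d3"),
    label = c("beneficial", "detrimental_major"),
    source = "toy"
  )
  f <- withr::local_tempfile()
  write_combinations(combos, f)
  back <- read_combinations(f)
  expect_equal(back$combination, combos$combination)
  expect_equal(back$drug_ids, list(c("d1", "d2"), c("d1", "d2", "d3")))
  expect_equal(back$label, combos$label)
})

test_that("configuration defaults match the study conditions and YAML overrides work", {
  cfg <- run_config()
  expect_equal(cfg$mu, 0.1)
  expect_equal(cfg$alpha, 0.005)
  expect_equal(cfg$n_permutations, 10000L)
  expect_equal(cfg$p_threshold, 0.05)
  expect_equal(cfg$max_targets, 45L)
  expect_equal(cfg$tanimoto_cutoff, 0.85)
  expect_equal(cfg$neg_pos_ratio, 5L)
  expect_equal(cfg$n_folds, 5L)
  expect_equal(cfg$n_repeats, 100L)

  f <- withr::local_tempfile()
  writeLines(c("mu: 0.2", "n_permutations: 50"), f)
  cfg2 <- read_run_config(f, n_permutations = 100L)
  expect_equal(cfg2$mu, 0.2)
  expect_equal(cfg2$n_permutations, 100L)  # explicit override beats file
  writeLines("not_a_key: 1", f)
  expect_error(read_run_config(f), "Unknown configuration keys")
})
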