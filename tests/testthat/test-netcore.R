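test_that("regularized Laplacian is mu*G - A with the expected arithmetic", {
  net <- two_node_network()
  L <- as.matrix(regularized_laplacian(net, mu = 0.1))
  expect_equal(unname(L), matrix(c(0.1, -1, -1, 0.1), 2), tolerance = 1e-12)

  # mu = 1 on an unweighted graph: classical Laplacian, rows sum to zero
  net3 <- path3_network()
  L1 <- regularized_laplacian(net3, mu = 1)
  expect_equal(unname(Matrix::rowSums(L1)), rep(0, 3), tolerance = 1e-12)
  expect_true(Matrix::isSymmetric(L1))
  expect_equal(unname(Matrix::diag(L1)), unname(net3$degree), tolerance = 1e-12)
})

test_that("diffusion kernel matches the eigendecomposition oracle", {
  net <- two_node_network()
  K <- diffusion_kernel(net, mu = 0.1, alpha = 0.005)
  # eigenvalues of L are 0.1 -+ 1 = -0.9, 1.1
  L <- as.matrix(regularized_laplacian(net, 0.1))
  expect_equal(sort(eigen(L)$values), c(-0.9, 1.1), tolerance = 1e-12)
  expect_equal(unname(K$K), unname(kernel_oracle(net, 0.1, 0.005)),
               tolerance = 1e-10)
  expect_true(isSymmetric(K$K, tol = 1e-12))

  # alpha = 0 is the identity: no propagation
  K0 <- diffusion_kernel(net, mu = 0.1, alpha = 0)
  expect_equal(unname(K0$K), diag(2))
  expect_error(diffusion_kernel(net, mu = 0.1, alpha = -1), "non-negative")

  # random graphs: dense path vs oracle, elementwise
  for (s in 1:5) {
    rnet <- as_interaction_network(random_edges(30, 0.15, seed = s))
    Kr <- diffusion_kernel(rnet, 0.1, 0.005)
    expect_lt(max(abs(Kr$K - kernel_oracle(rnet, 0.1, 0.005))), 1e-8)
  }
})

test_that("action-on-vector path agrees with the dense kernel", {
  net <- as_interaction_network(random_edges(40, 0.15, seed = 7))
  dense <- diffusion_kernel(net, 0.1, 0.005)
  lazy <- diffusion_kernel(net, 0.1, 0.005, dense_cutoff = 0L)
  expect_null(lazy$K)
  ts <- net$nodes[c(2, 9, 17)]
  expect_equal(perturbation_scores(lazy, ts)$score,
               perturbation_scores(dense, ts)$score, tolerance = 1e-8)
})

test_that("perturbation scores are K p0 with the documented edge cases", {
  net <- path3_network()
  K <- diffusion_kernel(net, 0.1, 0.005)
  # all nodes targeted: S equals row sums of K
  expect_equal(perturbation_scores(K, net$nodes)$score,
               unname(rowSums(K$K)), tolerance = 1e-12)
  # alpha = 0, single target: indicator of that node
  K0 <- diffusion_kernel(net, 0.1, 0)
  expect_equal(perturbation_scores(K0, "P2")$score, c(0, 1, 0))
  # hand oracle: explicit K p0 product via the eigendecomposition
  oracle <- kernel_oracle(net, 0.1, 0.005) %*% c(1, 0, 0)
  expect_equal(perturbation_scores(K, "P1")$score, oracle[, 1],
               tolerance = 1e-10)
  expect_error(perturbation_scores(K, character()), "empty")
  expect_error(perturbation_scores(K, "nope"), "not in network")
})

test_that("Monte-Carlo p-values obey the add-one bound, reproducibility and symmetry", {
  net <- as_interaction_network(random_edges(25, 0.25, seed = 3))
  K <- diffusion_kernel(net, 0.1, 0.005)
  ts <- net$nodes[1:2]
  R <- 200L
  p1 <- monte_carlo_pvalues(K, ts, n_permutations = R, seed = 11)
  p2 <- monte_carlo_pvalues(K, ts, n_permutations = R, seed = 11)
  expect_identical(p1, p2)
  expect_true(all(p1$p_value >= 1 / (R + 1)))
  expect_true(all(p1$p_value <= 1))

  # complete graph with uniform weights: all non-target nodes are
  # exchangeable, so they share a single p-value
  cn <- complete_network(5, w = 0.5)
  Kc <- diffusion_kernel(cn, 0.1, 0.005)
  pc <- monte_carlo_pvalues(Kc, "P1", n_permutations = 100, seed = 2)
  expect_equal(length(unique(pc$p_value[pc$node != "P1"])), 1L)
})

test_that("degree-matched sampling is reproducible and fails on exhausted pools", {
  net <- as_interaction_network(random_edges(30, 0.2, seed = 5))
  K <- diffusion_kernel(net, 0.1, 0.005)
  a <- monte_carlo_pvalues(K, net$nodes[1:3], 50, sampling = "degree_matched",
                           seed = 4)
  b <- monte_carlo_pvalues(K, net$nodes[1:3], 50, sampling = "degree_matched",
                           seed = 4)
  expect_identical(a, b)
  # a 2-node network has 1-node degree bins once both targets are requested
  tiny <- two_node_network()
  Kt <- diffusion_kernel(tiny, 0.1, 0.005)
  expect_error(
    monte_carlo_pvalues(Kt, "P1", 10, sampling = "degree_matched",
                        degree_bins = 2))
})

test_that("neighborhood selection is strict and validates its threshold", {
  prof <- tibble::tibble(node = c("n1", "n2", "n3"),
                         p_value = c(0.01, 0.2, 0.049))
  expect_equal(neighborhood(prof, 0.05), c("n1", "n3"))
  prof$p_value[3] <- 0.05
  expect_equal(neighborhood(prof, 0.05), "n1")     # boundary excluded
  expect_equal(neighborhood(prof, 1 - 1e-9), c("n1", "n2", "n3"))
  expect_error(neighborhood(prof, 0), "p_threshold")
  expect_error(neighborhood(prof, 1), "p_threshold")
})

test_that("adding a target never decreases any perturbation score", {
  for (s in 1:3) {
    net <- as_interaction_network(random_edges(20, 0.25, seed = s))
    K <- diffusion_kernel(net, 0.1, 0.005)
    base <- sample(net$nodes, 3)
    extra <- sample(setdiff(net$nodes, base), 1)
    s0 <- perturbation_scores(K, base)$score
    s1 <- perturbation_scores(K, c(base, extra))$score
    expect_true(all(s1 >= s0 - 1e-12))
  }
})

test_that("profiles are deterministic and identical targets share a neighborhood", {
  spec <- synthetic_spec(n_nodes = 60, n_modules = 3, module_size = 20,
                         p_in = 0.4, p_out = 0.05, seed = 2)
  net <- quiet(generate_network(spec))
  K <- diffusion_kernel(net, 0.1, 0.005)
  drugs <- tibble::tibble(
    drug_id = c("a", "b", "c"),
    targets = list(net$nodes[1:2], net$nodes[1:2], net$nodes[5:6])
  )
  cfg <- run_config(n_permutations = 300, random_seed = 9)
  profs <- perturbation_profiles(drugs, K, cfg)
  profs2 <- perturbation_profiles(drugs, K, cfg)
  expect_equal(profs$neighborhood, profs2$neighborhood)
  # same target set, shared seed -> identical neighborhoods
  expect_identical(profs$neighborhood[[1]], profs$neighborhood[[2]])
})
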