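test_that("node weights follow the mode formulas, floor, and missing-node policy", {
  net <- make_net(c("G1", "G2", "G2", "G3"))
  fdr <- c(G1 = 0, G2 = 1)
  q1 <- compute_node_weights(net, fdr, walk_config(weight_mode = "one_minus_fdr"))
  expect_equal(unname(q1[c("G1", "G2")]), c(1.0, 0.01))
  expect_equal(unname(q1["G3"]), 0.01)          # unmeasured -> floor
  q2 <- compute_node_weights(net, fdr, walk_config(weight_mode = "fdr"))
  expect_equal(unname(q2[c("G1", "G2")]), c(0.01, 1.0))
  expect_equal(unname(q2["G3"]), 1.0)           # unmeasured -> 1 in fdr mode
  expect_error(compute_node_weights(net, c(G1 = 1.2), walk_config()), "\\[0, 1\\]")
})

test_that("transition rows are a_ij q_j renormalized, with self-loops on isolates", {
  tri <- make_net(c("A", "B", "B", "C", "A", "C"))
  P <- build_transition(tri, c(A = 1, B = 1, C = 1))
  expect_equal(unname(P$p["A", ]), c(0, 0.5, 0.5))
  expect_equal(unname(rowSums(P$p)), rep(1, 3))

  Pw <- build_transition(tri, c(A = 0.2, B = 0.4, C = 0.4))
  expect_equal(unname(Pw$p["B", ]), c(0.2 / 0.6, 0, 0.4 / 0.6))

  iso <- make_net(c("A", "B"), nodes = "Z")
  Pi <- build_transition(iso, c(A = 1, B = 1, Z = 1))
  expect_true(Pi$isolated["Z"])
  expect_equal(unname(Pi$p["Z", ]), c(0, 0, 1))
})

test_that("seed vector is uniform over mapped DRPs and errors when none map", {
  net <- make_net(c("A", "B", "B", "C"))
  expect_message(g0 <- seed_vector(net, c("A", "B", "X")), "not in network")
  expect_equal(unname(g0), c(0.5, 0.5, 0))
  expect_equal(unname(seed_vector(net, "A")), c(1, 0, 0))
  expect_error(seed_vector(net, c("X", "Y")), "X, Y")
})

test_that("propagation hits the closed-form stationary laws", {
  tri <- make_net(c("A", "B", "B", "C", "A", "C"))
  P <- build_transition(tri, c(A = 1, B = 1, C = 1))
  res <- propagate(P, seed_vector(tri, "A"), walk_config(tol = 1e-9))
  expect_true(res$converged)
  expect_equal(unname(res$g), rep(1 / 3, 3), tolerance = 1e-6)

  ## K2 with restart 0.5 from (1, 0): solve x = 0.5(1 - x) + 0.5 -> 2/3
  k2 <- make_net(c("A", "B"))
  P2 <- build_transition(k2, c(A = 1, B = 1))
  r2 <- propagate(P2, c(A = 1, B = 0), walk_config(restart = 0.5, tol = 1e-9))
  expect_equal(unname(r2$g), c(2 / 3, 1 / 3), tolerance = 1e-6)

  ## K2 at r = 0 oscillates with period 2: flagged, not silently accepted
  expect_warning(
    r0 <- propagate(P2, c(A = 1, B = 0), walk_config(max_iter = 500)),
    "did not converge"
  )
  expect_false(r0$converged)
  expect_identical(r0$iterations, 500L)
  expect_error(
    suppressWarnings(
      propagate(P2, c(A = 1, B = 0), walk_config(max_iter = 50, strict = TRUE))
    ),
    "restart"
  )
})

test_that("constant weights at r = 0 give the degree-proportional stationary law", {
  set.seed(31)
  a <- rand_adjacency(25, 0.25)
  rownames(a) <- colnames(a) <- sprintf("N%02d", 1:25)
  P <- a / rowSums(a)
  g0 <- c(1, rep(0, 24)); names(g0) <- rownames(a)
  res <- suppressWarnings(propagate(P, g0, walk_config(tol = 1e-9)))
  expect_true(res$converged)
  expect_equal(unname(res$g), unname(rowSums(a) / sum(a)), tolerance = 1e-4)
})

test_that("weighted stationary distribution matches the detailed-balance closed form", {
  ## for p_ij = a_ij q_j / s_i the chain is reversible with pi_i ~ q_i * s_i
  set.seed(32)
  a <- rand_adjacency(30, 0.3)
  q <- runif(30, 0.2, 1)
  P <- transition_from(a, q)
  g0 <- rep(1 / 30, 30)
  res <- propagate(P, g0, walk_config(tol = 1e-10))
  s <- rowSums(a * rep(q, each = 30))
  pi_cf <- q * s / sum(q * s)
  expect_equal(unname(res$g), pi_cf, tolerance = 1e-6)
})

test_that("restart fixed point matches the direct linear solve", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    P <- transition_from(rand_adjacency(n), runif(n, 0.2, 1))
    g0 <- numeric(n); g0[sample(n, 1)] <- 1
    for (r in c(0.3, 0.7)) {
      res <- propagate(P, g0, walk_config(restart = r, tol = 1e-12,
                                          max_iter = 100000))
      expect_lt(sum(abs(res$g - restart_fixed_point(P, g0, r))), 1e-8)
    }
  }
})

test_that("every iterate stays on the simplex and P stays row-stochastic", {
  set.seed(34)
  n <- 40
  P <- transition_from(rand_adjacency(n), runif(n, 0.2, 1))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  res <- propagate(P, rep(1 / n, n), walk_config(restart = 0.5, tol = 1e-8))
  expect_lt(abs(sum(res$g) - 1), 1e-10)
  expect_true(all(res$g >= 0))
})

test_that("top-k ordering, tie-breaks, and forced seeds behave as stated", {
  g <- c(A = 0.5, B = 0.3, C = 0.2)
  expect_identical(top_k_nodes(g, k = 2)$symbols, c("A", "B"))
  g2 <- c(C = 0.3, A = 0.4, B = 0.3)
  expect_identical(top_k_nodes(g2, k = 2)$symbols, c("A", "B"))  # symbol tie
  expect_identical(top_k_nodes(g, k = 3)$symbols, c("A", "B", "C"))
  top <- top_k_nodes(g, k = 2, seeds = "C", force_include_seeds = TRUE)
  expect_identical(top$symbols, c("A", "B", "C"))
  expect_identical(attr(top, "forced"), "C")
  expect_error(top_k_nodes(g, k = 4), "exceeds")
})

test_that("crosstalk extraction picks the high-probability component and classes", {
  net <- make_net(c("A", "B", "C", "D", "D", "E"))
  ext <- extract_crosstalk(net, c("A", "B", "C", "D"), seeds = "A",
                           probabilities = c(A = 0.4, B = 0.3, C = 0.2, D = 0.1))
  expect_identical(ext$component$nodes, c("A", "B"))
  expect_identical(ext$connector_drps, "A")
  expect_identical(unname(ext$node_classes["A"]), "seed_drp")

  ext2 <- extract_crosstalk(net, c("C", "D", "E"), seeds = "C",
                            degs = c("E"), tfs = gene_list("tfs", "D"))
  expect_identical(ext2$component$nodes, c("C", "D", "E"))
  expect_identical(unname(ext2$node_classes[c("C", "D", "E")]),
                   c("seed_drp", "transcription_factor", "deg"))

  ## disconnected top set -> empty component reported, not an error
  ext3 <- extract_crosstalk(make_net(c("A", "B", "C", "D")), c("A", "C"), "A")
  expect_true(ext3$empty)
  expect_identical(ext3$connector_drps, character(0))
})

test_that("planted crosstalk axis is recovered end to end", {
  sim <- simulate_network(seed = 5)
  net <- build_union_network(sim$collection)
  measured <- setdiff(net$nodes, c(sim$truth$seed_protein, sim$truth$signaling))
  set.seed(55)
  fdr <- setNames(runif(length(measured), 0.2, 1), measured)
  fdr[sim$truth$true_degs$symbols] <- runif(10, 0, 0.001)
  wr <- random_walk(net, sim$truth$seed_protein, fdr,
                    walk_config(restart = 0.5),
                    deg_list = sim$truth$true_degs)
  expect_true(all(sim$truth$planted_path %in% wr$top_nodes$symbols))
  expect_identical(wr$connector_drps, sim$truth$seed_protein)
  expect_true(all(sim$truth$true_degs$symbols %in% wr$component$nodes))
})
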