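ed2 <- function(p_fwd_12, p_rev_12) {
  as_edge_dist(matrix(c(0, p_rev_12, p_fwd_12, 0), 2, 2))
}

pd2 <- function(p_fwd_12, p_rev_12, p_undir_12) {
  as_pdag_dist(matrix(c(0, p_rev_12, p_fwd_12, 0), 2, 2),
               matrix(c(0, p_undir_12, p_undir_12, 0), 2, 2))
}

test_that("edge entropy matches frozen hand values and its bounds", {
  expect_equal(edge_entropy(ed2(1, 0))$value[1, 2], 0)
  expect_equal(edge_entropy(ed2(1 / 3, 1 / 3))$value[1, 2], 1)
  # H(0.5, 0.25, 0.25) = 1.5 bits; normalized by log2(3)
  expect_equal(edge_entropy(ed2(0.5, 0.25))$value[1, 2],
               1.5 / log2(3), tolerance = 1e-9)
  expect_equal(edge_entropy(ed2(0.5, 0.25))$value[1, 2], 0.94639,
               tolerance = 1e-5)
  # symmetric matrix, zero diagonal, values in [0, 1] on random input
  withr::with_seed(7, {
    for (rep in 1:10) {
      graphs <- lapply(1:15, function(i) random_test_dag(6, 0.4))
      d <- edge_state_distribution(posterior_samples(graphs))
      h <- edge_entropy(d)$value
      expect_equal(h, t(h))
      expect_true(all(diag(h) == 0))
      expect_true(all(h >= 0 & h <= 1 + 1e-12))
    }
  })
})

test_that("direction entropy conditions on an oriented edge", {
  expect_equal(direction_entropy(pd2(0.4, 0.4, 0.1))$value[1, 2], 1)
  # q = 0.3 / 0.4 = 0.75: binary entropy 0.81128 bits
  expect_equal(direction_entropy(pd2(0.3, 0.1, 0.2))$value[1, 2],
               0.81128, tolerance = 1e-5)
  expect_equal(direction_entropy(pd2(0, 0, 0.6))$value[1, 2], 0)
  # literal (unnormalized) variant stays available
  h_raw <- direction_entropy(pd2(0.3, 0.1, 0.2), renormalize = FALSE)$value[1, 2]
  expect_equal(h_raw, -(0.3 * log2(0.3) + 0.1 * log2(0.1)), tolerance = 1e-9)
})

test_that("four-state entropy matches frozen values", {
  expect_equal(four_state_entropy(pd2(0.25, 0.25, 0.25))$value[1, 2], 1)
  expect_equal(four_state_entropy(pd2(1, 0, 0))$value[1, 2], 0)
  # (0.3, 0.3, 0, 0.4): 1.57095 bits / 2
  expect_equal(four_state_entropy(pd2(0.3, 0.3, 0))$value[1, 2],
               oracle_entropy_bits(c(0.3, 0.3, 0.4)) / 2, tolerance = 1e-9)
  expect_equal(four_state_entropy(pd2(0.3, 0.3, 0))$value[1, 2], 0.785475,
               tolerance = 1e-5)
})

test_that("bald measures disagreement between ensemble members", {
  # identical members: zero everywhere
  m <- ed2(0.4, 0.3)
  expect_true(all(bald(list(m, m, m))$value == 0))
  # single member: H(mean) = E[H]
  expect_true(all(bald(list(m))$value == 0))
  # (1,0,0) vs (0,1,0): mean (0.5,0.5,0) -> 1 bit / log2(3)
  b <- bald(list(ed2(1, 0), ed2(0, 1)))$value[1, 2]
  expect_equal(b, 1 / log2(3), tolerance = 1e-9)
  expect_equal(b, 0.63093, tolerance = 1e-5)
  expect_error(bald(list()), "length")
})

test_that("bald and ebald never exceed the corresponding pooled entropy", {
  withr::with_seed(59, {
    for (rep in 1:10) {
      graphs <- lapply(1:24, function(i) random_test_dag(5, 0.4))
      s <- posterior_samples(graphs)
      mem3 <- ensemble_marginals(s, n_groups = 4, type = "dag")
      b <- bald(mem3)$value
      h <- edge_entropy(edge_state_distribution(s))$value
      expect_true(all(b >= 0 & b <= h + 1e-9))
      pd <- pdag_state_distribution(s)
      mem4 <- ensemble_marginals(s, n_groups = 4, type = "pdag")
      mask1 <- structure(list(n_nodes = 5, u = matrix(1, 5, 5) - diag(5),
                              seed = NULL), class = "grn_mask")
      eb <- ebald(mem4, mask1)$value
      expect_true(all(eb >= 0 & eb <= direction_entropy(pd)$value + 1e-9))
    }
  })
})

test_that("the undirectedness mask honours its Bernoulli contract", {
  d0 <- pd2(0.6, 0.4, 0)
  expect_true(all(sample_undirected_mask(d0, seed = 1)$u == 0))
  d1 <- pd2(0, 0, 1)
  u1 <- sample_undirected_mask(d1, seed = 1)$u
  expect_true(all(u1[upper.tri(u1)] == 1))
  expect_true(all(diag(u1) == 0))
  # p_undir = 0.5: empirical mean of u over many seeds within 0.5 +- 0.02
  dh <- pd2(0.25, 0.25, 0.5)
  draws <- vapply(1:5000, function(s) sample_undirected_mask(dh, seed = s)$u[1, 2],
                  0L)
  expect_equal(mean(draws), 0.5, tolerance = 0.04)
  # symmetric and reproducible given the seed
  expect_identical(sample_undirected_mask(dh, seed = 99)$u,
                   sample_undirected_mask(dh, seed = 99)$u)
})

test_that("eces switches between direction and four-state entropy via the mask", {
  withr::with_seed(61, {
    graphs <- lapply(1:20, function(i) random_test_dag(6, 0.4))
    d <- pdag_state_distribution(posterior_samples(graphs))
    mask0 <- sample_undirected_mask(as_pdag_dist(d$p_fwd * 0, d$p_undir * 0), seed = 1)
    expect_equal(eces(d, mask0)$value, four_state_entropy(d)$value)
    mask1 <- mask0
    mask1$u <- matrix(1L, 6, 6) - diag(6)
    expect_equal(eces(d, mask1)$value, direction_entropy(d)$value)
  })
  # maximal direction uncertainty on a masked pair scores 1
  dm <- pd2(0.3, 0.3, 0.4)
  m1 <- sample_undirected_mask(pd2(0, 0, 1), seed = 1)
  expect_equal(eces(dm, m1)$value[1, 2], 1)
  mask3 <- sample_undirected_mask(as_pdag_dist(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(eces(pd2(0.3, 0.3, 0), mask3), "dimension")
})

test_that("ebald reduces to its branches and to zero for identical members", {
  m <- pd2(0.3, 0.2, 0.4)
  maskany <- sample_undirected_mask(pd2(0, 0, 1), seed = 3)
  expect_true(all(ebald(list(m, m), maskany)$value == 0))
  # u = 0 everywhere: four-state disagreement only
  withr::with_seed(67, {
    graphs <- lapply(1:20, function(i) random_test_dag(5, 0.4))
    s <- posterior_samples(graphs)
    mem <- ensemble_marginals(s, n_groups = 4, type = "pdag")
    mask0 <- sample_undirected_mask(as_pdag_dist(matrix(0, 5, 5), matrix(0, 5, 5)),
                                    seed = 1)
    eb0 <- ebald(mem, mask0)$value
    pooled4 <- four_state_entropy(pdag_state_distribution(s))$value
    mean4 <- Reduce(`+`, lapply(mem, function(mm)
      attr(mm, "weight") * four_state_entropy(mm)$value))
    expect_equal(eb0, pmax(pooled4 - mean4, 0), tolerance = 1e-12)
  })
  # two members with opposite certain directions on a masked pair -> 1
  eb <- ebald(list(pd2(1, 0, 0), pd2(0, 1, 0)),
              sample_undirected_mask(pd2(0, 0, 1), seed = 5))
  expect_equal(eb$value[1, 2], 1)
})

test_that("node uncertainty equals brute-force column sums", {
  z <- as_edge_dist(matrix(0, 4, 4))
  expect_equal(node_uncertainty(edge_entropy(z)), rep(0, 4))
  # one uncertain pair spreads its score to both endpoints
  p <- matrix(0, 4, 4)
  p[2, 3] <- 1 / 3; p[3, 2] <- 1 / 3
  h <- edge_entropy(as_edge_dist(p))
  u <- node_uncertainty(h)
  expect_equal(u[2], u[3])
  expect_gt(u[2], 0)
  expect_equal(u[c(1, 4)], c(0, 0))
  withr::with_seed(71, {
    graphs <- lapply(1:15, function(i) random_test_dag(6, 0.4))
    h <- edge_entropy(edge_state_distribution(posterior_samples(graphs)))
    manual <- vapply(1:6, function(j) sum(h$value[, j]), 0)
    expect_equal(node_uncertainty(h), manual)
  })
})

test_that("knockout scores favour certain, probable parents of uncertain genes", {
  # fully certain posterior: nothing to resolve
  certain <- as_edge_dist(matrix(c(0, 0, 1, 0), 2, 2))
  expect_equal(knockout_scores(edge_entropy(certain), certain), c(0, 0))
  # all pair scores 1: the (1 - score) factor vanishes
  ones <- edge_entropy(ed2(1 / 3, 1 / 3))
  expect_equal(knockout_scores(ones, ed2(1 / 3, 1 / 3)), c(0, 0))
  # 3 genes: gene 1 is a certain parent of gene 2; pair (2,3) uncertain
  # with score 0.9 -> knocking out gene 1 is the best move
  s <- matrix(0, 3, 3)
  s[2, 3] <- s[3, 2] <- 0.9
  pf <- matrix(0, 3, 3)
  pf[1, 2] <- 1
  sm <- structure(list(n_nodes = 3, value = s, function_name = "test",
                       labels = NULL), class = "grn_scores")
  ks <- knockout_scores(sm, as_edge_dist(pf))
  expect_equal(which.max(ks), 1L)
  # hand evaluation: score[1] = (1 - 0) * 1 * u[2], u[2] = 0.9
  expect_equal(ks[1], 0.9)
})

test_that("knockout scoring is equivariant under gene relabeling", {
  withr::with_seed(73, {
    graphs <- lapply(1:15, function(i) random_test_dag(6, 0.4))
    s <- posterior_samples(graphs)
    d <- edge_state_distribution(s)
    ks <- knockout_scores(edge_entropy(d), d)
    perm <- sample.int(6)
    graphs_p <- lapply(graphs, function(g) {
      dag_from_adj_test(g$adj[order(perm), order(perm)])
    })
    dp <- edge_state_distribution(posterior_samples(graphs_p))
    ksp <- knockout_scores(edge_entropy(dp), dp)
    expect_equal(ksp, ks[order(perm)], tolerance = 1e-12)
  })
})

test_that("intervention selection obeys argmax, tie-break and uniform contracts", {
  expect_equal(select_interventions(c(0.1, 0.9, 0.5), 1, "argmax"), 2L)
  expect_equal(select_interventions(rep(0.5, 4), 2, "argmax"), c(1L, 2L))
  expect_equal(select_interventions(c(0.1, 0.9, 0.5), 2, "argmax"), c(2L, 3L))
  expect_error(select_interventions(c(1, 2), 3, "argmax"), "batch size")
  expect_equal(select_interventions(c(0.1, 0.9), 1, "argmax", exclude = 2L), 1L)
  # uniform: each of 64 genes selected with frequency 1/64 +- 0.01
  picks <- vapply(1:8000, function(s)
    select_interventions(rep(0, 64), 1, "uniform", seed = s), 0L)
  freq <- tabulate(picks, 64) / 8000
  expect_true(all(abs(freq - 1 / 64) < 0.01))
})

test_that("acquire wires distributions, scores and selection together", {
  withr::with_seed(79, {
    graphs <- lapply(1:24, function(i) random_test_dag(6, 0.35))
    s <- posterior_samples(graphs)
    for (m in c("entropy", "bald", "eces", "ebald")) {
      a <- acquire(s, method = m, batch_size = 2, seed = 11, n_groups = 4)
      expect_s3_class(a, "grn_acquisition")
      expect_length(a$selected, 2)
      expect_false(anyDuplicated(a$selected) > 0)
      expect_equal(a$function_name, m)
      expect_true(all(a$pair_scores$value >= 0 & a$pair_scores$value <= 1))
      # argmax selection consistent with the node scores
      expect_equal(sort(a$node_scores[a$selected], decreasing = TRUE),
                   sort(a$node_scores, decreasing = TRUE)[1:2],
                   tolerance = 1e-12)
    }
    a <- acquire(s, method = "uniform", batch_size = 3, seed = 2)
    expect_length(a$selected, 3)
    expect_true(all(tidy(a)$score == 0))
  })
})

test_that("degenerate undirectedness collapses ECES onto the four-state entropy ranking", {
  # colliders only: every sampled CPDAG is fully directed, p_undir = 0
  colliders <- list(dag(3, rbind(c(1, 3), c(2, 3))),
                    dag(3, rbind(c(1, 2), c(3, 2))))
  s <- posterior_samples(colliders)
  pd <- pdag_state_distribution(s)
  expect_true(all(pd$p_undir == 0))
  mask <- sample_undirected_mask(pd, seed = 13)
  expect_true(all(mask$u == 0))
  expect_equal(eces(pd, mask)$value, four_state_entropy(pd)$value)
  d <- edge_state_distribution(s)
  expect_equal(order(-knockout_scores(eces(pd, mask), d)),
               order(-knockout_scores(four_state_entropy(pd), d)))
})
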