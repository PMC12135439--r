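test_that("acyclicity detection matches igraph on fixed and random graphs", {
  expect_true(is_acyclic(dag(5)))
  expect_false(is_acyclic(dag(3, rbind(c(1, 2), c(2, 3), c(3, 1)))))
  expect_true(is_acyclic(dag(3, rbind(c(1, 2), c(1, 3), c(2, 3)))))
  withr::with_seed(11, {
    for (rep in 1:25) {
      g <- random_test_digraph(7, p = 0.25)
      ig <- igraph::graph_from_adjacency_matrix(g$adj, mode = "directed")
      expect_identical(is_acyclic(g), igraph::is_dag(ig))
    }
  })
})

test_that("cpdag handles chain, collider, and the compelled 4-node case", {
  # chain 1 -> 2 -> 3: no v-structure, fully undirected class
  p <- cpdag(dag(3, rbind(c(1, 2), c(2, 3))))
  expect_equal(sum(p$dir), 0)
  expect_equal(sum(p$undir) / 2, 2)
  # collider 1 -> 3 <- 2 with 1, 2 nonadjacent: both edges compelled
  p <- cpdag(dag(3, rbind(c(1, 3), c(2, 3))))
  expect_equal(sum(p$dir), 2)
  expect_equal(p$dir[1, 3] + p$dir[2, 3], 2)
  expect_equal(sum(p$undir), 0)
  # v-structure at node 2 plus descendant: all three edges compelled
  g <- dag(4, rbind(c(1, 2), c(3, 2), c(2, 4)))
  p <- cpdag(g)
  oracle <- oracle_cpdag(g$adj)
  expect_same_pdag(p, oracle)
  expect_equal(sum(p$dir), 3)
  expect_error(cpdag(dag(3, rbind(c(1, 2), c(2, 3), c(3, 1)))), "acyclic")
})

test_that("cpdag agrees with brute-force MEC enumeration for every DAG on <= 4 nodes", {
  for (n in 2:4) {
    all_dags <- oracle_all_dags(n)
    # group the class keys once so the oracle is cheap per DAG
    keys <- vapply(all_dags, function(a)
      paste(oracle_skeleton_key(a), oracle_vstruct_key(a), sep = "|"),
      character(1))
    for (i in seq_along(all_dags)) {
      mec <- all_dags[keys == keys[i]]
      present_all <- Reduce(`*`, mec)
      present_any <- (Reduce(`+`, mec) > 0)
      p <- cpdag(dag_from_adj_test(all_dags[[i]]))
      expect_identical(unname(p$dir), present_all * 1L,
                       label = sprintf("dir n=%d dag=%d", n, i))
      expect_identical(unname(p$undir), (present_any & t(present_any)) * 1L,
                       label = sprintf("undir n=%d dag=%d", n, i))
    }
  }
})

test_that("cpdag is invariant over Markov-equivalent DAGs (n <= 4)", {
  for (n in 3:4) {
    all_dags <- oracle_all_dags(n)
    keys <- vapply(all_dags, function(a)
      paste(oracle_skeleton_key(a), oracle_vstruct_key(a), sep = "|"),
      character(1))
    for (key in unique(keys)) {
      mec <- all_dags[keys == key]
      ps <- lapply(mec, function(a) cpdag(dag_from_adj_test(a)))
      for (p in ps[-1]) expect_same_pdag(p, list(dir = ps[[1]]$dir, undir = ps[[1]]$undir))
    }
  }
})

test_that("meek closure applies R1, leaves closed graphs alone, and is idempotent", {
  # R1: 1 -> 2, 2 - 3, 1 and 3 nonadjacent  =>  2 -> 3
  p <- meek_closure(pdag(3, directed = rbind(c(1, 2)), undirected = rbind(c(2, 3))))
  expect_equal(p$dir[2, 3], 1L)
  expect_equal(sum(p$undir), 0)
  # fully undirected triangle: no rule fires
  tri <- pdag(3, undirected = rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_same_pdag(meek_closure(tri), list(dir = tri$dir, undir = tri$undir))
  # idempotence and skeleton/directed-edge preservation on random PDAGs
  withr::with_seed(5, {
    for (rep in 1:10) {
      g <- random_test_dag(8, p = 0.3)
      e <- edges(g)
      half <- e[runif(nrow(e)) < 0.5, ]
      rest <- dplyr::anti_join(e, half, by = c("from", "to"))
      p0 <- pdag(8, directed = as.matrix(half), undirected = as.matrix(rest))
      p1 <- meek_closure(p0)
      p2 <- meek_closure(p1)
      expect_same_pdag(p2, list(dir = p1$dir, undir = p1$undir))
      expect_true(all(p1$dir[p0$dir == 1L] == 1L))  # never un-directs
      skel0 <- (p0$dir | t(p0$dir) | p0$undir)
      skel1 <- (p1$dir | t(p1$dir) | p1$undir)
      expect_identical(skel0, skel1)
    }
  })
  expect_error(meek_closure(pdag(3, directed = rbind(c(1, 2), c(2, 3), c(3, 1)))),
               "cyclic")
})

test_that("repair_to_dag is identity on DAGs, minimal on a 3-cycle, exact on the fixture scale", {
  g <- dag(4, rbind(c(1, 2), c(2, 3)))
  r <- repair_to_dag(g)
  expect_equal(nrow(r$removed), 0)
  expect_identical(r$dag$adj, g$adj)

  r <- repair_to_dag(dag(3, rbind(c(1, 2), c(2, 3), c(3, 1))))
  expect_equal(nrow(r$removed), 1)
  expect_true(is_acyclic(r$dag))

  # GNW-scale fixture: 207 edges, repair removes exactly the 21 back-edges
  truth <- random_ground_truth(64, 207, 21, seed = 5)
  expect_equal(n_edges(truth), 207)
  expect_false(is_acyclic(truth))
  r <- repair_to_dag(truth)
  expect_equal(nrow(r$removed), 21)
  expect_true(is_acyclic(r$dag))
  expect_equal(n_edges(r$dag), 186)
})

test_that("repair_to_dag output is always acyclic (random cyclic graphs)", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      g <- random_test_digraph(8, p = 0.3)
      r <- repair_to_dag(g)
      expect_true(is_acyclic(r$dag))
      # removed + kept partitions the original edges
      expect_equal(sum(r$dag$adj) + nrow(r$removed), sum(g$adj))
      if (nrow(r$removed) > 0)
        expect_true(all(g$adj[as.matrix(r$removed)] == 1L))
    }
  })
})

test_that("shd matches hand values and the exhaustive pair comparison", {
  a <- dag(3, rbind(c(1, 2), c(2, 3)))
  b <- dag(3, rbind(c(2, 1), c(2, 3)))
  expect_equal(shd(a, a, "directed"), 0)
  expect_equal(shd(a, a, "undirected"), 0)
  expect_equal(shd(cpdag(a), cpdag(a), "pdag"), 0)
  expect_equal(shd(dag(3), a, "directed"), 2)
  expect_equal(shd(dag(3), a, "undirected"), 2)
  expect_equal(shd(a, b, "directed"), 1)          # one reversal
  expect_equal(shd(a, b, "directed", reversal_cost = 2), 2)
  expect_equal(shd(a, b, "undirected"), 0)        # same skeleton
  # exhaustive per-pair oracle on random digraphs
  withr::with_seed(23, {
    for (rep in 1:10) {
      x <- random_test_digraph(6, 0.35)
      y <- random_test_digraph(6, 0.35)
      count <- 0
      for (i in 1:5) for (j in (i + 1):6) {
        sx <- c(x$adj[i, j], x$adj[j, i])
        sy <- c(y$adj[i, j], y$adj[j, i])
        if (!all(sx == sy)) count <- count + 1
      }
      expect_equal(shd(x, y, "directed"), count)
    }
  })
  expect_error(shd(dag(3), dag(4), "directed"), "node set")
})

test_that("shd is symmetric and satisfies the triangle inequality in every mode", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      gs <- lapply(1:3, function(i) random_test_dag(6, 0.35))
      for (mode in c("directed", "undirected")) {
        d12 <- shd(gs[[1]], gs[[2]], mode)
        d13 <- shd(gs[[1]], gs[[3]], mode)
        d23 <- shd(gs[[2]], gs[[3]], mode)
        expect_equal(d12, shd(gs[[2]], gs[[1]], mode))
        expect_lte(d13, d12 + d23)
      }
      ps <- lapply(gs, cpdag)
      d12 <- shd(ps[[1]], ps[[2]], "pdag")
      d13 <- shd(ps[[1]], ps[[3]], "pdag")
      d23 <- shd(ps[[2]], ps[[3]], "pdag")
      expect_equal(d12, shd(ps[[2]], ps[[1]], "pdag"))
      expect_lte(d13, d12 + d23)
    }
  })
})

test_that("graph constructors validate their invariants", {
  expect_error(dag(3, rbind(c(1, 1))), "self-loop")
  expect_error(dag(3, rbind(c(1, 4))), "range")
  expect_error(dag(2, labels = c("a", "a")), "unique")
  expect_error(pdag(3, directed = rbind(c(1, 2), c(2, 1))), "both orientations")
  expect_error(pdag(3, directed = rbind(c(1, 2)), undirected = rbind(c(1, 2))),
               "both directed and undirected")
})

test_that("edge-list, PDAG and adjacency round-trips preserve the graph", {
  g <- random_ground_truth(10, 15, 2, seed = 9)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, tf)
  g2 <- read_edge_list(tf, labels = g$labels)
  expect_identical(g2$adj, g$adj)

  p <- cpdag(repair_to_dag(g)$dag)
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_pdag_edge_list(p, tp)
  p2 <- read_pdag_edge_list(tp, labels = g$labels)
  expect_same_pdag(p2, list(dir = p$dir, undir = p$undir))

  ta <- withr::local_tempfile(fileext = ".csv")
  write_adjacency_csv(g, ta)
  g3 <- read_adjacency_csv(ta, labels = g$labels)
  expect_identical(g3$adj, g$adj)
})
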