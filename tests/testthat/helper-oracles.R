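# Independent brute-force oracles for the graph machinery.  These are
# deliberately written from first principles (no calls into the package's
# own Meek/CPDAG/enumeration code paths).

# All 0/1 adjacency matrices of DAGs on n nodes, by filtering every one
# of the 2^(n(n-1)) loop-free directed graphs through igraph's DAG test.
oracle_all_dags <- function(n) {
  cells <- which(diag(n) == 0)
  out <- list()
  for (code in 0:(2^length(cells) - 1)) {
    adj <- matrix(0L, n, n)
    bits <- as.integer(intToBits(code))[seq_along(cells)]
    adj[cells] <- bits
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
    if (igraph::is_dag(ig)) out[[length(out) + 1L]] <- adj
  }
  out
}

oracle_skeleton_key <- function(adj) {
  s <- (adj | t(adj)) * 1L
  paste(s[upper.tri(s)], collapse = "")
}

# V-structures a -> c <- b with a, b nonadjacent, as a canonical string.
oracle_vstruct_key <- function(adj) {
  n <- nrow(adj)
  s <- (adj | t(adj)) * 1L
  keys <- character(0)
  for (cc in seq_len(n)) {
    pa <- which(adj[, cc] == 1L)
    if (length(pa) >= 2) {
      for (i in seq_along(pa)) for (j in seq_along(pa)) {
        if (i < j && s[pa[i], pa[j]] == 0L) {
          keys <- c(keys, paste(pa[i], pa[j], cc, sep = "-"))
        }
      }
    }
  }
  paste(sort(keys), collapse = ";")
}

# Essential graph of `adj` by explicit Markov-equivalence-class
# enumeration: collect every DAG with the same skeleton and v-structures,
# and call an edge compelled iff it has the same orientation in all of
# them.  Returns list(dir = matrix, undir = matrix).
oracle_cpdag <- function(adj, all_dags = NULL) {
  n <- nrow(adj)
  all_dags <- if (is.null(all_dags)) oracle_all_dags(n) else all_dags
  sk <- oracle_skeleton_key(adj)
  vs <- oracle_vstruct_key(adj)
  mec <- Filter(function(d) oracle_skeleton_key(d) == sk &&
                  oracle_vstruct_key(d) == vs, all_dags)
  present_all <- Reduce(`*`, mec)        # 1 iff edge in every member
  present_any <- (Reduce(`+`, mec) > 0)  # 1 iff edge in some member
  dir <- present_all
  undir <- (present_any & t(present_any)) * 1L
  list(dir = dir * 1L, undir = undir, n_class = length(mec))
}

expect_same_pdag <- function(p, oracle) {
  expect_identical(unname(p$dir == 1L), unname(oracle$dir == 1L))
  expect_identical(unname(p$undir == 1L), unname(oracle$undir == 1L))
}

dag_from_adj_test <- function(adj, labels = NULL) {
  dag(nrow(adj), which(adj == 1L, arr.ind = TRUE), labels = labels)
}

# Small random DAG generator for property tests (independent of the
# package's simulator): random permutation order, edge prob p.
random_test_dag <- function(n, p = 0.3) {
  ord <- sample.int(n)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) adj[ord[i], ord[j]] <- 1L
  }
  dag(n, which(adj == 1L, arr.ind = TRUE))
}

# Random directed (possibly cyclic) graph for SHD property tests.
random_test_digraph <- function(n, p = 0.3) {
  adj <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(adj) <- 0L
  dag(n, which(adj == 1L, arr.ind = TRUE))
}

# Direct entropy helpers used to freeze expected acquisition values.
oracle_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Expression fixture: small SEM datasets shared across learner tests.
make_chain3_data <- function(n_per_series = 200, n_series = 5, seed = 3) {
  sem <- gaussian_sem(dag(3, rbind(c(1, 2), c(2, 3)), labels = c("A", "B", "C")),
                      seed = 2)
  simulate_expression(sem, n_series, n_per_series, seed = seed, perturb_sd = 0)
}

make_collider3_data <- function(n_per_series = 200, n_series = 5, seed = 3) {
  sem <- gaussian_sem(dag(3, rbind(c(1, 3), c(2, 3)), labels = c("A", "B", "C")),
                      seed = 2)
  simulate_expression(sem, n_series, n_per_series, seed = seed, perturb_sd = 0)
}

# Empty dataset on `genes`: every family score is the empty-data
# convention 0, so the structure posterior is flat.
flat_score_data <- function(genes) {
  out <- tibble::as_tibble(setNames(rep(list(numeric(0)), length(genes)),
                                    genes))
  out$intervention <- character(0)
  out
}
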