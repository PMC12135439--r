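#' Random ground-truth regulatory network
#'
#' Draws a network with exactly `n_edges` edges: `n_edges - n_back_edges`
#' edges placed on a random topological order (the acyclic part) plus
#' `n_back_edges` back-edges obtained by duplicating randomly chosen
#' acyclic-part edges in the reverse direction (reciprocal regulation).
#' Every back-edge therefore closes a cycle, and DAG repair removes
#' exactly `n_back_edges` edges.  Deterministic given `seed`.
#'
#' @param n_nodes Number of genes.
#' @param n_edges Total edge count.
#' @param n_back_edges Number of cycle-inducing back-edges.
#' @param seed Integer seed.
#' @param labels Optional gene names (default `G1 ... Gn`).
#' @return A `grn_dag` (cyclic when `n_back_edges > 0`).
#' @export
random_ground_truth <- function(n_nodes, n_edges, n_back_edges = 0, seed = 1,
                                labels = NULL) {
  n <- as.integer(n_nodes)
  n_dag <- n_edges - n_back_edges
  if (n_back_edges < 0 || n_dag < 0) stop("infeasible edge counts")
  if (n_dag > n * (n - 1) / 2) stop("too many edges for a DAG on n_nodes")
  if (n_back_edges > n_dag) stop("more back-edges than acyclic edges to reverse")
  labels <- labels %||% paste0("G", seq_len(n))
  withr::with_seed(seed, {
    ord <- sample.int(n)  # ord[k] = node at topological position k
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- sample.int(nrow(pairs), n_dag)
    fwd <- cbind(ord[pairs[pick, 1]], ord[pairs[pick, 2]])
    back_of <- fwd[sample.int(n_dag, n_back_edges), , drop = FALSE]
    dag(n, rbind(fwd, back_of[, 2:1, drop = FALSE]), labels = labels)
  })
}

#' Linear-Gaussian structural equation model over a gene network
#'
#' Assigns each edge of an acyclic regulatory graph a nonzero linear
#' coefficient and each gene a noise standard deviation and baseline
#' expression.  Edge weights default to uniform draws from
#' `+-[0.5, 1.5]` (signed), avoiding near-unidentifiable tiny effects.
#'
#' @param graph An acyclic `grn_dag`.
#' @param weight_range Magnitude range for edge coefficients.
#' @param noise_sd Per-gene noise standard deviation (recycled).
#' @param baseline Per-gene basal expression (recycled).  The default of
#'   1 keeps unperturbed expression away from the knockout clamp value 0:
#'   abolishing a gene then shifts its targets' means, which is the
#'   signal that lets interventional data orient edges (clamping a gene
#'   to its own basal mean would be uninformative).
#' @param seed Seed for the weight draw.
#' @return An object of class `grn_sem`.
#' @export
gaussian_sem <- function(graph, weight_range = c(0.5, 1.5), noise_sd = 1,
                         baseline = 1, seed = 1) {
  stopifnot(inherits(graph, "grn_dag"))
  if (!is_acyclic(graph)) stop("SEM graph must be acyclic")
  n <- graph$n_nodes
  e <- edges(graph)
  W <- matrix(0, n, n)
  if (nrow(e) > 0) {
    w <- withr::with_seed(seed, {
      runif(nrow(e), weight_range[1], weight_range[2]) *
        sample(c(-1, 1), nrow(e), replace = TRUE)
    })
    W[cbind(e$from, e$to)] <- w
  }
  noise_sd <- rep_len(noise_sd, n)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  structure(list(graph = graph, weights = W, noise_sd = noise_sd,
                 baseline = rep_len(baseline, n), labels = graph$labels),
            class = "grn_sem")
}

#' @export
print.grn_sem <- function(x, ...) {
  cat(sprintf("<grn_sem> linear-Gaussian SEM over %d genes, %d edges\n",
              x$graph$n_nodes, n_edges(x$graph)))
  invisible(x)
}

#' Closed-form observational covariance of a linear-Gaussian SEM
#'
#' `(I - W)^-T D (I - W)^-1` with `W` the weighted adjacency and `D` the
#' diagonal noise covariance (series perturbation offsets excluded).
#'
#' @param sem A `grn_sem`.
#' @return Covariance matrix of the stationary observational draw.
#' @export
sem_covariance <- function(sem) {
  n <- sem$graph$n_nodes
  A <- solve(diag(n) - sem$weights)  # x = (I - W)^-1' applied to noise
  t(A) %*% diag(sem$noise_sd^2, n) %*% A
}

#' Simulate expression series from a SEM
#'
#' Emulates perturbation time series: each series draws a random per-gene
#' perturbation offset, then generates `n_timepoints` independent samples
#' by propagating baseline + offset + parent contributions + Gaussian
#' noise through the genes in topological order.  Under a knockout the
#' target gene is clamped to `clamp` in every sample and its incoming
#' mechanism is inert, while its clamped value still feeds its targets
#' (a perfect intervention).
#'
#' @param sem A `grn_sem`.
#' @param n_series Number of perturbation series.
#' @param n_timepoints Samples per series.
#' @param intervention Gene index (or label) to knock out, or `NULL`.
#' @param seed Integer seed.
#' @param perturb_sd Standard deviation of the per-series perturbation
#'   offsets.
#' @param clamp Knockout expression value (default 0: abolished).
#' @return A tibble with one column per gene plus `intervention`
#'   (`"none"` or the gene label), `series` and `time` columns.
#' @export
simulate_expression <- function(sem, n_series, n_timepoints,
                                intervention = NULL, seed = 1,
                                perturb_sd = 1, clamp = 0) {
  stopifnot(inherits(sem, "grn_sem"))
  n <- sem$graph$n_nodes
  labels <- sem$labels %||% paste0("G", seq_len(n))
  iv <- NULL
  if (!is.null(intervention)) {
    iv <- if (is.character(intervention)) match(intervention, labels) else as.integer(intervention)
    if (is.na(iv) || iv < 1 || iv > n) stop("unknown intervention gene")
  }
  ord <- topological_order(sem$graph$adj)
  rows <- withr::with_seed(seed, {
    out <- vector("list", n_series)
    for (s in seq_len(n_series)) {
      offset <- rnorm(n, 0, perturb_sd)
      X <- matrix(0, n_timepoints, n)
      eps <- matrix(rnorm(n_timepoints * n), n_timepoints, n) *
        rep(sem$noise_sd, each = n_timepoints)
      for (j in ord) {
        if (!is.null(iv) && j == iv) {
          X[, j] <- clamp
        } else {
          pa <- which(sem$weights[, j] != 0)
          contrib <- if (length(pa)) X[, pa, drop = FALSE] %*% sem$weights[pa, j] else 0
          X[, j] <- sem$baseline[j] + offset[j] + contrib + eps[, j]
        }
      }
      out[[s]] <- X
    }
    out
  })
  values <- do.call(rbind, rows)
  colnames(values) <- labels
  dplyr::bind_cols(
    tibble::as_tibble(values),
    tibble::tibble(
      intervention = if (is.null(iv)) "none" else labels[iv],
      series = rep(seq_len(n_series), each = n_timepoints),
      time = rep(seq_len(n_timepoints), times = n_series)
    )
  )
}

#' GeneNetWeaver-scale synthetic benchmark fixture
#'
#' Builds the package's stand-in for the DREAM4 GeneNetWeaver example
#' setup: a 64-gene, 207-edge reference network whose 21 cycle-inducing
#' edges are removed by DAG repair; the essential graph (CPDAG) of the
#' repaired DAG as reference PDAG; 10 observational perturbation series
#' of 21 time points (210 samples); and one 21-sample knockout series per
#' gene (64 x 21 = 1,344 interventional samples).  Fully deterministic
#' given `seed`.
#'
#' @param seed Integer seed.
#' @param n_nodes,n_edges,n_back_edges,n_series,n_timepoints Shape
#'   parameters, defaulting to the GeneNetWeaver example scale.
#' @return A list with elements `truth` (cyclic reference `grn_dag`),
#'   `dag` (repaired DAG), `removed` (tibble of repaired-away edges),
#'   `reference_pdag` (`grn_pdag`), `sem`, `observational` (tibble) and
#'   `knockout_pool` (named list of per-gene knockout tibbles).
#' @export
gnw_scale_fixture <- function(seed = 1, n_nodes = 64, n_edges = 207,
                              n_back_edges = 21, n_series = 10,
                              n_timepoints = 21) {
  truth <- random_ground_truth(n_nodes, n_edges, n_back_edges, seed = seed)
  rep_ <- repair_to_dag(truth)
  reference_pdag <- cpdag(rep_$dag)
  sem <- gaussian_sem(rep_$dag, seed = seed + 1L)
  observational <- simulate_expression(sem, n_series, n_timepoints,
                                       seed = seed + 2L)
  labels <- truth$labels
  knockout_pool <- lapply(seq_len(n_nodes), function(g) {
    simulate_expression(sem, 1, n_timepoints, intervention = g,
                        seed = seed + 2L + g)
  })
  names(knockout_pool) <- labels
  list(truth = truth, dag = rep_$dag, removed = rep_$removed,
       reference_pdag = reference_pdag, sem = sem,
       observational = observational, knockout_pool = knockout_pool)
}
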