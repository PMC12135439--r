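#' Posterior sample set over network structures
#'
#' A weighted collection of sampled DAGs, the package's interchange format
#' between structure samplers and acquisition functions.  Weights default
#' to uniform; `group_ids` optionally assign each sample to an ensemble
#' member (an MCMC chain or replicate), which the BALD-style acquisition
#' functions use to measure between-member disagreement.
#'
#' @param graphs List of acyclic `grn_dag` objects over a common gene set.
#' @param weights Optional non-negative weights, one per sample
#'   (normalized to sum to 1).
#' @param group_ids Optional integer/character vector assigning each
#'   sample to an ensemble member.
#'
#' @return An object of class `grn_posterior`.
#' @export
posterior_samples <- function(graphs, weights = NULL, group_ids = NULL) {
  stopifnot(is.list(graphs), length(graphs) >= 1)
  n <- graphs[[1]]$n_nodes
  for (g in graphs) {
    if (!inherits(g, "grn_dag")) stop("all samples must be grn_dag objects")
    if (g$n_nodes != n) stop("all samples must share n_nodes")
    if (!is_acyclic(g)) stop("all samples must be acyclic")
  }
  if (is.null(weights)) {
    weights <- rep(1 / length(graphs), length(graphs))
  } else {
    if (length(weights) != length(graphs)) stop("one weight per sample required")
    if (any(weights < 0)) stop("weights must be non-negative")
    s <- sum(weights)
    if (s <= 0) stop("weights must not all be zero")
    weights <- weights / s
  }
  if (!is.null(group_ids) && length(group_ids) != length(graphs))
    stop("one group id per sample required")
  structure(list(graphs = graphs, weights = weights, group_ids = group_ids,
                 n_nodes = n, labels = graphs[[1]]$labels),
            class = "grn_posterior")
}

#' @export
print.grn_posterior <- function(x, ...) {
  cat(sprintf("<grn_posterior> %d sampled DAGs over %d genes%s\n",
              length(x$graphs), x$n_nodes,
              if (is.null(x$group_ids)) ""
              else sprintf(", %d ensemble groups", length(unique(x$group_ids)))))
  invisible(x)
}

#' Three-state edge distribution of a posterior sample set
#'
#' For every ordered gene pair, the weighted fraction of sampled DAGs
#' containing the edge `i -> j`; per unordered pair the three
#' probabilities forward / reverse / absent sum to one because DAG samples
#' never carry both orientations.
#'
#' @param s A `grn_posterior`.
#' @return An object of class `grn_edge_dist` with matrix field `p_fwd`
#'   (`p_rev` is its transpose, `p_none` the complement).
#' @export
edge_state_distribution <- function(s) {
  stopifnot(inherits(s, "grn_posterior"))
  if (length(s$graphs) == 0) stop("empty sample set")
  p <- matrix(0, s$n_nodes, s$n_nodes)
  for (k in seq_along(s$graphs)) p <- p + s$weights[k] * s$graphs[[k]]$adj
  edge_dist_from_matrix(p, s$labels)
}

#' Build edge-state distributions from probability matrices
#'
#' Constructors for users bringing their own posterior summaries (for
#' example soft adjacency matrices from an external sampler) instead of
#' a sample set.  `as_edge_dist()` takes the `n x n` matrix of directed
#' edge probabilities `P(i -> j)`; `as_pdag_dist()` additionally takes
#' the symmetric undirected-state probabilities `P(i - j)`.  Per
#' unordered pair the states must not exceed total probability 1; the
#' remainder is the no-edge state.
#'
#' @param p_fwd Matrix of forward-edge probabilities (diagonal ignored).
#' @param labels Optional gene names.
#' @return An object of class `grn_edge_dist`.
#' @export
as_edge_dist <- function(p_fwd, labels = NULL) {
  p_fwd <- as.matrix(p_fwd)
  check_prob_matrix(p_fwd + t(p_fwd))
  edge_dist_from_matrix(p_fwd, labels)
}

#' @rdname as_edge_dist
#' @param p_undir Symmetric matrix of undirected-state probabilities.
#' @export
as_pdag_dist <- function(p_fwd, p_undir, labels = NULL) {
  p_fwd <- as.matrix(p_fwd)
  p_undir <- as.matrix(p_undir)
  if (any(abs(p_undir - t(p_undir)) > 1e-9)) stop("p_undir must be symmetric")
  check_prob_matrix(p_fwd + t(p_fwd) + p_undir)
  pdag_dist_from_matrices(p_fwd, p_undir, labels)
}

check_prob_matrix <- function(total) {
  diag(total) <- 0
  if (any(total < -1e-9 | total > 1 + 1e-9))
    stop("per-pair state probabilities must lie in [0, 1]")
  invisible(TRUE)
}

edge_dist_from_matrix <- function(p_fwd, labels = NULL) {
  diag(p_fwd) <- 0
  structure(list(n_nodes = nrow(p_fwd), p_fwd = p_fwd, labels = labels),
            class = "grn_edge_dist")
}

#' @export
print.grn_edge_dist <- function(x, ...) {
  cat(sprintf("<grn_edge_dist> 3-state edge probabilities over %d genes\n",
              x$n_nodes))
  invisible(x)
}

p_rev <- function(d) t(d$p_fwd)
p_none_dag <- function(d) {
  out <- 1 - d$p_fwd - t(d$p_fwd)
  diag(out) <- 0
  out
}

#' Four-state essential-graph edge distribution
#'
#' Each sampled DAG is first mapped to its essential graph (CPDAG); the
#' per-pair weighted frequencies of the four CPDAG states forward /
#' reverse / undirected / absent are collected.  CPDAG conversion is
#' cached by graph hash because sample sets routinely contain duplicates.
#'
#' @param s A `grn_posterior`.
#' @return An object of class `grn_pdag_dist` with matrix fields `p_fwd`
#'   (directed-state probabilities, `p_rev` its transpose) and `p_undir`
#'   (symmetric).
#' @export
pdag_state_distribution <- function(s) {
  stopifnot(inherits(s, "grn_posterior"))
  if (length(s$graphs) == 0) stop("empty sample set")
  n <- s$n_nodes
  pf <- matrix(0, n, n)
  pu <- matrix(0, n, n)
  cache <- new.env(parent = emptyenv())
  for (k in seq_along(s$graphs)) {
    cp <- cached_cpdag(s$graphs[[k]], cache)
    pf <- pf + s$weights[k] * cp$dir
    pu <- pu + s$weights[k] * cp$undir
  }
  pdag_dist_from_matrices(pf, pu, s$labels)
}

cached_cpdag <- function(g, cache) {
  key <- paste0("k", paste(which(g$adj == 1L), collapse = ","))
  got <- cache[[key]]
  if (!is.null(got)) return(got)
  cp <- cpdag(g)
  cache[[key]] <- cp
  cp
}

pdag_dist_from_matrices <- function(p_fwd, p_undir, labels = NULL) {
  diag(p_fwd) <- 0
  diag(p_undir) <- 0
  structure(list(n_nodes = nrow(p_fwd), p_fwd = p_fwd, p_undir = p_undir,
                 labels = labels),
            class = "grn_pdag_dist")
}

#' @export
print.grn_pdag_dist <- function(x, ...) {
  cat(sprintf("<grn_pdag_dist> 4-state essential-graph edge probabilities over %d genes\n",
              x$n_nodes))
  invisible(x)
}

p_none_pdag <- function(d) {
  out <- 1 - d$p_fwd - t(d$p_fwd) - d$p_undir
  diag(out) <- 0
  out
}

#' Ensemble-member edge distributions
#'
#' Splits a posterior sample set into ensemble members and computes one
#' edge-state distribution per member.  Members follow `group_ids` when
#' present, otherwise the samples are divided into `n_groups` contiguous
#' blocks.  Each returned distribution carries attribute `weight`, the
#' member's share of total sample weight; the weighted mean of member
#' distributions equals the pooled distribution.
#'
#' @param s A `grn_posterior`.
#' @param n_groups Number of contiguous blocks when `group_ids` is absent.
#' @param type `"dag"` for 3-state members (`grn_edge_dist`), `"pdag"`
#'   for 4-state essential-graph members (`grn_pdag_dist`).
#' @return A list of distributions, one per ensemble member.
#' @export
ensemble_marginals <- function(s, n_groups = 8, type = c("dag", "pdag")) {
  stopifnot(inherits(s, "grn_posterior"))
  type <- match.arg(type)
  m <- length(s$graphs)
  if (!is.null(s$group_ids)) {
    ids <- s$group_ids
  } else {
    if (n_groups > m) stop("n_groups exceeds the number of samples")
    ids <- ceiling(seq_len(m) / (m / n_groups))
  }
  groups <- split(seq_len(m), ids)
  purrr::map(groups, function(idx) {
    w <- s$weights[idx]
    sub <- posterior_samples(s$graphs[idx], weights = w)
    d <- if (type == "dag") edge_state_distribution(sub) else pdag_state_distribution(sub)
    attr(d, "weight") <- sum(w)
    d
  })
}

#' Tidy edge-state distributions
#'
#' @param x A `grn_edge_dist` or `grn_pdag_dist`.
#' @param ... Unused.
#' @return A tibble with one row per unordered gene pair (`from < to`)
#'   and the per-state probabilities.
#' @method tidy grn_edge_dist
#' @export
tidy.grn_edge_dist <- function(x, ...) {
  up <- which(upper.tri(x$p_fwd), arr.ind = TRUE)
  tibble::tibble(
    from = as.integer(up[, 1]), to = as.integer(up[, 2]),
    p_fwd = x$p_fwd[up], p_rev = t(x$p_fwd)[up], p_none = p_none_dag(x)[up]
  )
}

#' @rdname tidy.grn_edge_dist
#' @method tidy grn_pdag_dist
#' @export
tidy.grn_pdag_dist <- function(x, ...) {
  up <- which(upper.tri(x$p_fwd), arr.ind = TRUE)
  tibble::tibble(
    from = as.integer(up[, 1]), to = as.integer(up[, 2]),
    p_fwd = x$p_fwd[up], p_rev = t(x$p_fwd)[up],
    p_undir = x$p_undir[up], p_none = p_none_pdag(x)[up]
  )
}

#' Posterior summary
#'
#' @param x A `grn_posterior`.
#' @param ... Unused.
#' @return A one-row tibble with sample count, gene count, expected edge
#'   count and effective sample size of the weights.
#' @method glance grn_posterior
#' @export
glance.grn_posterior <- function(x, ...) {
  nnz <- sum(vapply(seq_along(x$graphs),
                    function(k) x$weights[k] * sum(x$graphs[[k]]$adj), 0))
  tibble::tibble(
    n_samples = length(x$graphs),
    n_genes = x$n_nodes,
    expected_edges = nnz,
    ess = 1 / sum(x$weights^2)
  )
}
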