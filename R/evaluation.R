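#' Posterior-quality metrics against a reference network
#'
#' Posterior-weighted expectations over the sampled DAGs of: directed and
#' undirected (skeleton) structural Hamming distance to the reference
#' DAG; SHD between each sample's essential graph and the reference PDAG;
#' number of predicted edges (NNZ); and recall of the reference edges.
#' `recall` counts an edge only when its orientation is correct;
#' `recall_skeleton` counts adjacency regardless of orientation (the
#' orientation-blind variant).
#'
#' @param s A `grn_posterior`.
#' @param truth Reference `grn_dag` (the repaired acyclic network).
#' @param reference_pdag Optional reference `grn_pdag` (essential graph
#'   of `truth`); computed from `truth` when omitted.
#' @return A one-row tibble with columns `shd_directed`,
#'   `shd_undirected`, `shd_pdag`, `nnz`, `recall`, `recall_skeleton`.
#' @export
evaluate_posterior <- function(s, truth, reference_pdag = NULL) {
  stopifnot(inherits(s, "grn_posterior"), inherits(truth, "grn_dag"))
  if (s$n_nodes != truth$n_nodes) stop("posterior and truth node sets differ")
  reference_pdag <- reference_pdag %||% cpdag(truth)
  if (reference_pdag$n_nodes != truth$n_nodes) stop("reference PDAG node set differs")
  t_adj <- truth$adj
  n_true <- sum(t_adj)
  t_skel <- (t_adj | t(t_adj)) * 1L
  cache <- new.env(parent = emptyenv())
  acc <- c(shd_directed = 0, shd_undirected = 0, shd_pdag = 0, nnz = 0,
           recall = 0, recall_skeleton = 0)
  for (k in seq_along(s$graphs)) {
    g <- s$graphs[[k]]
    w <- s$weights[k]
    if (w == 0) next
    cp <- cached_cpdag(g, cache)
    s_skel <- (g$adj | t(g$adj)) * 1L
    rec <- if (n_true > 0) sum(g$adj & t_adj) / n_true else 1
    rec_sk <- if (n_true > 0) sum(s_skel & t_skel & upper.tri(t_skel)) /
      sum(t_skel[upper.tri(t_skel)]) else 1
    acc <- acc + w * c(
      shd(g, truth, "directed"),
      shd(g, truth, "undirected"),
      shd(cp, reference_pdag, "pdag"),
      sum(g$adj), rec, rec_sk
    )
  }
  tibble::tibble(!!!as.list(acc))
}
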