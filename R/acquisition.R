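# Shannon term with the 0 * log 0 := 0 convention; base-2 logs are used
# throughout, which is irrelevant after normalization by log(#states).
xlg <- function(p) {
  out <- p * 0
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

score_matrix <- function(m, name, labels = NULL) {
  diag(m) <- 0
  m[m < 0] <- 0  # absorb floating-point residue
  structure(list(n_nodes = nrow(m), value = m, function_name = name,
                 labels = labels),
            class = "grn_scores")
}

#' @export
print.grn_scores <- function(x, ...) {
  cat(sprintf("<grn_scores> %s pair scores over %d genes (max %.3f)\n",
              x$function_name, x$n_nodes, max(x$value)))
  invisible(x)
}

#' Tidy a pairwise score matrix
#'
#' @param x A `grn_scores` object.
#' @param ... Unused.
#' @return Tibble with one row per unordered pair and its score.
#' @method tidy grn_scores
#' @export
tidy.grn_scores <- function(x, ...) {
  up <- which(upper.tri(x$value), arr.ind = TRUE)
  tibble::tibble(from = as.integer(up[, 1]), to = as.integer(up[, 2]),
                 score = x$value[up], function_name = x$function_name)
}

#' Edge Entropy over the three DAG edge states
#'
#' Per unordered gene pair, the Shannon entropy of the distribution over
#' \{`i -> j`, `i <- j`, no edge\}, normalized by `log(3)` so that the
#' uniform distribution scores 1 and a degenerate one scores 0.  The
#' normalization keeps the `(1 - H)` certainty factor of the knockout
#' score well defined.
#'
#' @param d A `grn_edge_dist`.
#' @return A symmetric `grn_scores` matrix with entries in `[0, 1]`.
#' @export
edge_entropy <- function(d) {
  stopifnot(inherits(d, "grn_edge_dist"))
  h <- -(xlg(d$p_fwd) + xlg(t(d$p_fwd)) + xlg(p_none_dag(d))) / log2(3)
  score_matrix(h, "entropy", d$labels)
}

#' Direction entropy of an essential-graph edge distribution
#'
#' The binary entropy of the edge's orientation, conditional on the edge
#' being oriented: with `q = p_fwd / (p_fwd + p_rev)`, the score is
#' `H2(q) / log 2`, and 0 by convention when no oriented mass exists.
#' Set `renormalize = FALSE` for the literal two-term entropy of the raw
#' marginals (not guaranteed to stay within `[0, 1]`).
#'
#' @param d A `grn_pdag_dist`.
#' @param renormalize Condition on an oriented edge (default) or use raw
#'   marginal probabilities.
#' @return A symmetric `grn_scores` matrix.
#' @export
direction_entropy <- function(d, renormalize = TRUE) {
  stopifnot(inherits(d, "grn_pdag_dist"))
  pf <- d$p_fwd
  pr <- t(d$p_fwd)
  if (renormalize) {
    s <- pf + pr
    q <- ifelse(s > 0, pf / s, 0)
    h <- -(xlg(q) + xlg(1 - q))
    h[s == 0] <- 0
  } else {
    h <- -(xlg(pf) + xlg(pr))
  }
  score_matrix(h, "direction_entropy", d$labels)
}

#' Four-state essential-graph edge entropy
#'
#' Entropy over \{forward, reverse, undirected, absent\}, normalized by
#' `log(4)`.
#'
#' @param d A `grn_pdag_dist`.
#' @return A symmetric `grn_scores` matrix with entries in `[0, 1]`.
#' @export
four_state_entropy <- function(d) {
  stopifnot(inherits(d, "grn_pdag_dist"))
  h <- -(xlg(d$p_fwd) + xlg(t(d$p_fwd)) + xlg(d$p_undir) + xlg(p_none_pdag(d))) / 2
  score_matrix(h, "four_state_entropy", d$labels)
}

member_weights <- function(members) {
  w <- vapply(members, function(m) attr(m, "weight") %||% NA_real_, 0)
  if (anyNA(w)) w <- rep(1, length(members))
  w / sum(w)
}

pool_edge_dists <- function(members, w) {
  p <- Reduce(`+`, Map(function(m, wk) wk * m$p_fwd, members, w))
  edge_dist_from_matrix(p, members[[1]]$labels)
}

pool_pdag_dists <- function(members, w) {
  pf <- Reduce(`+`, Map(function(m, wk) wk * m$p_fwd, members, w))
  pu <- Reduce(`+`, Map(function(m, wk) wk * m$p_undir, members, w))
  pdag_dist_from_matrices(pf, pu, members[[1]]$labels)
}

#' BALD over the three DAG edge states
#'
#' Bayesian Active Learning by Disagreement: the mutual information
#' between the edge state and the ensemble member, computed per pair as
#' the Edge Entropy of the pooled (mean) distribution minus the mean of
#' the members' Edge Entropies.  Zero when members agree; never exceeds
#' the pooled entropy; small negative rounding residue is clipped to 0.
#'
#' @param members List of `grn_edge_dist` ensemble members (e.g. from
#'   [ensemble_marginals()]); optional `weight` attributes set the member
#'   weights.
#' @return A symmetric `grn_scores` matrix.
#' @export
bald <- function(members) {
  stopifnot(is.list(members), length(members) >= 1)
  w <- member_weights(members)
  h_mean <- edge_entropy(pool_edge_dists(members, w))$value
  mean_h <- Reduce(`+`, Map(function(m, wk) wk * edge_entropy(m)$value, members, w))
  score_matrix(h_mean - mean_h, "bald", members[[1]]$labels)
}

#' Sample an undirectedness mask
#'
#' For every unordered gene pair independently, draw
#' `U[i, j] ~ Bernoulli(P(i - j))` from the essential-graph undirected
#' probability, mirror to the lower triangle, and zero the diagonal.
#' The equivalence-class acquisition functions use `U` to switch between
#' "resolve the direction" and "resolve the whole edge state" per pair.
#'
#' @param d A `grn_pdag_dist`.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `grn_mask` with 0/1 symmetric matrix `u`.
#' @export
sample_undirected_mask <- function(d, seed = NULL) {
  stopifnot(inherits(d, "grn_pdag_dist"))
  n <- d$n_nodes
  draw <- function() {
    u <- matrix(0L, n, n)
    up <- upper.tri(u)
    u[up] <- as.integer(runif(sum(up)) < d$p_undir[up])
    u[lower.tri(u)] <- t(u)[lower.tri(u)]
    u
  }
  u <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(n_nodes = n, u = u, seed = seed), class = "grn_mask")
}

#' Equivalence Class Entropy Sampling (ECES)
#'
#' Per pair, the direction entropy where the sampled mask flags the pair
#' as likely undirected, and the four-state essential-graph entropy on the
#' complement:
#' `ECES = H_dir * U + H_4 * (1 - U)`.
#'
#' @param d A `grn_pdag_dist`.
#' @param mask A `grn_mask` from [sample_undirected_mask()].
#' @return A symmetric `grn_scores` matrix.
#' @export
eces <- function(d, mask) {
  stopifnot(inherits(d, "grn_pdag_dist"), inherits(mask, "grn_mask"))
  if (mask$n_nodes != d$n_nodes) stop("mask and distribution dimensions differ")
  v <- direction_entropy(d)$value * mask$u +
    four_state_entropy(d)$value * (1 - mask$u)
  score_matrix(v, "eces", d$labels)
}

#' Equivalence-class BALD (EBALD)
#'
#' BALD computed in the essential-graph space: per pair the
#' direction-entropy disagreement on the masked entries and the
#' four-state-entropy disagreement on the complement, each bracket being
#' `H(pooled) - mean(H(member))` clipped at 0.
#'
#' @param members List of `grn_pdag_dist` ensemble members.
#' @param mask A `grn_mask`.
#' @return A symmetric `grn_scores` matrix.
#' @export
ebald <- function(members, mask) {
  stopifnot(is.list(members), length(members) >= 1, inherits(mask, "grn_mask"))
  w <- member_weights(members)
  pooled <- pool_pdag_dists(members, w)
  bald_dir <- direction_entropy(pooled)$value -
    Reduce(`+`, Map(function(m, wk) wk * direction_entropy(m)$value, members, w))
  bald_four <- four_state_entropy(pooled)$value -
    Reduce(`+`, Map(function(m, wk) wk * four_state_entropy(m)$value, members, w))
  bald_dir[bald_dir < 0] <- 0
  bald_four[bald_four < 0] <- 0
  score_matrix(bald_dir * mask$u + bald_four * (1 - mask$u), "ebald",
               members[[1]]$labels)
}

#' Per-gene incoming uncertainty
#'
#' Sums each gene's pairwise uncertainty scores: genes with the largest
#' total are the ones with the most "problematic" (uncertain) incoming
#' edges, the targets whose mechanisms an experiment should pin down.
#'
#' @param pair_scores A symmetric `grn_scores` matrix.
#' @return Numeric vector of per-gene scores (column sums).
#' @export
node_uncertainty <- function(pair_scores) {
  stopifnot(inherits(pair_scores, "grn_scores"))
  colSums(pair_scores$value)
}

#' Knockout candidate scores
#'
#' Ranks genes as knockout candidates: a gene scores highly when it is a
#' certain (`1 - score`), probable (`p_fwd`) parent of genes whose
#' incoming edges carry high total uncertainty.  Per gene `i`:
#' `sum_j (1 - S[i, j]) * p_fwd[i, j] * u[j]` with
#' `u = node_uncertainty(S)`.  Knocking out such a parent perturbs the
#' uncertain targets through a mechanism the posterior already trusts,
#' which is what makes the resulting samples informative.
#'
#' @param pair_scores A symmetric `grn_scores` matrix (edge entropy, BALD,
#'   ECES or EBALD).
#' @param d A `grn_edge_dist` supplying the DAG-space parent
#'   probabilities `p_fwd`.
#' @return Numeric vector of per-gene knockout scores.
#' @export
knockout_scores <- function(pair_scores, d) {
  stopifnot(inherits(pair_scores, "grn_scores"), inherits(d, "grn_edge_dist"))
  if (pair_scores$n_nodes != d$n_nodes) stop("dimension mismatch")
  u <- node_uncertainty(pair_scores)
  as.numeric(((1 - pair_scores$value) * d$p_fwd) %*% u)
}

#' Select an intervention batch
#'
#' @param node_scores Numeric per-gene scores.
#' @param k Batch size.
#' @param mode `"argmax"` picks the `k` highest-scoring genes (ties broken
#'   by smallest index); `"uniform"` draws `k` genes uniformly without
#'   replacement.
#' @param seed Optional seed for the uniform draw.
#' @param exclude Optional gene indices ineligible this round.
#' @return Integer vector of `k` distinct gene indices.
#' @export
select_interventions <- function(node_scores, k,
                                 mode = c("argmax", "uniform"),
                                 seed = NULL, exclude = NULL) {
  mode <- match.arg(mode)
  eligible <- setdiff(seq_along(node_scores), exclude)
  if (k > length(eligible)) stop("batch size exceeds the number of eligible genes")
  if (mode == "argmax") {
    ord <- eligible[order(-node_scores[eligible], eligible)]
    return(ord[seq_len(k)])
  }
  draw <- function() sample(eligible, k, replace = FALSE)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Score and select knockout experiments from a posterior
#'
#' One acquisition round: condense the posterior sample set into the
#' distribution the chosen acquisition function needs (3-state DAG
#' distribution for `entropy`/`bald`, 4-state essential-graph distribution
#' for `eces`/`ebald`), compute pairwise scores, aggregate them into
#' per-gene knockout scores, and pick the batch.  `uniform` ignores the
#' posterior and draws genes at random.
#'
#' @param posterior A `grn_posterior`.
#' @param method One of `"uniform"`, `"entropy"`, `"bald"`, `"eces"`,
#'   `"ebald"`.
#' @param batch_size Number of knockouts to select.
#' @param seed Seed for the undirectedness mask and/or the uniform draw.
#' @param n_groups Ensemble size for BALD-style methods when the
#'   posterior has no `group_ids`.
#' @param exclude Gene indices ineligible for selection.
#' @return An object of class `grn_acquisition` with fields `pair_scores`
#'   (`grn_scores`), `node_scores`, `selected` and `function_name`.
#' @export
acquire <- function(posterior, method = c("entropy", "bald", "eces", "ebald", "uniform"),
                    batch_size = 1, seed = NULL, n_groups = 8, exclude = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(posterior, "grn_posterior"))
  n <- posterior$n_nodes
  edist <- edge_state_distribution(posterior)
  if (method == "uniform") {
    pair <- score_matrix(matrix(0, n, n), "uniform", posterior$labels)
    node <- rep(0, n)
    sel <- select_interventions(node, batch_size, "uniform", seed, exclude)
  } else {
    pair <- switch(
      method,
      entropy = edge_entropy(edist),
      bald = bald(ensemble_marginals(posterior, n_groups, type = "dag")),
      eces = {
        pd <- pdag_state_distribution(posterior)
        eces(pd, sample_undirected_mask(pd, seed))
      },
      ebald = {
        pd <- pdag_state_distribution(posterior)
        ebald(ensemble_marginals(posterior, n_groups, type = "pdag"),
              sample_undirected_mask(pd, seed))
      }
    )
    node <- knockout_scores(pair, edist)
    sel <- select_interventions(node, batch_size, "argmax", exclude = exclude)
  }
  structure(list(pair_scores = pair, node_scores = node, selected = sel,
                 function_name = method, labels = posterior$labels),
            class = "grn_acquisition")
}

#' @export
print.grn_acquisition <- function(x, ...) {
  lab <- x$labels %||% paste0("G", seq_along(x$node_scores))
  cat(sprintf("<grn_acquisition> %s; selected: %s\n", x$function_name,
              paste(lab[x$selected], collapse = ", ")))
  invisible(x)
}

#' Tidy an acquisition result
#'
#' @param x A `grn_acquisition`.
#' @param ... Unused.
#' @return Tibble of per-gene knockout scores with selection flags.
#' @method tidy grn_acquisition
#' @export
tidy.grn_acquisition <- function(x, ...) {
  lab <- x$labels %||% paste0("G", seq_along(x$node_scores))
  tibble::tibble(
    gene = seq_along(x$node_scores),
    label = lab,
    score = x$node_scores,
    selected = seq_along(x$node_scores) %in% x$selected,
    function_name = x$function_name
  )
}
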