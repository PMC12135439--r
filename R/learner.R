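#' Learner configuration
#'
#' Settings shared by the reference posterior samplers.
#'
#' @param max_parents Fan-in cap per gene; GRNs are sparse and the cap
#'   bounds the local-score search space.
#' @param n_samples Total posterior samples to return (split across
#'   chains for MCMC).
#' @param n_chains Independent MCMC chains; chains double as the BALD
#'   ensemble members.
#' @param burn_in Discarded initial iterations per chain.
#' @param thinning Keep every `thinning`-th post-burn-in state.
#' @param seed Base seed; chain `c` runs under `seed + c - 1`.
#' @param score `"bic_gaussian"` (default, no prior hyperparameters) or
#'   `"bge"` (Gaussian-Wishart marginal likelihood).
#' @param bge_am,bge_aw BGe hyperparameters: prior precision of the mean
#'   (`alpha_mu`, default 1) and Wishart degrees of freedom (`alpha_w`,
#'   default `n_genes + 2`).
#' @return A list of class `grn_learner_config`.
#' @export
learner_config <- function(max_parents = 4, n_samples = 1000, n_chains = 8,
                           burn_in = 500, thinning = 5, seed = 1,
                           score = c("bic_gaussian", "bge"),
                           bge_am = 1, bge_aw = NULL) {
  score <- match.arg(score)
  stopifnot(max_parents >= 1, n_samples >= 1, n_chains >= 1,
            burn_in >= 0, thinning >= 1)
  structure(list(max_parents = as.integer(max_parents),
                 n_samples = as.integer(n_samples),
                 n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed), score = score,
                 bge_am = bge_am, bge_aw = bge_aw),
            class = "grn_learner_config")
}

# Columns of an expression tibble that are genes (everything except the
# per-sample annotations).
gene_columns <- function(data) {
  setdiff(names(data), c("intervention", "series", "time"))
}

# Per-sample intervention target as gene index (NA = observational).
intervention_targets <- function(data) {
  genes <- gene_columns(data)
  if (!"intervention" %in% names(data)) return(rep(NA_integer_, nrow(data)))
  iv <- as.character(data$intervention)
  out <- match(iv, genes)
  bad <- !is.na(iv) & iv != "none" & is.na(out)
  if (any(bad)) stop("intervention column names unknown genes: ",
                     paste(unique(iv[bad]), collapse = ", "))
  out
}

gene_matrix <- function(data) {
  as.matrix(data[, gene_columns(data), drop = FALSE])
}

#' Interventional Gaussian family score
#'
#' Decomposable local score of one gene given a candidate parent set,
#' computed only over samples in which the gene itself is \emph{not} the
#' intervention target (the truncated factorization of a perfect
#' knockout: the clamped gene's own mechanism is inert, but its clamped
#' value still acts as a predictor for its children).
#'
#' `bic_gaussian` is the maximized Gaussian log-likelihood of the linear
#' regression of the gene on its parents minus `(|parents| + 2)/2 log n`;
#' `bge` is the Gaussian-Wishart marginal likelihood (score-equivalent
#' across Markov-equivalent DAGs).
#'
#' @param data Expression tibble: gene columns plus optional
#'   `intervention` (gene name or `"none"`), `series`, `time` columns.
#' @param node Gene index to score.
#' @param parents Integer vector of parent gene indices (possibly empty).
#' @param score `"bic_gaussian"` or `"bge"`.
#' @param config Optional `grn_learner_config` supplying `score` and BGe
#'   hyperparameters.
#' @return Log score; 0 when no sample contributes, `-Inf` when the
#'   regression is singular or under-determined.
#' @export
family_score <- function(data, node, parents = integer(0),
                         score = NULL, config = NULL) {
  config <- config %||% learner_config()
  if (!is.null(score)) config$score <- match.arg(score, c("bic_gaussian", "bge"))
  scorer <- make_scorer(data, config)
  scorer(as.integer(node), sort(as.integer(parents)))
}

# Builds a memoized (node, parents) -> log score closure over one dataset.
make_scorer <- function(data, config) {
  X <- gene_matrix(data)
  iv <- intervention_targets(data)
  n_genes <- ncol(X)
  memo <- new.env(parent = emptyenv())
  # Sufficient statistics per distinct row subset (one per intervened gene
  # plus the all-rows subset shared by never-intervened genes).
  stats_cache <- new.env(parent = emptyenv())
  node_stats <- function(node) {
    key <- if (any(iv == node, na.rm = TRUE)) paste0("n", node) else "all"
    got <- stats_cache[[key]]
    if (!is.null(got)) return(got)
    rows <- is.na(iv) | iv != node
    Xs <- X[rows, , drop = FALSE]
    n <- nrow(Xs)
    st <- if (n == 0) {
      list(n = 0)
    } else {
      xbar <- colMeans(Xs)
      ctr <- sweep(Xs, 2, xbar)
      list(n = n, xbar = xbar, scatter = crossprod(ctr),
           xtx = crossprod(cbind(1, Xs)))
    }
    stats_cache[[key]] <- st
    st
  }
  if (config$score == "bge") {
    am <- config$bge_am
    aw <- config$bge_aw %||% (n_genes + am + 1)
    t0 <- am * (aw - n_genes - 1) / (am + 1)
  }
  function(node, parents) {
    key <- paste0(node, "|", paste(parents, collapse = ","))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    st <- node_stats(node)
    val <- if (st$n == 0) {
      0
    } else if (config$score == "bic_gaussian") {
      bic_family(st, node, parents)
    } else {
      bge_family(st, node, parents, am, aw, t0)
    }
    memo[[key]] <- val
    val
  }
}

bic_family <- function(st, node, parents) {
  n <- st$n
  p <- length(parents)
  if (n < p + 2) return(-Inf)
  idx <- c(1L, parents + 1L)  # intercept + parent columns in xtx
  Sxx <- st$xtx[idx, idx, drop = FALSE]
  Sxy <- st$xtx[idx, node + 1L]
  Syy <- st$xtx[node + 1L, node + 1L]
  beta <- tryCatch(solve(Sxx, Sxy), error = function(e) NULL)
  if (is.null(beta)) return(-Inf)
  rss <- max(Syy - sum(beta * Sxy), 1e-12)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  ll - (p + 2) / 2 * log(n)
}

# Gaussian-Wishart marginal-likelihood local score.  R is the posterior
# parameter matrix T0 + scatter + am*n/(am+n) * xbar xbar' (prior mean 0);
# the score is the log ratio of the set marginals for {node, parents} and
# {parents}.
bge_family <- function(st, node, parents, am, aw, t0) {
  n <- st$n
  nv <- length(st$xbar)
  p <- length(parents)
  R <- st$scatter + (am * n / (am + n)) * tcrossprod(st$xbar)
  diag(R) <- diag(R) + t0
  s2 <- c(parents, node)
  logdet <- function(idx) {
    if (length(idx) == 0) return(0)
    d <- determinant(R[idx, idx, drop = FALSE], logarithm = TRUE)
    as.numeric(d$modulus)
  }
  a_post <- (n + aw - nv + p + 1) / 2
  a_prior <- (aw - nv + p + 1) / 2
  if (a_prior <= 0) return(-Inf)
  -n / 2 * log(pi) + 0.5 * log(am / (am + n)) +
    lgamma(a_post) - lgamma(a_prior) +
    a_prior * (p + 1) * log(t0) - (a_prior - 0.5) * p * log(t0) -
    a_post * logdet(s2) + (a_post - 0.5) * logdet(parents)
}

# All DAG adjacency matrices on n nodes obeying a parent cap, via
# enumeration of the 3^{n(n-1)/2} pair-state assignments.
enumerate_dags <- function(n, max_parents = n - 1) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  states <- rep(0L, m)
  repeat {
    adj <- matrix(0L, n, n)
    fwd <- states == 1L
    rev_ <- states == 2L
    adj[pairs[fwd, , drop = FALSE]] <- 1L
    adj[pairs[rev_, 2:1, drop = FALSE]] <- 1L
    if (all(colSums(adj) <= max_parents) && is_acyclic(adj))
      out[[length(out) + 1L]] <- adj
    # next ternary number
    k <- 1L
    while (k <= m && states[k] == 2L) { states[k] <- 0L; k <- k + 1L }
    if (k > m) break
    states[k] <- states[k] + 1L
  }
  out
}

#' Exact structure posterior by enumeration
#'
#' Enumerates every DAG on the gene set (feasible for up to 5 genes),
#' scores each by the sum of its family scores, and returns the full
#' support weighted by the normalized exponentiated scores.  Serves as
#' the small-network oracle against which the MCMC sampler is checked.
#'
#' @param data Expression tibble (see [family_score()]).
#' @param config A `grn_learner_config`.
#' @return A `grn_posterior` holding every DAG with its posterior weight.
#' @export
exact_posterior <- function(data, config = learner_config()) {
  genes <- gene_columns(data)
  n <- length(genes)
  if (n > 5) stop("exact enumeration is limited to 5 genes")
  scorer <- make_scorer(data, config)
  adjs <- enumerate_dags(n, min(config$max_parents, n - 1))
  scores <- vapply(adjs, function(adj) {
    sum(vapply(seq_len(n), function(j) scorer(j, which(adj[, j] == 1L)), 0))
  }, 0)
  w <- exp(scores - max(scores))
  posterior_samples(purrr::map(adjs, dag_from_adj, labels = genes),
                    weights = w / sum(w))
}

#' Structure MCMC posterior sampler
#'
#' Metropolis-Hastings over DAG space with single-edge add / delete /
#' reverse proposals drawn uniformly over unordered gene pairs (a
#' symmetric proposal), respecting acyclicity and the fan-in cap.
#' `n_chains` independent chains start from the empty graph under seeds
#' `seed, seed + 1, ...`; thinned post-burn-in states are returned with
#' `group_ids` set to the chain index, so the chains double as the BALD
#' ensemble.
#'
#' @param data Expression tibble (see [family_score()]).
#' @param config A `grn_learner_config`.
#' @return A `grn_posterior` of `n_samples` sampled DAGs.
#' @export
mcmc_posterior <- function(data, config = learner_config()) {
  genes <- gene_columns(data)
  n <- length(genes)
  scorer <- make_scorer(data, config)
  per_chain <- ceiling(config$n_samples / config$n_chains)
  graphs <- list()
  group_ids <- integer(0)
  for (chain in seq_len(config$n_chains)) {
    kept <- withr::with_seed(config$seed + chain - 1L, {
      run_chain(n, scorer, config, per_chain)
    })
    graphs <- c(graphs, purrr::map(kept, dag_from_adj, labels = genes))
    group_ids <- c(group_ids, rep(chain, length(kept)))
  }
  posterior_samples(graphs, group_ids = group_ids)
}

run_chain <- function(n, scorer, config, n_keep) {
  adj <- matrix(0L, n, n)
  fam <- vapply(seq_len(n), function(j) scorer(j, integer(0)), 0)
  n_iter <- config$burn_in + n_keep * config$thinning
  kept <- vector("list", n_keep)
  k_out <- 0L
  if (n < 2) {
    for (s in seq_len(n_keep)) kept[[s]] <- adj
    return(kept)
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (it in seq_len(n_iter)) {
    pr <- pairs[sample.int(nrow(pairs), 1L), ]
    i <- pr[1]; j <- pr[2]
    coin <- runif(1)
    if (adj[i, j] == 0L && adj[j, i] == 0L) {
      # add, direction by coin
      if (coin < 0.5) { from <- i; to <- j } else { from <- j; to <- i }
      if (sum(adj[, to]) + 1L <= config$max_parents && !has_path(adj, to, from)) {
        new_fam <- scorer(to, sort(c(which(adj[, to] == 1L), from)))
        if (accept_mh(new_fam - fam[to])) {
          adj[from, to] <- 1L
          fam[to] <- new_fam
        }
      }
    } else {
      if (adj[i, j] == 1L) { from <- i; to <- j } else { from <- j; to <- i }
      if (coin < 0.5) {
        # delete
        new_fam <- scorer(to, setdiff(which(adj[, to] == 1L), from))
        if (accept_mh(new_fam - fam[to])) {
          adj[from, to] <- 0L
          fam[to] <- new_fam
        }
      } else {
        # reverse from->to to to->from
        adj[from, to] <- 0L
        ok <- sum(adj[, from]) + 1L <= config$max_parents &&
          !has_path(adj, from, to)
        if (ok) {
          new_to <- scorer(to, which(adj[, to] == 1L))
          new_from <- scorer(from, sort(c(which(adj[, from] == 1L), to)))
          if (accept_mh(new_to + new_from - fam[to] - fam[from])) {
            adj[to, from] <- 1L
            fam[to] <- new_to
            fam[from] <- new_from
          } else {
            adj[from, to] <- 1L
          }
        } else {
          adj[from, to] <- 1L
        }
      }
    }
    if (it > config$burn_in && (it - config$burn_in) %% config$thinning == 0L) {
      k_out <- k_out + 1L
      kept[[k_out]] <- adj
    }
  }
  kept[seq_len(k_out)]
}

accept_mh <- function(delta) {
  if (is.nan(delta)) return(FALSE)
  delta >= 0 || runif(1) < exp(delta)
}
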