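#' Simulated truth environment for active learning
#'
#' Wraps a ground-truth network and its simulator into the interface the
#' active loop consumes: observational data plus a knockout oracle.  The
#' oracle returns one fixed perturbation series per gene (generated
#' deterministically from `seed`, emulating a pre-simulated interventional
#' pool), so repeated acquisition of a gene re-appends the same series.
#'
#' @param n_nodes,n_edges,n_back_edges Ground-truth shape (see
#'   [random_ground_truth()]).
#' @param seed Integer seed controlling truth, SEM and all series.
#' @param n_series,n_timepoints Observational data shape.
#' @param knockout_timepoints Samples per knockout series.
#' @param perturb_sd Per-series perturbation-offset standard deviation
#'   for both observational and knockout series.  The default 0 draws
#'   i.i.d. samples, matching the i.i.d. likelihood of the reference
#'   samplers; set it positive to emulate per-series outside
#'   perturbations (which the reference samplers treat as extra,
#'   block-correlated noise).
#' @param ... Passed to [gaussian_sem()] (e.g. `weight_range`,
#'   `noise_sd`).
#' @return A list of class `grn_truth_env` with elements `observational`,
#'   `knockout` (function of gene index), `truth` (repaired DAG),
#'   `reference_pdag`, `sem` and `labels`.
#' @export
simulated_truth_env <- function(n_nodes, n_edges, n_back_edges = 0, seed = 1,
                                n_series = 10, n_timepoints = 21,
                                knockout_timepoints = 21, perturb_sd = 0,
                                ...) {
  truth <- random_ground_truth(n_nodes, n_edges, n_back_edges, seed = seed)
  rep_ <- repair_to_dag(truth)
  sem <- gaussian_sem(rep_$dag, seed = seed + 1L, ...)
  obs <- simulate_expression(sem, n_series, n_timepoints, seed = seed + 2L,
                             perturb_sd = perturb_sd)
  pool <- new.env(parent = emptyenv())
  knockout <- function(gene) {
    key <- as.character(gene)
    got <- pool[[key]]
    if (is.null(got)) {
      got <- simulate_expression(sem, 1, knockout_timepoints,
                                 intervention = gene,
                                 seed = seed + 2L + as.integer(gene),
                                 perturb_sd = perturb_sd)
      pool[[key]] <- got
    }
    got
  }
  structure(list(observational = obs, knockout = knockout,
                 truth = rep_$dag, reference_pdag = cpdag(rep_$dag),
                 sem = sem, labels = truth$labels),
            class = "grn_truth_env")
}

#' Truth environment backed by a pre-generated fixture
#'
#' @param fixture A list as returned by [gnw_scale_fixture()].
#' @return A `grn_truth_env` whose knockout oracle serves the fixture's
#'   pre-simulated per-gene series.
#' @export
as_truth_env <- function(fixture) {
  structure(list(
    observational = fixture$observational,
    knockout = function(gene) fixture$knockout_pool[[as.integer(gene)]],
    truth = fixture$dag, reference_pdag = fixture$reference_pdag,
    sem = fixture$sem, labels = fixture$truth$labels
  ), class = "grn_truth_env")
}

#' Active-learning loop configuration
#'
#' @param acquisition One of `"uniform"`, `"entropy"`, `"bald"`,
#'   `"eces"`, `"ebald"`.
#' @param batch_size Knockouts acquired per round.
#' @param max_rounds Experiment budget in rounds.
#' @param learner A `grn_learner_config`.
#' @param sampler `"mcmc"`, `"exact"`, or a function
#'   `(data, learner_config) -> grn_posterior` implementing the pluggable
#'   sampler interface.
#' @param seed Loop-level seed (drives acquisition masks, uniform draws
#'   and per-round learner seeds).
#' @param n_groups BALD ensemble size when the posterior lacks group ids.
#' @param exclude_intervened Make already-knocked-out genes ineligible in
#'   later rounds.
#' @param stop_metric,stop_threshold Optional early stop: end when the
#'   named [evaluate_posterior()] metric (e.g. `"shd_directed"`) drops to
#'   or below the threshold after retraining.
#' @return A list of class `grn_loop_config`.
#' @export
loop_config <- function(acquisition = c("entropy", "bald", "eces", "ebald", "uniform"),
                        batch_size = 1, max_rounds = 5,
                        learner = learner_config(),
                        sampler = c("mcmc", "exact"),
                        seed = 1, n_groups = 8,
                        exclude_intervened = FALSE,
                        stop_metric = NULL, stop_threshold = NULL) {
  acquisition <- match.arg(acquisition)
  stopifnot(batch_size >= 1, max_rounds >= 1)
  if (!is.function(sampler)) {
    sampler <- switch(match.arg(sampler),
                      mcmc = mcmc_posterior,
                      exact = exact_posterior)
  }
  structure(list(acquisition = acquisition, batch_size = as.integer(batch_size),
                 max_rounds = as.integer(max_rounds), learner = learner,
                 sampler = sampler, seed = as.integer(seed),
                 n_groups = as.integer(n_groups),
                 exclude_intervened = exclude_intervened,
                 stop_metric = stop_metric, stop_threshold = stop_threshold),
            class = "grn_loop_config")
}

#' Run the active-learning cycle
#'
#' Orchestrates the experiment-design loop: pretrain the structure
#' learner on observational data, then per round (1) score candidate
#' knockouts with the configured acquisition function from the current
#' posterior (`entropy`/`bald` use the 3-state DAG edge distribution,
#' `eces`/`ebald` the 4-state essential-graph distribution, `uniform`
#' ignores the posterior), (2) select a batch, (3) fetch the simulated
#' knockout series from the truth environment and append them to the
#' training data, (4) retrain, and (5) evaluate the posterior before and
#' after retraining so learning curves can be read off the log.  Stops at
#' `max_rounds` or when the configured stop metric is reached.  Fully
#' reproducible given the config seed.
#'
#' @param env A `grn_truth_env`.
#' @param config A `grn_loop_config`.
#' @return An object of class `grn_loop`: list with `rounds` (tibble log,
#'   one row per acquisition round), `posterior` (final `grn_posterior`),
#'   `pretrain_metrics`, `config` and `env` labels.
#' @export
run_active_loop <- function(env, config = loop_config()) {
  stopifnot(inherits(env, "grn_truth_env"), inherits(config, "grn_loop_config"))
  data <- env$observational
  lcfg <- config$learner
  fit <- function(round) {
    lcfg$seed <- config$seed + 97L * round
    config$sampler(data, lcfg)
  }
  post <- fit(0L)
  metrics <- function(p) evaluate_posterior(p, env$truth, env$reference_pdag)
  pre_metrics <- metrics(post)
  intervened <- integer(0)
  records <- list()
  for (r in seq_len(config$max_rounds)) {
    t0 <- proc.time()[["elapsed"]]
    acq <- acquire(post, method = config$acquisition,
                   batch_size = config$batch_size,
                   seed = config$seed + 1009L * r,
                   n_groups = config$n_groups,
                   exclude = if (config$exclude_intervened) intervened else NULL)
    for (g in acq$selected) data <- dplyr::bind_rows(data, env$knockout(g))
    intervened <- union(intervened, acq$selected)
    before <- metrics(post)
    post <- fit(r)
    after <- metrics(post)
    records[[r]] <- dplyr::bind_cols(
      tibble::tibble(round = r, acquisition = config$acquisition,
                     selected = list(acq$selected),
                     node_scores = list(acq$node_scores),
                     n_interventional = nrow(data) - nrow(env$observational)),
      dplyr::rename_with(before, ~ paste0(.x, "_before")),
      dplyr::rename_with(after, ~ paste0(.x, "_after")),
      tibble::tibble(seconds = proc.time()[["elapsed"]] - t0)
    )
    if (!is.null(config$stop_metric) &&
        after[[config$stop_metric]] <= config$stop_threshold) break
  }
  structure(list(rounds = dplyr::bind_rows(records), posterior = post,
                 pretrain_metrics = pre_metrics, config = config,
                 labels = env$labels),
            class = "grn_loop")
}

#' @export
print.grn_loop <- function(x, ...) {
  cat(sprintf("<grn_loop> %s acquisition, %d rounds\n",
              x$config$acquisition, nrow(x$rounds)))
  if (nrow(x$rounds)) {
    last <- x$rounds[nrow(x$rounds), ]
    cat(sprintf("  final expected directed SHD %.2f, NNZ %.1f\n",
                last$shd_directed_after, last$nnz_after))
  }
  invisible(x)
}

#' Tidy the round log of an active-learning run
#'
#' @param x A `grn_loop`.
#' @param ... Unused.
#' @return The per-round log tibble, with the pretraining state prepended
#'   as round 0.
#' @method tidy grn_loop
#' @export
tidy.grn_loop <- function(x, ...) {
  round0 <- dplyr::bind_cols(
    tibble::tibble(round = 0L, acquisition = x$config$acquisition,
                   selected = list(integer(0)), node_scores = list(NULL),
                   n_interventional = 0L),
    dplyr::rename_with(x$pretrain_metrics, ~ paste0(.x, "_after")),
    tibble::tibble(seconds = NA_real_)
  )
  dplyr::bind_rows(round0, x$rounds)
}

#' @rdname tidy.grn_loop
#' @method glance grn_loop
#' @export
glance.grn_loop <- function(x, ...) {
  last <- if (nrow(x$rounds)) x$rounds[nrow(x$rounds), ] else NULL
  tibble::tibble(
    acquisition = x$config$acquisition,
    rounds = nrow(x$rounds),
    final_shd_directed = if (is.null(last)) x$pretrain_metrics$shd_directed else last$shd_directed_after,
    final_nnz = if (is.null(last)) x$pretrain_metrics$nnz else last$nnz_after,
    final_recall = if (is.null(last)) x$pretrain_metrics$recall else last$recall_after
  )
}
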