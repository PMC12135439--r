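#' Read / write expression datasets
#'
#' Expression datasets travel as tab-separated tables with a header of
#' gene names plus an `intervention` column (`"none"` or the knocked-out
#' gene's name) and optional `series` / `time` columns.
#'
#' @param path File path.
#' @return `read_expression_tsv()` returns the expression tibble;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_expression_tsv
#' @param data Expression tibble.
#' @export
write_expression_tsv <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
}

#' Read / write posterior sample sets
#'
#' Sample sets are serialized as stacked headerless CSV adjacency blocks
#' (`n_samples * n_nodes` rows of `n_nodes` columns) plus an optional
#' sidecar CSV of per-sample `weight` and `group_id`.
#'
#' @param path Path of the stacked adjacency CSV.
#' @param sidecar Path of the weights/group sidecar; defaults to
#'   `<path>.meta.csv` (written always, read when present).
#' @param labels Optional gene names.
#' @return `read_posterior_csv()` returns a `grn_posterior`;
#'   `write_posterior_csv()` returns `path` invisibly.
#' @export
read_posterior_csv <- function(path, sidecar = paste0(path, ".meta.csv"),
                               labels = NULL) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  n <- ncol(m)
  if (nrow(m) %% n != 0) stop("stacked adjacency file is not a multiple of n_nodes rows")
  k <- nrow(m) %/% n
  graphs <- purrr::map(seq_len(k), function(i) {
    dag_from_adj((m[((i - 1) * n + 1):(i * n), , drop = FALSE] != 0) * 1L,
                 labels)
  })
  weights <- NULL
  group_ids <- NULL
  if (file.exists(sidecar)) {
    meta <- utils::read.csv(sidecar)
    weights <- meta$weight
    if ("group_id" %in% names(meta) && !all(is.na(meta$group_id)))
      group_ids <- meta$group_id
  }
  posterior_samples(graphs, weights = weights, group_ids = group_ids)
}

#' @rdname read_posterior_csv
#' @param s A `grn_posterior`.
#' @export
write_posterior_csv <- function(s, path, sidecar = paste0(path, ".meta.csv")) {
  stopifnot(inherits(s, "grn_posterior"))
  stacked <- do.call(rbind, purrr::map(s$graphs, "adj"))
  utils::write.table(stacked, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(
    data.frame(weight = s$weights,
               group_id = s$group_ids %||% rep(NA, length(s$graphs))),
    sidecar, row.names = FALSE
  )
  invisible(path)
}

#' Write acquisition scores as labeled CSV
#'
#' @param acq A `grn_acquisition`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_acquisition_csv <- function(acq, path) {
  stopifnot(inherits(acq, "grn_acquisition"))
  readr::write_csv(tidy(acq), path, progress = FALSE)
  invisible(path)
}
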