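#' Read a network from a gold-standard edge list
#'
#' Reads the tab-separated `source<TAB>target<TAB>value` dialect used by
#' GeneNetWeaver gold standards; rows with value 1 are edges, rows with
#' value 0 are ignored.  Gene names are mapped to indices in order of
#' first appearance unless `labels` fixes the gene set.
#'
#' @param path File path.
#' @param labels Optional character vector fixing the gene set and order.
#' @return A `grn_dag`.
#' @export
read_edge_list <- function(path, labels = NULL) {
  tab <- readr::read_tsv(path, col_names = c("source", "target", "value"),
                         col_types = "ccd", progress = FALSE)
  tab <- dplyr::filter(tab, .data$value != 0)
  if (is.null(labels)) labels <- unique(c(tab$source, tab$target))
  from <- match(tab$source, labels)
  to <- match(tab$target, labels)
  if (anyNA(from) || anyNA(to)) stop("edge list names a gene absent from `labels`")
  dag(length(labels), cbind(from, to), labels = labels)
}

#' Write a network as a gold-standard edge list
#'
#' @param g A `grn_dag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "grn_dag"))
  lab <- g$labels %||% paste0("G", seq_len(g$n_nodes))
  e <- edges(g)
  readr::write_tsv(
    tibble::tibble(source = lab[e$from], target = lab[e$to], value = 1L),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read / write a PDAG edge list
#'
#' Essential graphs are serialized as edge lists whose third column is
#' `">"` for a directed edge and `"-"` for an undirected one (listed
#' once).
#'
#' @param path File path.
#' @param labels Optional gene set fixing indices.
#' @return `read_pdag_edge_list()` returns a `grn_pdag`;
#'   `write_pdag_edge_list()` returns `path` invisibly.
#' @export
read_pdag_edge_list <- function(path, labels = NULL) {
  tab <- readr::read_tsv(path, col_names = c("source", "target", "kind"),
                         col_types = "ccc", progress = FALSE)
  if (is.null(labels)) labels <- unique(c(tab$source, tab$target))
  from <- match(tab$source, labels)
  to <- match(tab$target, labels)
  if (anyNA(from) || anyNA(to)) stop("edge list names a gene absent from `labels`")
  d <- cbind(from, to)[tab$kind == ">", , drop = FALSE]
  u <- cbind(from, to)[tab$kind == "-", , drop = FALSE]
  pdag(length(labels), directed = d, undirected = u, labels = labels)
}

#' @rdname read_pdag_edge_list
#' @param p A `grn_pdag`.
#' @export
write_pdag_edge_list <- function(p, path) {
  stopifnot(inherits(p, "grn_pdag"))
  lab <- p$labels %||% paste0("G", seq_len(p$n_nodes))
  e <- edges(p)
  readr::write_tsv(
    tibble::tibble(source = lab[e$from], target = lab[e$to],
                   kind = ifelse(e$type == "directed", ">", "-")),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read / write an adjacency matrix as headerless CSV
#'
#' @param path File path.
#' @param labels Optional gene names.
#' @return `read_adjacency_csv()` returns a `grn_dag`;
#'   `write_adjacency_csv()` returns `path` invisibly.
#' @export
read_adjacency_csv <- function(path, labels = NULL) {
  m <- as.matrix(readr::read_csv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_double()), progress = FALSE))
  dimnames(m) <- NULL
  dag_from_adj((m != 0) * 1L, labels)
}

#' @rdname read_adjacency_csv
#' @param g A `grn_dag`.
#' @export
write_adjacency_csv <- function(g, path) {
  stopifnot(inherits(g, "grn_dag"))
  utils::write.table(g$adj, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
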