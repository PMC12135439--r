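#' Heatmap of a pairwise acquisition score matrix
#'
#' @param object A `grn_scores` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grn_scores
#' @export
autoplot.grn_scores <- function(object, ...) {
  lab <- object$labels %||% paste0("G", seq_len(object$n_nodes))
  df <- tidyr::expand_grid(from = seq_len(object$n_nodes),
                           to = seq_len(object$n_nodes))
  df$score <- as.vector(object$value)[(df$to - 1L) * object$n_nodes + df$from]
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$to, levels = seq_along(lab), labels = lab),
    y = factor(.data$from, levels = rev(seq_along(lab)), labels = rev(lab)),
    fill = .data$score
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = object$function_name,
                  title = sprintf("%s pair scores", object$function_name)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-gene knockout scores of an acquisition round
#'
#' @param object A `grn_acquisition`.
#' @param ... Unused.
#' @return A ggplot object: genes ranked by knockout score, selected
#'   batch highlighted.
#' @method autoplot grn_acquisition
#' @export
autoplot.grn_acquisition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, .data$score),
    y = .data$score, fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#d95f02")) +
    ggplot2::labs(x = NULL, y = "knockout score",
                  title = sprintf("%s acquisition", object$function_name)) +
    ggplot2::theme_minimal()
}

#' Learning curves of an active-learning run
#'
#' @param object A `grn_loop`.
#' @param metrics Which posterior metrics to draw.
#' @param ... Unused.
#' @return A ggplot object: metric trajectories over rounds (round 0 is
#'   the observational pretraining fit).
#' @method autoplot grn_loop
#' @export
autoplot.grn_loop <- function(object, metrics = c("shd_directed", "nnz", "recall"),
                              ...) {
  log_ <- tidy(object)
  cols <- paste0(metrics, "_after")
  df <- tidyr::pivot_longer(log_[, c("round", cols)], -"round",
                            names_to = "metric", values_to = "value")
  df$metric <- sub("_after$", "", df$metric)
  ggplot2::ggplot(df, ggplot2::aes(.data$round, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "acquisition round", y = NULL,
                  title = sprintf("Active learning with %s acquisition",
                                  object$config$acquisition)) +
    ggplot2::theme_minimal()
}
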