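# ggplot2 visualisations for the main result types.

#' Stacked-bar plot of estimated proportions
#'
#' @param object A `deconvolution_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deconvolution_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                                 fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = if (object$relative) "relative index" else "proportion",
                  fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Estimated-versus-true scatter for a chimeric validation
#'
#' @param object An `evaluation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_result <- function(object, ...) {
  object$errors |>
    ggplot2::ggplot(ggplot2::aes(x = .data$truth, y = .data$estimated,
                                 colour = .data$cell_type)) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "true proportion", y = "estimated proportion",
                  subtitle = paste0("pooled RMSE = ", signif(object$rmse, 3))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Self-type recovery plot for a LOOCV run
#'
#' @param object A `loocv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loocv_result <- function(object, ...) {
  object$per_sample |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cell_type, y = .data$self_proportion)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "predicted self-type proportion") +
    ggplot2::theme_minimal()
}

#' Grouped box plot of cell-type proportions
#'
#' @param proportions Proportion tibble, matrix, or `deconvolution_result`.
#' @param metadata Optional metadata joined by `sample_id`.
#' @param group Optional metadata column used for grouping (e.g. `status`).
#' @return A ggplot object.
#' @export
plot_proportions <- function(proportions, metadata = NULL, group = NULL) {
  props <- prop_as_tibble(prop_as_matrix(proportions))
  long <- tidyr::pivot_longer(props, -"sample_id", names_to = "cell_type",
                              values_to = "proportion")
  if (!is.null(metadata) && !is.null(group)) {
    long <- dplyr::inner_join(long, tibble::as_tibble(metadata), by = "sample_id")
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type,
                                            y = .data$proportion,
                                            fill = .data[[group]])) +
      ggplot2::geom_boxplot(position = ggplot2::position_dodge())
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type,
                                            y = .data$proportion)) +
      ggplot2::geom_boxplot()
  }
  p + ggplot2::labs(x = NULL, y = "proportion") + ggplot2::theme_minimal()
}
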