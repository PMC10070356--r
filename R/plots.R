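# ggplot2 visualizations for the main result types.

#' @describeIn pr_curve Plot the precision-recall curve (step interpolation,
#'   matching the average-precision area).
#' @param object A `pr_curve`.
#' @param ... Unused.
#' @export
autoplot.pr_curve <- function(object, ...) {
  df <- tibble(recall = c(0, object$recall),
               precision = c(object$precision[1], object$precision))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("AUPRC = %.3f (prevalence %.3f)",
                                  attr(object, "auprc"),
                                  attr(object, "prevalence"))) +
    ggplot2::theme_minimal()
}

#' Plot per-cell-type score distributions
#'
#' Density of raw scores per cell type; when the table carries an
#' `in_reference` column (from [compare_link_sets()]) the two partitions are
#' overlaid with their means marked, mirroring the reference-vs-background
#' comparison.
#'
#' @param object An `eg_scores` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eg_scores <- function(object, ...) {
  df <- as_tibble(object)
  if ("in_reference" %in% names(df)) {
    mu <- df |>
      dplyr::group_by(.data$cell_type, .data$in_reference) |>
      dplyr::summarise(m = mean(.data$raw_score), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$raw_score,
                                     fill = .data$in_reference)) +
      ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
      ggplot2::geom_vline(data = mu,
                          ggplot2::aes(xintercept = .data$m,
                                       colour = .data$in_reference)) +
      ggplot2::facet_wrap(~cell_type) +
      ggplot2::labs(x = "Raw score", y = "Pairs", fill = "In reference",
                    colour = "In reference") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$raw_score)) +
      ggplot2::geom_histogram(bins = 40) +
      ggplot2::facet_wrap(~cell_type) +
      ggplot2::labs(x = "Raw score", y = "Pairs") +
      ggplot2::theme_minimal()
  }
}

#' Plot a selection report as a test-set performance grid
#'
#' @param object A `selection_report` from [cross_cell_evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$test_dataset, y = .data$model_id,
                               fill = .data$auprc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$auprc)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Test dataset", y = "Model", fill = "AUPRC") +
    ggplot2::theme_minimal()
}
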