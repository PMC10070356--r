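# broom-style tidiers for fitted objects and result containers.

#' Tidy a trained model
#'
#' @param x An `eg_model`.
#' @param ... Unused.
#' @return Tibble with one row per feature used by the model, with the
#'   training-set standardization moments where applicable.
#' @export
tidy.eg_model <- function(x, ...) {
  tibble(feature = x$feature_names,
         standardized = x$feature_names %in%
           setdiff(x$standardization$columns, x$standardization$constant),
         train_mean = unname(x$standardization$mean[x$feature_names]),
         train_sd = unname(x$standardization$sd[x$feature_names]))
}

#' One-row model summary
#'
#' @param x An `eg_model`.
#' @param ... Unused.
#' @return One-row tibble: algorithm, training set, size, prevalence,
#'   feature count, P300 usage, seed.
#' @export
glance.eg_model <- function(x, ...) {
  tibble(algorithm = x$algorithm, train_dataset = x$dataset_id,
         n_train = x$n_train, train_prevalence = x$train_prevalence,
         n_features = length(x$feature_names), uses_p300 = x$uses_p300,
         seed = x$seed)
}

#' Tidy a labeled dataset
#'
#' @param x An `eg_dataset`.
#' @param ... Unused.
#' @return The labeled pair tibble.
#' @export
tidy.eg_dataset <- function(x, ...) x$pairs

#' One-row dataset summary
#'
#' @param x An `eg_dataset`.
#' @param ... Unused.
#' @return One-row tibble with counts, prevalence and P300 availability.
#' @export
glance.eg_dataset <- function(x, ...) {
  tibble(id = x$id, cell_types = paste(x$cell_types, collapse = "+"),
         n = nrow(x$pairs), n_pos = x$n_pos, n_neg = x$n_neg,
         prevalence = x$prevalence, p300_available = x$p300_available)
}

#' Tidy a model-selection result
#'
#' @param x A `model_selection` from [select_final_model()].
#' @param ... Unused.
#' @return The per-model summary table with a `winner` flag.
#' @export
tidy.model_selection <- function(x, ...) {
  dplyr::mutate(x$summary, winner = .data$model_id == x$winner)
}

#' Tidy a PR curve into its points
#'
#' @param x A `pr_curve`.
#' @param ... Unused.
#' @return Plain tibble of curve points.
#' @export
tidy.pr_curve <- function(x, ...) as_tibble(x)

#' One-row PR-curve summary
#'
#' @param x A `pr_curve`.
#' @param ... Unused.
#' @return One-row tibble: `auprc`, `prevalence`, `n_pos`, `n_neg`.
#' @export
glance.pr_curve <- function(x, ...) {
  tibble(auprc = attr(x, "auprc"), prevalence = attr(x, "prevalence"),
         n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg"))
}

#' Tidy an ablation result
#'
#' @param x An `ablation` from [ablate_features()].
#' @param ... Unused.
#' @return The per-candidate-drop history table.
#' @export
tidy.ablation <- function(x, ...) x$history
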