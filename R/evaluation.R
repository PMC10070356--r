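# Precision-recall / ROC analysis, the prevalence baseline, the
# cross-cell-type selection rule (min AUPRC + mean AUPRC, with a < 0.10
# disqualifier, then highest mean AUC), greedy drop-one feature ablation,
# and the two-sample Kolmogorov-Smirnov comparison.

#' Precision-recall curve
#'
#' Thresholds are taken at each distinct score in descending order, with tied
#' scores grouped into one threshold. The area is the average-precision step
#' sum `sum((R_i - R_{i-1}) * P_i)` (no trapezoidal interpolation).
#'
#' @param scores Numeric score vector.
#' @param labels Labels (`"positive"`/`"negative"`, logical, or 0/1); both
#'   classes must be present.
#' @return A tibble of class `pr_curve` with columns `threshold`, `tp`, `fp`,
#'   `precision`, `recall`; attributes `auprc` and `prevalence`.
#' @export
pr_curve <- function(scores, labels) {
  y <- as_label01(labels)
  if (length(y) != length(scores)) abort("scores and labels differ in length")
  P <- sum(y); N <- sum(1 - y)
  if (P == 0 || N == 0) abort("both classes must be present to compute a PR curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tied block
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  out <- tibble(threshold = s[last], tp = tp, fp = fp,
                precision = tp / (tp + fp), recall = tp / P)
  auprc <- sum(diff(c(0, out$recall)) * out$precision)
  structure(out, class = c("pr_curve", class(out)),
            auprc = auprc, prevalence = P / (P + N),
            n_pos = P, n_neg = N)
}

#' Area under the precision-recall curve
#' @inheritParams pr_curve
#' @return Scalar AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) attr(pr_curve(scores, labels), "auprc")

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation; tied scores contribute 1/2.
#'
#' @inheritParams pr_curve
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_label01(labels)
  P <- sum(y); N <- sum(1 - y)
  if (P == 0 || N == 0) abort("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Random-classifier AUPRC baseline
#'
#' The AUPRC of a random classifier equals the positive-class prevalence.
#'
#' @param labels Label vector (see [pr_curve()]).
#' @return Positive fraction of `labels`.
#' @export
random_baseline_auprc <- function(labels) {
  y <- as_label01(labels)
  if (!length(y)) abort("labels must be non-empty")
  mean(y)
}

#' Evaluate every model on every eligible test set
#'
#' A model is never evaluated on a dataset sharing any (enhancer, gene, cell
#' type) observation with its training data; such pairings are skipped with
#' a warning. Each remaining pairing contributes one row with AUPRC and AUC.
#'
#' @param models Named list of `eg_model` objects.
#' @param datasets Named list of `eg_dataset` objects.
#' @return Tibble of class `selection_report`: `model_id`, `algorithm`,
#'   `train_dataset`, `test_dataset`, `n_pos`, `n_neg`, `auprc`, `auc`.
#' @export
cross_cell_evaluate <- function(models, datasets) {
  if (is.null(names(models))) names(models) <- paste0("model_", seq_along(models))
  rows <- purrr::imap(models, function(m, mid) {
    purrr::imap(datasets, function(d, did) {
      if (any(pair_key(d$pairs) %in% m$train_keys)) {
        warn(sprintf("skipping %s on %s: shared training observations", mid, did))
        return(NULL)
      }
      s <- predict_scores(m, d)
      y <- d$pairs$label
      tibble(model_id = mid, algorithm = m$algorithm,
             train_dataset = m$dataset_id, test_dataset = did,
             n_pos = d$n_pos, n_neg = d$n_neg,
             auprc = auprc(s, y), auc = roc_auc(s, y))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  structure(out, class = c("selection_report", class(out)))
}

#' Summarize a selection report per model
#'
#' @param report A `selection_report` from [cross_cell_evaluate()].
#' @return Tibble: one row per model with `min_auprc`, `mean_auprc`,
#'   `selection_score = min + mean`, `mean_auc` and the `disqualified` flag
#'   (`min_auprc < 0.10`).
#' @export
summarize_selection <- function(report) {
  report |>
    dplyr::group_by(.data$model_id, .data$algorithm, .data$train_dataset) |>
    dplyr::summarise(n_tests = dplyr::n(),
                     min_auprc = min(.data$auprc),
                     mean_auprc = mean(.data$auprc),
                     mean_auc = mean(.data$auc), .groups = "drop") |>
    dplyr::mutate(selection_score = .data$min_auprc + .data$mean_auprc,
                  disqualified = .data$min_auprc < 0.10) |>
    dplyr::arrange(.data$model_id)
}

#' Apply the final-model selection rule
#'
#' Within each training set, the candidate is the qualified model (minimum
#' AUPRC at least 0.10) maximizing `min AUPRC + mean AUPRC`; across training
#' sets, the winner is the candidate with the highest mean AUC. All ties
#' break deterministically on the lexicographically smaller model id.
#'
#' @param report A `selection_report`.
#' @return List of class `model_selection`: `winner` (model id),
#'   `candidates` (per-training-set best), `summary` (full per-model table).
#' @export
select_final_model <- function(report) {
  if (nrow(report) == 0) abort("empty selection report")
  summ <- summarize_selection(report)
  qualified <- summ[!summ$disqualified, ]
  if (nrow(qualified) == 0) abort("all models disqualified (min AUPRC < 0.10)")
  candidates <- qualified |>
    dplyr::group_by(.data$train_dataset) |>
    dplyr::arrange(dplyr::desc(.data$selection_score), .data$model_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  winner <- candidates |>
    dplyr::arrange(dplyr::desc(.data$mean_auc), .data$model_id) |>
    dplyr::slice(1)
  structure(list(winner = winner$model_id,
                 candidates = candidates,
                 summary = summ),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> winner: %s\n", x$winner))
  print(x$candidates)
  invisible(x)
}

#' Greedy drop-one feature ablation
#'
#' Starting from the full feature set, each feature is dropped in turn, the
#' model retrained, and the mean AUPRC across the test sets recorded.
#' While some drop improves on the incumbent mean AUPRC the best such drop is
#' applied and the sweep repeats; the loop stops at the first sweep with no
#' improving drop.
#'
#' @param dataset Training `eg_dataset`.
#' @param algorithm Model algorithm.
#' @param test_datasets Named list of `eg_dataset` test sets.
#' @param features Starting feature set (default: all available).
#' @param seed Training seed.
#' @param hyperparameters Passed to [train_model()].
#' @return List of class `ablation`: `history` (per-candidate-drop table,
#'   with `round`, `dropped`, `mean_auprc`, `kept`), `final_features`,
#'   `baseline_auprc`, `final_auprc`.
#' @export
ablate_features <- function(dataset, algorithm, test_datasets,
                            features = NULL, seed = 1L,
                            hyperparameters = list()) {
  if (is.null(features)) {
    features <- intersect(feature_names(p300 = dataset$p300_available),
                          names(dataset$features_raw))
  }
  if (length(features) < 2) abort("ablation needs at least two features")
  mean_auprc_for <- function(feats) {
    m <- train_model(dataset, algorithm, features = feats, seed = seed,
                     hyperparameters = hyperparameters)
    mean(vapply(test_datasets,
                function(d) auprc(predict_scores(m, d), d$pairs$label),
                numeric(1)))
  }
  current <- features
  base <- mean_auprc_for(current)
  baseline <- base
  history <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    cand <- tibble(round = round, dropped = current,
                   mean_auprc = vapply(current, function(f) {
                     mean_auprc_for(setdiff(current, f))
                   }, numeric(1)))
    cand$kept <- FALSE
    best <- cand[order(-cand$mean_auprc, cand$dropped), ][1, ]
    history[[round]] <- cand
    if (best$mean_auprc > base && length(current) > 2) {
      current <- setdiff(current, best$dropped)
      base <- best$mean_auprc
      history[[round]]$kept <- history[[round]]$dropped == best$dropped
    } else if (best$mean_auprc > base) {
      current <- setdiff(current, best$dropped)
      base <- best$mean_auprc
      history[[round]]$kept <- history[[round]]$dropped == best$dropped
      break
    } else break
  }
  structure(list(history = dplyr::bind_rows(history),
                 final_features = current,
                 baseline_auprc = baseline,
                 final_auprc = base),
            class = "ablation")
}

#' @export
print.ablation <- function(x, ...) {
  cat(sprintf("<ablation> %d -> %d features, mean AUPRC %.4f -> %.4f\n",
              length(unique(x$history$dropped[x$history$round == 1])),
              length(x$final_features), x$baseline_auprc, x$final_auprc))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value uses the asymptotic Kolmogorov distribution with
#' effective sample size `n1 * n2 / (n1 + n2)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return One-row tibble: `statistic`, `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         n_x = length(x), n_y = length(y))
}
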