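# Classifier registry. All models consume the dataset's standardized feature
# matrix and emit raw scores in [0, 1]. The k-nearest-neighbors scorer (the
# final-model algorithm) is implemented here directly; kernel SVMs, ridge,
# random forest and LDA are delegated to kernlab, glmnet, randomForest and
# MASS behind a uniform train/predict surface.

#' Available model algorithms
#' @return Character vector of algorithm names accepted by [train_model()].
#' @export
model_algorithms <- function() {
  c("knn", "ridge", "lda", "random_forest",
    "svm_rbf", "svm_laplace", "svm_anova")
}

default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    knn = list(k = 5),
    ridge = list(lambda = 0.01),
    lda = list(),
    random_forest = list(ntree = 500),
    svm_rbf = list(C = 1),
    svm_laplace = list(C = 1),
    svm_anova = list(C = 1, sigma = 1, degree = 1),
    abort(sprintf("unknown algorithm '%s'", algorithm))
  )
}

#' Train a classifier on a labeled dataset
#'
#' Features are taken from the dataset's standardized matrix; the model
#' carries the training-set standardization parameters so new data is always
#' rescaled with the *training* moments. Hyperparameters default to standard
#' values (`k = 5`, `lambda = 0.01`, `C = 1`, `ntree = 500`) unless
#' overridden. Training is deterministic given `seed`.
#'
#' @param dataset An `eg_dataset`.
#' @param algorithm One of [model_algorithms()].
#' @param features Feature columns to use; default: all features of the
#'   dataset (dropping `p300_enh` when the dataset lacks P300 data).
#' @param seed Integer seed for stochastic algorithms.
#' @param hyperparameters Named list overriding algorithm defaults.
#' @return An object of class `eg_model`.
#' @export
train_model <- function(dataset, algorithm = "knn", features = NULL,
                        seed = 1L, hyperparameters = list()) {
  stopifnot(inherits(dataset, "eg_dataset"))
  algorithm <- match.arg(algorithm, model_algorithms())
  if (is.null(features)) {
    features <- intersect(c(feature_names(p300 = dataset$p300_available),
                            "distance"),
                          names(dataset$features_raw))
  }
  if ("p300_enh" %in% features && !dataset$p300_available) {
    abort(sprintf("dataset '%s' has no P300 data but p300_enh was requested",
                  dataset$id))
  }
  hp <- modifyList(default_hyperparameters(algorithm), hyperparameters)
  X <- dataset_matrix(dataset, features)
  y01 <- dataset_labels(dataset)
  y <- factor(ifelse(y01 == 1, "positive", "negative"),
              levels = c("negative", "positive"))
  set.seed(seed)
  fit <- switch(algorithm,
    knn = {
      if (hp$k > nrow(X)) abort("k exceeds the number of training rows")
      list(X = X, y01 = y01, k = hp$k)
    },
    ridge = glmnet::glmnet(pad_single_column(X), y, family = "binomial",
                           alpha = 0, lambda = hp$lambda, standardize = FALSE),
    lda = MASS::lda(X, grouping = y),
    random_forest = randomForest::randomForest(X, y, ntree = hp$ntree),
    svm_rbf = kernlab::ksvm(X, y, kernel = "rbfdot", C = hp$C,
                            kpar = "automatic", scaled = FALSE,
                            prob.model = FALSE),
    svm_laplace = kernlab::ksvm(X, y, kernel = "laplacedot", C = hp$C,
                                kpar = "automatic", scaled = FALSE,
                                prob.model = FALSE),
    svm_anova = kernlab::ksvm(X, y, kernel = "anovadot", C = hp$C,
                              kpar = list(sigma = hp$sigma, degree = hp$degree),
                              scaled = FALSE, prob.model = FALSE)
  )
  model <- structure(list(
    algorithm = algorithm,
    hyperparameters = hp,
    feature_names = features,
    uses_p300 = "p300_enh" %in% features,
    fit = fit,
    standardization = dataset$standardization,
    dataset_id = dataset$id,
    train_keys = pair_key(dataset$pairs),
    train_prevalence = dataset$prevalence,
    n_train = nrow(dataset$pairs),
    seed = seed,
    score_link = if (startsWith(algorithm, "svm_")) "logistic-decision" else "native"
  ), class = "eg_model")
  if (startsWith(algorithm, "svm_")) {
    d <- kernlab::predict(fit, X, type = "decision")[, 1]
    flip <- isTRUE(suppressWarnings(stats::cor(d, y01)) < 0)
    model$svm_flip <- flip
  }
  model
}

#' @export
print.eg_model <- function(x, ...) {
  cat(sprintf("<eg_model %s> trained on '%s' (%d rows, prevalence %.4g)\n",
              x$algorithm, x$dataset_id, x$n_train, x$train_prevalence))
  cat(sprintf("  features (%d): %s\n", length(x$feature_names),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

# glmnet requires >= 2 columns; a zero dummy leaves the fit unchanged for
# single-feature (distance-only) models.
pad_single_column <- function(X) {
  if (ncol(X) == 1) cbind(X, .dummy = 0) else X
}

# Stable-tie Euclidean kNN vote: the score is the positive fraction among the
# k nearest training rows; equal distances are resolved by training-row index.
knn_vote <- function(trainX, y01, k, queryX) {
  cross <- queryX %*% t(trainX)
  d2 <- outer(rowSums(queryX^2), rowSums(trainX^2), `+`) - 2 * cross
  apply(d2, 1, function(d) {
    nn <- order(d)[seq_len(k)]   # order() is stable: ties -> lower index
    mean(y01[nn])
  })
}

#' k-NN score for a single standardized row
#'
#' Exposes the final-model vote directly: the fraction of the `k` nearest
#' training rows (Euclidean distance on the standardized feature space)
#' labeled positive. Scores therefore take values in `{0, 1/k, ..., 1}`.
#'
#' @param model An `eg_model` with `algorithm = "knn"`.
#' @param row A one-row data frame of *raw* feature values (the model applies
#'   its training standardization), or a numeric vector already on the
#'   standardized scale.
#' @return A single score in `[0, 1]`.
#' @export
knn_score <- function(model, row) {
  stopifnot(inherits(model, "eg_model"), model$algorithm == "knn")
  if (is.data.frame(row)) {
    q <- as.matrix(standardize_apply(row, model$standardization)[model$feature_names])
  } else {
    q <- matrix(row, nrow = 1)
  }
  knn_vote(model$fit$X, model$fit$y01, model$fit$k, q)[[1]]
}

#' Score new rows with a trained model
#'
#' Accepts an `eg_dataset` or a raw feature tibble; the model's training-set
#' standardization is applied before scoring, and one score in `[0, 1]` is
#' returned per row in input order.
#'
#' @param model An `eg_model`.
#' @param newdata An `eg_dataset` or a tibble containing the model's raw
#'   feature columns.
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, newdata) {
  stopifnot(inherits(model, "eg_model"))
  raw <- if (inherits(newdata, "eg_dataset")) newdata$features_raw else as_tibble(newdata)
  if (nrow(raw) == 0) return(numeric())
  missing <- setdiff(model$feature_names, names(raw))
  if (length(missing)) {
    abort(sprintf("newdata lacks model feature(s): %s",
                  paste(missing, collapse = ", ")))
  }
  std <- standardize_apply(raw, model$standardization)
  X <- as.matrix(std[model$feature_names])
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("newdata has missing feature values for this model")
  s <- switch(model$algorithm,
    knn = knn_vote(model$fit$X, model$fit$y01, model$fit$k, X),
    ridge = as.numeric(predict(model$fit, pad_single_column(X),
                               type = "response")),
    lda = as.numeric(predict(model$fit, X)$posterior[, "positive"]),
    random_forest = as.numeric(predict(model$fit, X, type = "prob")[, "positive"]),
    {
      d <- kernlab::predict(model$fit, X, type = "decision")[, 1]
      if (isTRUE(model$svm_flip)) d <- -d
      stats::plogis(d)
    }
  )
  pmin(1, pmax(0, s))
}

#' Distance-only reference dataset
#'
#' Builds a single-feature dataset whose only predictor is the signed
#' midpoint distance `gene_mid - enhancer_mid` (or its absolute value), the
#' reference against which the feature-based models are compared.
#'
#' @param labeled_pairs Tibble with `enhancer_id`, `gene_id`, `label`
#'   (and optional `cell_type`).
#' @param enhancers,genes Element tables.
#' @param absolute Use `|distance|` instead of the signed value.
#' @param cell_type,id Dataset tags, as in [assemble_dataset()].
#' @return An `eg_dataset` with one feature column, `distance`.
#' @export
make_distance_dataset <- function(labeled_pairs, enhancers, genes,
                                  absolute = FALSE, cell_type = "cell",
                                  id = paste0(cell_type, "_distance")) {
  e <- dplyr::transmute(enhancers, .data$enhancer_id,
                        enh_mid = (.data$start + .data$end) / 2)
  g <- dplyr::transmute(genes, .data$gene_id,
                        gene_mid = (.data$start + .data$end) / 2)
  feats <- labeled_pairs |>
    dplyr::left_join(e, by = "enhancer_id") |>
    dplyr::left_join(g, by = "gene_id") |>
    dplyr::mutate(distance = .data$gene_mid - .data$enh_mid)
  if (absolute) feats$distance <- abs(feats$distance)
  feats <- dplyr::select(feats, "enhancer_id", "gene_id", "distance")
  assemble_dataset(labeled_pairs[labeled_pairs$label == "positive", ],
                   labeled_pairs[labeled_pairs$label == "negative", ],
                   feats, cell_type = cell_type, id = id)
}
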