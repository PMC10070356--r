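# Genome-wide scoring: model routing by P300 availability, per-cell-type
# normalization (Z-score and percentile F(score)), comparison of scored link
# subsets against a reference link set, and regulatory-landscape summaries.

#' Z-scores of raw scores within a cell type
#'
#' `(s - mean(s)) / sd(s)` with the sample standard deviation.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector of Z-scores (mean 0, sd 1).
#' @export
zscores <- function(x) {
  if (length(unique(x)) < 2) abort("Z-scores undefined for constant scores (sd = 0)")
  (x - mean(x)) / sd(x)
}

#' Percentile F(scores) within a cell type
#'
#' Weak-percentile convention: `F(s) = #\{scores <= s\} / N`, so the maximum
#' score always has `F = 1` and tied scores share a percentile.
#'
#' @param x Non-empty numeric vector.
#' @return Numeric vector of percentiles in `(0, 1]`.
#' @export
fscores <- function(x) {
  if (!length(x)) abort("scores must be non-empty")
  rank(x, ties.method = "max") / length(x)
}

#' Score cis pairs for one or more cell types with model routing
#'
#' Each cell type's feature table is scored with `final_model` when its P300
#' feature is available and with `alternate_model` otherwise; raw scores are
#' then normalized per cell type into Z-scores and F(scores).
#'
#' @param cell_features Named list (one element per cell type) of feature
#'   tibbles from [build_feature_matrix()].
#' @param final_model `eg_model` trained with the P300 feature.
#' @param alternate_model `eg_model` trained without P300 (may be `NULL`
#'   when every cell type has P300 data).
#' @return A tibble of class `eg_scores`: `enhancer_id`, `gene_id`,
#'   `cell_type`, `raw_score`, `z_score`, `f_score`, `model_used`.
#' @export
score_cis_pairs <- function(cell_features, final_model, alternate_model = NULL) {
  if (is.null(names(cell_features))) {
    abort("cell_features must be a named list keyed by cell type")
  }
  rows <- purrr::imap(cell_features, function(feats, cell) {
    p300 <- isTRUE(attr(feats, "p300_available")) && !anyNA(feats$p300_enh)
    model <- if (p300) final_model else alternate_model
    used <- if (p300) "final" else "alternate"
    if (is.null(model)) {
      abort(sprintf("cell type '%s' lacks P300 data and no alternate model was supplied",
                    cell))
    }
    non_p300 <- setdiff(model$feature_names, "p300_enh")
    if (!all(non_p300 %in% names(feats)) ||
        anyNA(feats[intersect(non_p300, names(feats))])) {
      abort(sprintf("cell type '%s' is missing features beyond P300; unscorable", cell))
    }
    s <- predict_scores(model, feats)
    tibble(enhancer_id = feats$enhancer_id, gene_id = feats$gene_id,
           cell_type = cell, raw_score = s,
           z_score = zscores(s), f_score = fscores(s),
           model_used = used)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("eg_scores", class(out)))
}

#' Compare scored link subsets against a reference link set
#'
#' Reference enhancer intervals are mapped onto the catalog (default 33%
#' either-region overlap); a scored pair is "in reference" when its mapped
#' enhancer and gene id match a reference link. Group means and a two-sample
#' KS comparison of the raw-score distributions are reported per cell type
#' (skipped with a warning when a partition is empty).
#'
#' @param score_table An `eg_scores` table.
#' @param reference_links Tibble with `chrom`, `start`, `end`, `gene_id`.
#' @param catalog Enhancer catalog used for mapping.
#' @param min_frac Mapping overlap threshold.
#' @return List: `scores` (input plus `in_reference`), `group_means`,
#'   `ks` (per cell type; zero rows where skipped).
#' @export
compare_link_sets <- function(score_table, reference_links, catalog,
                              min_frac = 0.33) {
  mp <- map_external_enhancers(reference_links, catalog, min_frac = min_frac)
  reference_links <- as_tibble(reference_links)
  if (!"external_id" %in% names(reference_links)) {
    reference_links$external_id <- sprintf(
      "%s:%d-%d", reference_links$chrom,
      as.integer(reference_links$start), as.integer(reference_links$end))
  }
  ref_pairs <- mp$mapped |>
    dplyr::inner_join(dplyr::select(reference_links, "external_id", "gene_id"),
                      by = "external_id", relationship = "many-to-many") |>
    dplyr::distinct(.data$enhancer_id, .data$gene_id)
  scored <- dplyr::mutate(score_table, in_reference = paste(
    .data$enhancer_id, .data$gene_id) %in%
      paste(ref_pairs$enhancer_id, ref_pairs$gene_id))
  group_means <- scored |>
    dplyr::group_by(.data$cell_type, .data$in_reference) |>
    dplyr::summarise(n = dplyr::n(), mean_score = mean(.data$raw_score),
                     .groups = "drop")
  ks <- scored |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_modify(function(df, key) {
      a <- df$raw_score[df$in_reference]
      b <- df$raw_score[!df$in_reference]
      if (!length(a) || !length(b)) {
        warn(sprintf("cell type '%s': empty partition, KS skipped", key$cell_type))
        return(tibble(statistic = double(), p_value = double(),
                      n_x = integer(), n_y = integer()))
      }
      ks_two_sample(a, b)
    }) |>
    dplyr::ungroup()
  list(scores = scored, group_means = group_means, ks = ks)
}

#' Regulatory-landscape summary of high-scoring links
#'
#' Restricted to pairs with `f_score >= f_min` (default the top 5%), reports
#' per cell type the percentage of enhancers linked to more than one gene,
#' the percentage of genes linked to more than one enhancer, and the
#' top-degree gene(s) and enhancer(s) (all tied winners listed).
#'
#' @param score_table An `eg_scores` table.
#' @param f_min Minimum F(score) in `(0, 1]`.
#' @return Tibble, one row per cell type, with list-columns `top_genes` and
#'   `top_enhancers`.
#' @export
regulatory_summary <- function(score_table, f_min = 0.95) {
  if (!is.numeric(f_min) || f_min <= 0 || f_min > 1) abort("f_min must be in (0, 1]")
  kept <- dplyr::filter(as_tibble(score_table), .data$f_score >= f_min)
  if (nrow(kept) == 0) {
    warn("no pairs at or above f_min; empty summary")
    return(tibble(cell_type = character(), n_links = integer(),
                  pct_enhancers_multigene = double(),
                  pct_genes_multienhancer = double(),
                  max_enhancers_per_gene = integer(),
                  max_genes_per_enhancer = integer(),
                  top_genes = list(), top_enhancers = list()))
  }
  kept |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 0) {
        return(tibble(n_links = 0L, pct_enhancers_multigene = NA_real_,
                      pct_genes_multienhancer = NA_real_,
                      max_enhancers_per_gene = NA_integer_,
                      max_genes_per_enhancer = NA_integer_,
                      top_genes = list(character()),
                      top_enhancers = list(character())))
      }
      per_enh <- dplyr::count(df, .data$enhancer_id, name = "n_genes")
      per_gene <- dplyr::count(df, .data$gene_id, name = "n_enhancers")
      tibble(
        n_links = nrow(df),
        pct_enhancers_multigene = 100 * mean(per_enh$n_genes > 1),
        pct_genes_multienhancer = 100 * mean(per_gene$n_enhancers > 1),
        max_enhancers_per_gene = max(per_gene$n_enhancers),
        max_genes_per_enhancer = max(per_enh$n_genes),
        top_genes = list(sort(per_gene$gene_id[
          per_gene$n_enhancers == max(per_gene$n_enhancers)])),
        top_enhancers = list(sort(per_enh$enhancer_id[
          per_enh$n_genes == max(per_enh$n_genes)]))
      )
    }) |>
    dplyr::ungroup()
}
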