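# Labeled training/test dataset assembly: curated positives mapped onto the
# enhancer catalog, screen-derived positives/negatives, the inaccessibility
# negative universe, gene-matched negative sampling, and pooling across cell
# types.

#' Map curated literature links onto the catalog as positive pairs
#'
#' Each curated interval is mapped with [map_external_enhancers()] (default
#' 33% either-region overlap); one positive pair is emitted per (mapped
#' enhancer, gene). Rows whose gene is not in the protein-coding allow-list
#' (when given) are skipped, and unmapped rows are reported via attributes.
#'
#' @param curated Curated-link tibble (see [read_curated_links()]); must
#'   carry `cell_type`.
#' @param catalog Enhancer catalog tibble.
#' @param protein_coding Optional character vector of allowed gene ids.
#' @param min_frac Mapping overlap threshold.
#' @return Tibble `enhancer_id`, `gene_id`, `cell_type`, `label =
#'   "positive"`, deduplicated; attributes `n_unmapped`, `n_skipped`,
#'   `unmapped`.
#' @export
load_curated_positives <- function(curated, catalog, protein_coding = NULL,
                                   min_frac = 0.33) {
  check_intervals(curated, "curated links")
  if (!"cell_type" %in% names(curated)) abort("curated links need a cell_type column")
  curated <- dplyr::distinct(as_tibble(curated))
  n_skipped <- 0L
  if (!is.null(protein_coding)) {
    keep <- curated$gene_id %in% protein_coding
    n_skipped <- sum(!keep)
    curated <- curated[keep, ]
  }
  curated$external_id <- sprintf("row_%d", seq_len(nrow(curated)))
  mp <- map_external_enhancers(curated, catalog, min_frac = min_frac)
  out <- mp$mapped |>
    dplyr::inner_join(dplyr::select(curated, "external_id", "gene_id", "cell_type"),
                      by = "external_id") |>
    dplyr::distinct(.data$enhancer_id, .data$gene_id, .data$cell_type) |>
    dplyr::mutate(label = "positive") |>
    dplyr::arrange(.data$gene_id, .data$enhancer_id)
  attr(out, "n_unmapped") <- nrow(mp$unmapped)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "unmapped") <- mp$unmapped
  out
}

#' Partition CRISPR/CRISPRi screen results into positives and negatives
#'
#' Rows below `pos_max` on the statistic become positives, rows above
#' `neg_min` negatives; rows in the gap are dropped. Negatives found in the
#' positive set are removed (and counted). When the table carries enhancer
#' coordinates instead of catalog ids, supply `catalog` to map them first.
#'
#' @param screen Tibble with `gene_id`, `cell_type`, a statistic column, and
#'   either `enhancer_id` or `chrom`/`start`/`end`.
#' @param statistic_col Name of the statistic column (e.g. `"p_value"` or
#'   `"fdr"`).
#' @param pos_max Positive rule: statistic strictly below this value.
#' @param neg_min Negative rule: statistic strictly above this value.
#' @param catalog Optional enhancer catalog for coordinate mapping.
#' @param min_frac Mapping overlap threshold when `catalog` is used.
#' @return List `positives`, `negatives` (labeled pair tibbles), `n_dropped`,
#'   `n_conflict` (negatives removed because they appeared as positives).
#' @export
load_screen_links <- function(screen, statistic_col = "p_value",
                              pos_max = 0.05, neg_min = 0.10,
                              catalog = NULL, min_frac = 0.33) {
  if (!statistic_col %in% names(screen)) {
    abort(sprintf("screen table lacks statistic column '%s'", statistic_col))
  }
  if (!"enhancer_id" %in% names(screen)) {
    if (is.null(catalog)) {
      abort("screen table has no enhancer_id; supply a catalog to map coordinates")
    }
    screen$external_id <- sprintf("row_%d", seq_len(nrow(screen)))
    mp <- map_external_enhancers(screen, catalog, min_frac = min_frac)
    screen <- dplyr::inner_join(mp$mapped[c("external_id", "enhancer_id")],
                                screen, by = "external_id")
  }
  stat <- screen[[statistic_col]]
  pos <- screen[stat < pos_max, ] |>
    dplyr::distinct(.data$enhancer_id, .data$gene_id, .data$cell_type) |>
    dplyr::mutate(label = "positive")
  neg <- screen[stat > neg_min, ] |>
    dplyr::distinct(.data$enhancer_id, .data$gene_id, .data$cell_type) |>
    dplyr::mutate(label = "negative")
  n_dropped <- sum(stat >= pos_max & stat <= neg_min)
  conflict <- pair_key(neg) %in% pair_key(pos)
  if (any(conflict)) {
    warn(sprintf("%d screen pair(s) present in both classes removed from negatives",
                 sum(conflict)))
  }
  list(positives = pos, negatives = neg[!conflict, ],
       n_dropped = n_dropped, n_conflict = sum(conflict))
}

#' Identify elements never overlapped by accessibility peaks
#'
#' An element is inaccessible when its interval, padded by `pad` bp on each
#' side, intersects no DNase/FAIRE peak by even one base. Defaults follow the
#' pipeline convention: `pad = 0` for enhancers, 2000 for gene bodies.
#'
#' @param elements Tibble with an id column (`enhancer_id`/`gene_id`) and
#'   `chrom`, `start`, `end`.
#' @param accessibility_peaks Peak tibble.
#' @param pad Padding in bp applied to each element end.
#' @return Character vector of inaccessible element ids.
#' @export
find_inaccessible <- function(elements, accessibility_peaks, pad = 0) {
  check_intervals(elements, "elements")
  idc <- element_id_col(elements)
  padded <- dplyr::mutate(elements, start = pmax(0, .data$start - pad),
                          end = .data$end + pad)
  if (is.null(accessibility_peaks) || nrow(accessibility_peaks) == 0) {
    return(elements[[idc]])
  }
  n <- GenomicRanges::countOverlaps(as_granges0(padded),
                                    as_granges0(accessibility_peaks))
  elements[[idc]][n == 0]
}

#' Negative universe from inaccessibility
#'
#' A cis pair enters the negative universe when its enhancer is inaccessible
#' and/or its gene is inaccessible.
#'
#' @param cis_pairs Output of [enumerate_cis_pairs()].
#' @param inaccessible_enhancers,inaccessible_genes Id vectors from
#'   [find_inaccessible()].
#' @return Tibble `enhancer_id`, `gene_id`, `label = "negative"`.
#' @export
build_negative_universe <- function(cis_pairs, inaccessible_enhancers,
                                    inaccessible_genes) {
  cis_pairs |>
    dplyr::filter(.data$enhancer_id %in% inaccessible_enhancers |
                    .data$gene_id %in% inaccessible_genes) |>
    dplyr::distinct(.data$enhancer_id, .data$gene_id) |>
    dplyr::mutate(label = "negative")
}

#' Sample gene-matched negatives
#'
#' For each gene appearing in the positive set, up to `n_per_gene` negative
#' pairs targeting that same gene are drawn uniformly without replacement
#' from the negative universe. Genes are visited in sorted id order under a
#' single seed, so the draw is deterministic and independent of input row
#' order. Exact (enhancer, gene) duplicates of positives are excluded.
#'
#' @param universe Negative universe from [build_negative_universe()].
#' @param positives Positive pair tibble.
#' @param n_per_gene Negatives per positive-set gene (default 30).
#' @param seed Integer seed (mandatory).
#' @return Tibble `enhancer_id`, `gene_id`, `label = "negative"`.
#' @export
sample_matched_negatives <- function(universe, positives, n_per_gene = 30,
                                     seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory for reproducibility")
  pool <- universe[!paste(universe$enhancer_id, universe$gene_id) %in%
                     paste(positives$enhancer_id, positives$gene_id), ]
  genes <- sort(unique(positives$gene_id))
  set.seed(seed)
  drawn <- purrr::map(genes, function(g) {
    cand <- pool[pool$gene_id == g, ]
    cand <- cand[order(cand$enhancer_id), ]
    if (nrow(cand) == 0) {
      warn(sprintf("gene %s has no available negatives", g))
      return(cand)
    }
    if (nrow(cand) < n_per_gene) {
      warn(sprintf("gene %s has only %d negatives (requested %d); taking all",
                   g, nrow(cand), n_per_gene))
      return(cand)
    }
    cand[sample.int(nrow(cand), n_per_gene), ]
  })
  out <- dplyr::bind_rows(drawn)
  if (nrow(out)) out <- dplyr::arrange(out, .data$gene_id, .data$enhancer_id)
  dplyr::mutate(out, label = "negative")
}

#' Assemble a labeled, feature-attached dataset
#'
#' Joins the labeled pairs to their feature rows, fits standardization on the
#' dataset's own rows, and records class counts and prevalence. Overlap
#' between the positive and negative keys is a hard error.
#'
#' @param positives,negatives Labeled pair tibbles (`enhancer_id`, `gene_id`,
#'   optional `cell_type`).
#' @param features Feature matrix from [build_feature_matrix()] for the same
#'   cell type.
#' @param cell_type Cell-type tag applied to rows lacking one.
#' @param id Dataset identifier (defaults to `cell_type`).
#' @return An object of class `eg_dataset`.
#' @export
assemble_dataset <- function(positives, negatives, features,
                             cell_type = "cell", id = cell_type) {
  add_cell <- function(df) {
    if (!"cell_type" %in% names(df)) df$cell_type <- cell_type
    df
  }
  pos <- add_cell(dplyr::mutate(as_tibble(positives), label = "positive"))
  neg <- add_cell(dplyr::mutate(as_tibble(negatives), label = "negative"))
  if (any(pair_key(neg) %in% pair_key(pos))) {
    abort("pair(s) labeled both positive and negative")
  }
  pairs <- dplyr::bind_rows(pos, neg)[, c("enhancer_id", "gene_id",
                                          "cell_type", "label")]
  if (anyDuplicated(pair_key(pairs))) {
    abort("duplicate (enhancer, gene, cell type) rows in dataset")
  }
  features <- features[setdiff(names(features), c("cell_type", "label"))]
  fx <- dplyr::left_join(pairs, features, by = c("enhancer_id", "gene_id"))
  fcols <- intersect(c(feature_names(), "distance"), names(fx))
  miss <- !stats::complete.cases(fx[setdiff(fcols, "p300_enh")])
  if (any(miss)) {
    abort(sprintf("%d dataset pair(s) have no feature row", sum(miss)))
  }
  features_raw <- fx[c("enhancer_id", "gene_id", "cell_type", "label", fcols)]
  p300_available <- "p300_enh" %in% fcols && !anyNA(features_raw$p300_enh)
  std <- suppressWarnings(standardize_fit(features_raw))
  structure(list(
    id = id,
    cell_types = unique(pairs$cell_type),
    pairs = pairs,
    features_raw = features_raw,
    standardization = std,
    p300_available = p300_available,
    n_pos = sum(pairs$label == "positive"),
    n_neg = sum(pairs$label == "negative"),
    prevalence = mean(pairs$label == "positive")
  ), class = "eg_dataset")
}

#' @export
print.eg_dataset <- function(x, ...) {
  cat(sprintf("<eg_dataset '%s'> %d pairs (%d positive / %d negative, prevalence %.4g)\n",
              x$id, nrow(x$pairs), x$n_pos, x$n_neg, x$prevalence))
  cat(sprintf("  cell types: %s | P300 %s\n",
              paste(x$cell_types, collapse = ", "),
              if (x$p300_available) "available" else "missing"))
  invisible(x)
}

#' Pool datasets across cell types
#'
#' Concatenates the labeled pairs and their own cell type-specific feature
#' values, then refits standardization on the pooled rows. P300 features
#' survive pooling only when every component dataset has them.
#'
#' @param datasets List of `eg_dataset` objects.
#' @param id Identifier of the pooled dataset (default: component ids joined
#'   with `+`).
#' @return An `eg_dataset`.
#' @export
pool_datasets <- function(datasets,
                          id = paste(vapply(datasets, `[[`, "", "id"),
                                     collapse = "+")) {
  pairs <- dplyr::bind_rows(lapply(datasets, `[[`, "pairs"))
  if (anyDuplicated(pair_key(pairs))) {
    abort("pooling would duplicate an (enhancer, gene, cell type) key")
  }
  cls <- split(pairs$label, pair_key(pairs))
  features_raw <- dplyr::bind_rows(lapply(datasets, `[[`, "features_raw"))
  p300 <- all(vapply(datasets, `[[`, logical(1), "p300_available"))
  if (!p300 && "p300_enh" %in% names(features_raw)) {
    features_raw$p300_enh <- NA_real_
    features_raw <- compute_p300_na(features_raw)
  }
  std <- suppressWarnings(standardize_fit(features_raw))
  structure(list(
    id = id,
    cell_types = unique(pairs$cell_type),
    pairs = pairs,
    features_raw = features_raw,
    standardization = std,
    p300_available = p300,
    n_pos = sum(pairs$label == "positive"),
    n_neg = sum(pairs$label == "negative"),
    prevalence = mean(pairs$label == "positive")
  ), class = "eg_dataset")
}

# When p300 is structurally missing, no interaction involves it, so only the
# p300_enh column itself is blanked.
compute_p300_na <- function(features_raw) features_raw

# Standardized numeric matrix for modeling.
dataset_matrix <- function(dataset, feature_names) {
  fx <- standardize_apply(dataset$features_raw, dataset$standardization)
  missing <- setdiff(feature_names, names(fx))
  if (length(missing)) {
    abort(sprintf("dataset '%s' lacks feature(s): %s", dataset$id,
                  paste(missing, collapse = ", ")))
  }
  m <- as.matrix(fx[feature_names])
  if (anyNA(m)) {
    abort(sprintf("dataset '%s' has missing values in requested features (P300 absent?)",
                  dataset$id))
  }
  storage.mode(m) <- "double"
  m
}

dataset_labels <- function(dataset) as_label01(dataset$pairs$label)
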