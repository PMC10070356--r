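# Feature engineering for cis enhancer-gene pairs: the nine main features
# (enhancer marks H3K27ac/H3K4me1/P300, promoter marks H3K4me3/H3K27ac,
# combined eQTL Z-score and mean |slope|, nearest-gene and intronic flags),
# the eight interaction products, and training-set standardization.

main_feature_names <- c(
  "h3k27ac_enh", "h3k4me1_enh", "h3k4me3_prom", "p300_enh", "eqtl_z",
  "nearest_gene", "intronic", "eqtl_avg_abs_coef", "h3k27ac_prom"
)

# Interaction terms: products of enhancer-mark and promoter-mark factors
# (row-major over the enhancer x promoter grid), then the significance-by-
# effect eQTL interaction and the double enhancer-mark interaction. The
# promoter H3K27ac factor is the continuous promoter score; the promoter
# H3K4me3 factor is the binary call.
interaction_spec <- list(
  h3k27ac_enh_x_h3k27ac_prom = c("h3k27ac_enh", "h3k27ac_prom"),
  h3k27ac_enh_x_h3k4me3_prom = c("h3k27ac_enh", "h3k4me3_prom"),
  h3k4me1_enh_x_h3k27ac_prom = c("h3k4me1_enh", "h3k27ac_prom"),
  h3k4me1_enh_x_h3k4me3_prom = c("h3k4me1_enh", "h3k4me3_prom"),
  h3k27ac_enh_x_h3k4me1_enh_x_h3k27ac_prom =
    c("h3k27ac_enh", "h3k4me1_enh", "h3k27ac_prom"),
  h3k27ac_enh_x_h3k4me1_enh_x_h3k4me3_prom =
    c("h3k27ac_enh", "h3k4me1_enh", "h3k4me3_prom"),
  eqtl_z_x_eqtl_avg_abs_coef = c("eqtl_z", "eqtl_avg_abs_coef"),
  h3k27ac_enh_x_h3k4me1_enh = c("h3k27ac_enh", "h3k4me1_enh")
)

binary_feature_names <- c("h3k27ac_enh", "h3k4me3_prom", "nearest_gene",
                          "intronic", "h3k27ac_enh_x_h3k4me3_prom")

#' Feature names used by the pipeline
#'
#' @param p300 Include the P300 enhancer feature? Cell types without P300
#'   ChIP-seq data drop it (the alternate-model feature space).
#' @return Character vector of the (up to 17) feature column names, in
#'   canonical order: nine main features then eight interaction terms.
#' @export
feature_names <- function(p300 = TRUE) {
  out <- c(main_feature_names, names(interaction_spec))
  if (!p300) out <- setdiff(out, "p300_enh")
  out
}

#' Pipeline feature configuration
#'
#' @param peak_overlap Fractional-overlap threshold for assigning a ChIP peak
#'   to an enhancer or promoter (default 0.5, either-region semantics).
#' @param overlap_mode Overlap semantics: `"either"`, `"reciprocal"` or
#'   `"of-first"`.
#' @param promoter_up,promoter_down Promoter extent around the TSS in bp
#'   (strand-aware; default 1 kb each side).
#' @param eqtl_method p-value combination for the eQTL Z feature:
#'   `"stouffer"` (default) or `"fisher"` (Fisher combination mapped back to
#'   a Z quantile).
#' @param window Cis window half-width in bp.
#' @param high_enhancer_ids,high_promoter_gene_ids Optional precomputed
#'   "high-signal" element lists (emulating a cCRE registry) for the binary
#'   H3K27ac-enhancer and H3K4me3-promoter features; when `NULL` the binary
#'   call is computed from the peaks at `peak_overlap`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(peak_overlap = 0.5, overlap_mode = "either",
                           promoter_up = 1000, promoter_down = 1000,
                           eqtl_method = c("stouffer", "fisher"),
                           window = 1e6,
                           high_enhancer_ids = NULL,
                           high_promoter_gene_ids = NULL) {
  structure(list(peak_overlap = peak_overlap, overlap_mode = overlap_mode,
                 promoter_up = promoter_up, promoter_down = promoter_down,
                 eqtl_method = match.arg(eqtl_method), window = window,
                 high_enhancer_ids = high_enhancer_ids,
                 high_promoter_gene_ids = high_promoter_gene_ids),
            class = "feature_config")
}

#' Combine eQTL p-values into a single Z-score
#'
#' Stouffer's method on one-sided z-values: `Z = sum(qnorm(1 - p)) / sqrt(k)`.
#' The `"fisher"` alternative combines via `-2 * sum(log p)` against a
#' chi-squared with `2k` df, then maps the combined tail probability back to
#' a normal quantile. An empty vector returns 0 (absence of evidence).
#'
#' @param p Numeric vector of p-values in `(0, 1]`; may be empty.
#' @param method `"stouffer"` (default) or `"fisher"`.
#' @return A single Z value.
#' @export
combined_eqtl_z <- function(p, method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  if (length(p) == 0) return(0)
  if (any(p <= 0 | p > 1)) abort("p values must be in (0, 1]")
  if (method == "stouffer") {
    sum(qnorm(p, lower.tail = FALSE)) / sqrt(length(p))
  } else {
    x2 <- -2 * sum(log(p))
    lp <- pchisq(x2, df = 2 * length(p), lower.tail = FALSE, log.p = TRUE)
    qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  }
}

#' Average absolute eQTL effect size
#'
#' @param slopes Numeric vector of signed eQTL slopes; may be empty.
#' @return Mean of `|slopes|`; 0 when empty.
#' @export
avg_abs_coeff <- function(slopes) {
  if (length(slopes) == 0) return(0)
  mean(abs(slopes))
}

#' Peak-derived feature value for a set of regions
#'
#' A peak qualifies for a region when their overlap passes the fractional
#' threshold (either-region semantics by default). `"binary"` returns 1 when
#' any peak qualifies; `"continuous"` returns the maximum score among
#' qualifying peaks (0 when none).
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`), one row per
#'   region.
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `score`), one assay.
#' @param mode `"binary"` or `"continuous"`.
#' @param threshold Overlap fraction threshold (default 0.5).
#' @param overlap_mode See [meets_overlap_threshold()].
#' @return Numeric vector aligned to `regions` rows.
#' @export
peak_feature <- function(regions, peaks, mode = c("binary", "continuous"),
                         threshold = 0.5, overlap_mode = "either") {
  mode <- match.arg(mode)
  check_intervals(regions, "regions")
  if (nrow(regions) == 0) return(numeric())
  if (is.null(peaks) || nrow(peaks) == 0) return(rep(0, nrow(regions)))
  check_intervals(peaks, "peaks")
  hits <- GenomicRanges::findOverlaps(as_granges0(regions), as_granges0(peaks))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- meets_overlap_threshold(regions[qi, c("chrom", "start", "end")],
                                  peaks[si, c("chrom", "start", "end")],
                                  threshold = threshold, mode = overlap_mode)
  qi <- qi[keep]; si <- si[keep]
  out <- rep(0, nrow(regions))
  if (length(qi)) {
    agg <- tapply(peaks$score[si], qi, max)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  if (mode == "binary") as.numeric(out > 0 | seq_len(nrow(regions)) %in% qi)
  else out
}

#' Strand-aware promoter window around the TSS
#'
#' `[tss - up, tss + down)` on `+` genes, mirrored on `-` genes, clipped at
#' the chromosome start.
#'
#' @param genes Gene tibble with `gene_id`, `chrom`, `strand`, `tss`.
#' @param up,down Extent upstream/downstream of the TSS in bp.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_region <- function(genes, up = 1000, down = 1000) {
  s <- ifelse(genes$strand == "+", genes$tss - up, genes$tss - down)
  e <- ifelse(genes$strand == "+", genes$tss + down, genes$tss + up)
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = as.integer(pmax(0, s)), end = as.integer(e))
}

# Check that every auxiliary input shares chromosome names with the
# enhancer/gene universe; mixed naming (chr1 vs 1) is a hard error.
check_chrom_consistency <- function(universe, inputs) {
  offenders <- purrr::imap(inputs, function(df, nm) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    if (!length(intersect(unique(df$chrom), universe))) {
      sprintf("%s (chroms: %s)", nm,
              paste(head(unique(df$chrom), 3), collapse = ", "))
    } else NULL
  })
  offenders <- purrr::compact(offenders)
  if (length(offenders)) {
    abort(paste0("chromosome names irreconcilable with enhancer/gene inputs: ",
                 paste(unlist(offenders), collapse = "; ")))
  }
  invisible(TRUE)
}

#' Build the feature matrix for a set of cis pairs
#'
#' Computes the nine main features and eight interaction products for each
#' pair. eQTLs are attributed to a pair when the variant position lies inside
#' the enhancer and the eQTL targets the pair's gene. When no P300 peaks are
#' supplied the `p300_enh` column is `NA` and the table is flagged
#' (`attr(., "p300_available") == FALSE`): the feature is structurally
#' missing for that cell type, not zero.
#'
#' @param pairs Cis pairs from [enumerate_cis_pairs()] (`enhancer_id`,
#'   `gene_id`).
#' @param enhancers,genes Element tables.
#' @param peaks Peak tibble with an `assay` column covering any of H3K27ac,
#'   H3K4me1, H3K4me3, P300 (accessibility assays are ignored here).
#' @param eqtls Optional eQTL tibble (see [read_eqtl_tsv()]).
#' @param config A [feature_config()].
#' @return Tibble: `enhancer_id`, `gene_id`, then the feature columns of
#'   [feature_names()]; attribute `p300_available`.
#' @export
build_feature_matrix <- function(pairs, enhancers, genes, peaks,
                                 eqtls = NULL, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  universe <- union(unique(enhancers$chrom), unique(genes$chrom))
  check_chrom_consistency(universe,
                          list(peaks = peaks,
                               eqtls = eqtls %||% tibble(chrom = character())))
  pk <- function(assay) peaks[peaks$assay == assay, , drop = FALSE]
  p300_available <- !is.null(peaks) && any(peaks$assay == "P300")

  enh <- enhancers[enhancers$enhancer_id %in% pairs$enhancer_id, ]
  ereg <- enh[c("chrom", "start", "end")]
  efeat <- tibble(
    enhancer_id = enh$enhancer_id,
    h3k27ac_enh = if (!is.null(config$high_enhancer_ids)) {
      as.numeric(enh$enhancer_id %in% config$high_enhancer_ids)
    } else {
      peak_feature(ereg, pk("H3K27ac"), "binary", config$peak_overlap,
                   config$overlap_mode)
    },
    h3k4me1_enh = peak_feature(ereg, pk("H3K4me1"), "continuous",
                               config$peak_overlap, config$overlap_mode),
    p300_enh = if (p300_available) {
      peak_feature(ereg, pk("P300"), "continuous", config$peak_overlap,
                   config$overlap_mode)
    } else NA_real_
  )

  gen <- genes[genes$gene_id %in% pairs$gene_id, ]
  prom <- promoter_region(gen, config$promoter_up, config$promoter_down)
  preg <- prom[c("chrom", "start", "end")]
  gfeat <- tibble(
    gene_id = gen$gene_id,
    h3k4me3_prom = if (!is.null(config$high_promoter_gene_ids)) {
      as.numeric(gen$gene_id %in% config$high_promoter_gene_ids)
    } else {
      peak_feature(preg, pk("H3K4me3"), "binary", config$peak_overlap,
                   config$overlap_mode)
    },
    h3k27ac_prom = peak_feature(preg, pk("H3K27ac"), "continuous",
                                config$peak_overlap, config$overlap_mode)
  )

  ng <- nearest_gene(enh, genes)
  out <- pairs |>
    dplyr::select("enhancer_id", "gene_id") |>
    dplyr::left_join(efeat, by = "enhancer_id") |>
    dplyr::left_join(gfeat, by = "gene_id") |>
    dplyr::left_join(dplyr::select(ng, "enhancer_id", "nearest_gene_id"),
                     by = "enhancer_id") |>
    dplyr::mutate(nearest_gene = as.numeric(.data$gene_id == .data$nearest_gene_id),
                  nearest_gene_id = NULL)
  out$intronic <- as.numeric(is_intronic(out, enhancers, genes))

  if (!is.null(eqtls) && nrow(eqtls) > 0) {
    hits <- dplyr::inner_join(
      dplyr::select(enh, "enhancer_id", "chrom", "start", "end"),
      dplyr::select(eqtls, "chrom", "position", eqtl_gene = "gene_id",
                    "p_value", "slope"),
      by = "chrom", relationship = "many-to-many") |>
      dplyr::filter(.data$position >= .data$start, .data$position < .data$end)
    eq <- hits |>
      dplyr::group_by(.data$enhancer_id, gene_id = .data$eqtl_gene) |>
      dplyr::summarise(
        eqtl_z = combined_eqtl_z(.data$p_value, method = config$eqtl_method),
        eqtl_avg_abs_coef = avg_abs_coeff(.data$slope), .groups = "drop")
    out <- dplyr::left_join(out, eq, by = c("enhancer_id", "gene_id"))
  } else {
    out$eqtl_z <- NA_real_
    out$eqtl_avg_abs_coef <- NA_real_
  }
  out$eqtl_z[is.na(out$eqtl_z)] <- 0
  out$eqtl_avg_abs_coef[is.na(out$eqtl_avg_abs_coef)] <- 0

  out <- compute_interactions(out)
  out <- out[c("enhancer_id", "gene_id", feature_names(p300 = TRUE))]
  attr(out, "p300_available") <- p300_available
  out
}

#' Add interaction-term columns to a main-feature table
#'
#' Each interaction column is the exact product of its named factor columns,
#' computed on the raw (pre-standardization) scale.
#'
#' @param features Tibble containing the main feature columns.
#' @return `features` with the interaction columns appended/overwritten.
#' @export
compute_interactions <- function(features) {
  for (nm in names(interaction_spec)) {
    factors <- interaction_spec[[nm]]
    missing <- setdiff(factors, names(features))
    if (length(missing)) {
      abort(sprintf("interaction %s needs missing column(s): %s", nm,
                    paste(missing, collapse = ", ")))
    }
    features[[nm]] <- Reduce(`*`, lapply(factors, function(f) features[[f]]))
  }
  features
}

#' Fit standardization parameters on training rows
#'
#' Continuous features are rescaled to mean 0, sd 1 (sample sd). Binary
#' features are left untouched; constant columns are flagged and passed
#' through unscaled.
#'
#' @param features Feature tibble (id columns are ignored).
#' @param cols Columns to standardize; default: every feature column present
#'   that is not a canonical binary feature and not all-`NA`.
#' @return An object of class `standardization_params`.
#' @export
standardize_fit <- function(features, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(intersect(c(feature_names(), "distance"), names(features)),
                    binary_feature_names)
    cols <- cols[vapply(cols, function(cl) !all(is.na(features[[cl]])),
                        logical(1))]
  }
  mu <- vapply(cols, function(cl) mean(features[[cl]]), numeric(1))
  sg <- vapply(cols, function(cl) sd(features[[cl]]), numeric(1))
  constant <- cols[is.na(sg) | sg == 0]
  if (length(constant)) {
    warn(sprintf("constant column(s) left unscaled: %s",
                 paste(constant, collapse = ", ")))
  }
  structure(list(columns = cols, mean = mu, sd = sg, constant = constant),
            class = "standardization_params")
}

#' Apply previously fitted standardization parameters
#'
#' @param features Feature tibble.
#' @param params A `standardization_params` object from [standardize_fit()].
#' @return `features` with the fitted columns rescaled by the training
#'   mean/sd (constant columns passed through).
#' @export
standardize_apply <- function(features, params) {
  stopifnot(inherits(params, "standardization_params"))
  for (cl in setdiff(params$columns, params$constant)) {
    if (!cl %in% names(features)) {
      abort(sprintf("column %s absent from features", cl))
    }
    features[[cl]] <- (features[[cl]] - params$mean[[cl]]) / params$sd[[cl]]
  }
  features
}
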