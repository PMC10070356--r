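# Coordinate logic: fractional overlap, cis-pair enumeration, nearest-gene and
# intronic calls, and mapping of external enhancer coordinates onto a catalog.

#' Fractional overlap between paired intervals
#'
#' Computes, for each row pair, the length of the intersection divided by the
#' length of each interval. Intervals are 0-based half-open, so adjacent
#' intervals (`end == start`) do not overlap. Rows on different chromosomes
#' return `(0, 0)`.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`. Either may have
#'   one row, which is recycled against the other.
#' @return A tibble with columns `frac_a` and `frac_b`, each in `[0, 1]`.
#' @examples
#' overlap_fraction(
#'   tibble::tibble(chrom = "chr1", start = 10, end = 20),
#'   tibble::tibble(chrom = "chr1", start = 15, end = 25)
#' )
#' @export
overlap_fraction <- function(a, b) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != nrow(b) && nrow(a) != 1 && nrow(b) != 1) {
    abort("a and b must have the same number of rows (or one row to recycle)")
  }
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  sa <- a$start[idx_a]; ea <- a$end[idx_a]
  sb <- b$start[idx_b]; eb <- b$end[idx_b]
  inter <- pmax(0, pmin(ea, eb) - pmax(sa, sb))
  inter[a$chrom[idx_a] != b$chrom[idx_b]] <- 0
  tibble(frac_a = inter / (ea - sa), frac_b = inter / (eb - sb))
}

#' Test a fractional-overlap threshold between paired intervals
#'
#' @param a,b Interval tables as in [overlap_fraction()].
#' @param threshold Minimum overlap fraction in `(0, 1]`.
#' @param mode `"either"` (default): pass if the intersection covers at least
#'   `threshold` of *either* interval; `"reciprocal"`: of both; `"of-first"`:
#'   of `a` only.
#' @return Logical vector, one element per row pair.
#' @export
meets_overlap_threshold <- function(a, b, threshold = 0.5,
                                    mode = c("either", "reciprocal", "of-first")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  fr <- overlap_fraction(a, b)
  switch(mode,
    either = fr$frac_a >= threshold | fr$frac_b >= threshold,
    reciprocal = fr$frac_a >= threshold & fr$frac_b >= threshold,
    `of-first` = fr$frac_a >= threshold
  )
}

#' Enumerate all cis enhancer-gene pairs
#'
#' A pair is *cis* when the enhancer intersects the window
#' `[tss - window, tss + window)` around the gene's transcription start site by
#' at least one base. Output is sorted by `(gene_id, enh_start)` and
#' duplicate-free.
#'
#' @param enhancers Tibble with `enhancer_id`, `chrom`, `start`, `end`.
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `tss` (and gene body
#'   `start`/`end`).
#' @param window Half-width of the cis window in bp (default 1 Mb).
#' @return Tibble with one row per cis pair: `enhancer_id`, `gene_id`, `chrom`,
#'   `enh_start`, `enh_end`, `tss`.
#' @export
enumerate_cis_pairs <- function(enhancers, genes, window = 1e6) {
  check_intervals(enhancers, "enhancers", require = "enhancer_id")
  if (nrow(enhancers) == 0 || nrow(genes) == 0) {
    return(tibble(enhancer_id = character(), gene_id = character(),
                  chrom = character(), enh_start = integer(),
                  enh_end = integer(), tss = integer()))
  }
  if (!all(c("gene_id", "tss", "chrom") %in% names(genes))) {
    abort("genes needs columns gene_id, chrom, tss")
  }
  win <- tibble(chrom = genes$chrom,
                start = pmax(0, genes$tss - window),
                end = genes$tss + window)
  hits <- GenomicRanges::findOverlaps(as_granges0(enhancers), as_granges0(win))
  out <- tibble(
    enhancer_id = enhancers$enhancer_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    chrom = enhancers$chrom[S4Vectors::queryHits(hits)],
    enh_start = enhancers$start[S4Vectors::queryHits(hits)],
    enh_end = enhancers$end[S4Vectors::queryHits(hits)],
    tss = genes$tss[S4Vectors::subjectHits(hits)]
  )
  out <- dplyr::distinct(out, .data$enhancer_id, .data$gene_id, .keep_all = TRUE)
  dplyr::arrange(out, .data$gene_id, .data$enh_start)
}

#' Nearest gene for each enhancer
#'
#' Distance is measured from the enhancer midpoint to the gene TSS; ties are
#' broken by the lexicographically smaller gene id so the result is invariant
#' under permutation of the gene table.
#'
#' @inheritParams enumerate_cis_pairs
#' @return Tibble `enhancer_id`, `nearest_gene_id`, `distance`.
#' @export
nearest_gene <- function(enhancers, genes) {
  check_intervals(enhancers, "enhancers", require = "enhancer_id")
  orphan <- setdiff(unique(enhancers$chrom), unique(genes$chrom))
  if (length(orphan)) {
    abort(sprintf("no gene on chromosome(s): %s", paste(orphan, collapse = ", ")))
  }
  mids <- enhancers |>
    dplyr::transmute(.data$enhancer_id, .data$chrom,
                     mid = (.data$start + .data$end) / 2)
  dplyr::inner_join(mids,
                    dplyr::select(genes, gene_id = "gene_id", "chrom", "tss"),
                    by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(distance = abs(.data$mid - .data$tss)) |>
    dplyr::arrange(.data$enhancer_id, .data$distance, .data$gene_id) |>
    dplyr::distinct(.data$enhancer_id, .keep_all = TRUE) |>
    dplyr::select("enhancer_id", nearest_gene_id = "gene_id", "distance")
}

#' Is each enhancer intronic within its paired gene?
#'
#' An enhancer is intronic for a gene when it lies fully inside the gene body
#' and intersects none of the gene's exons. For genes with no exon annotation
#' the whole body counts as non-exonic, so full containment alone suffices
#' (a data-quality warning is emitted once).
#'
#' @param pairs Tibble with `enhancer_id`, `gene_id`.
#' @param enhancers,genes Element tables; `genes` may carry an `exons`
#'   list-column of tibbles with `start`/`end`.
#' @return Logical vector aligned to `pairs` rows.
#' @export
is_intronic <- function(pairs, enhancers, genes) {
  if (nrow(pairs) == 0) return(logical())
  e <- dplyr::select(enhancers, "enhancer_id", e_chrom = "chrom",
                     e_start = "start", e_end = "end")
  g <- dplyr::select(genes, "gene_id", g_chrom = "chrom",
                     g_start = "start", g_end = "end",
                     dplyr::any_of("exons"))
  if (!"exons" %in% names(g)) g$exons <- rep(list(NULL), nrow(g))
  df <- pairs |>
    dplyr::left_join(e, by = "enhancer_id") |>
    dplyr::left_join(g, by = "gene_id")
  inside <- df$e_chrom == df$g_chrom &
    df$e_start >= df$g_start & df$e_end <= df$g_end
  inside[is.na(inside)] <- FALSE
  no_exons <- vapply(df$exons, function(x) is.null(x) || nrow(x) == 0, logical(1))
  if (any(inside & no_exons)) {
    warn("gene(s) with no exon annotation: whole gene body treated as non-exonic")
  }
  hits_exon <- rep(FALSE, nrow(df))
  idx <- which(inside & !no_exons)
  for (i in idx) {
    ex <- df$exons[[i]]
    hits_exon[i] <- any(pmin(df$e_end[i], ex$end) - pmax(df$e_start[i], ex$start) > 0)
  }
  inside & !hits_exon
}

#' Map external enhancer intervals onto a reference catalog
#'
#' Each external interval maps to every catalog enhancer whose overlap passes
#' [meets_overlap_threshold()] at `min_frac` (default 33%, either-region
#' semantics). Intervals that map nowhere are reported separately.
#'
#' @param external Tibble with `chrom`, `start`, `end` and optionally an
#'   `external_id` column (defaults to `chrom:start-end`).
#' @param catalog Enhancer catalog tibble (`enhancer_id`, `chrom`, `start`,
#'   `end`).
#' @param min_frac Overlap fraction threshold in `(0, 1]`.
#' @param mode Overlap semantics, see [meets_overlap_threshold()].
#' @return List with `mapped` (tibble `external_id`, `enhancer_id`,
#'   `frac_external`, `frac_catalog`) and `unmapped` (tibble of unmapped
#'   external rows).
#' @export
map_external_enhancers <- function(external, catalog, min_frac = 0.33,
                                   mode = "either") {
  check_intervals(external, "external")
  check_intervals(catalog, "catalog", require = "enhancer_id")
  external <- as_tibble(external)
  if (!"external_id" %in% names(external)) {
    external$external_id <- sprintf("%s:%d-%d", external$chrom,
                                    as.integer(external$start),
                                    as.integer(external$end))
  }
  if (nrow(external) == 0 || nrow(catalog) == 0) {
    return(list(mapped = tibble(external_id = character(),
                                enhancer_id = character(),
                                frac_external = double(),
                                frac_catalog = double()),
                unmapped = external))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(external), as_granges0(catalog))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  fr <- overlap_fraction(external[qi, c("chrom", "start", "end")],
                         catalog[si, c("chrom", "start", "end")])
  keep <- meets_overlap_threshold(external[qi, c("chrom", "start", "end")],
                                  catalog[si, c("chrom", "start", "end")],
                                  threshold = min_frac, mode = mode)
  mapped <- tibble(external_id = external$external_id[qi],
                   enhancer_id = catalog$enhancer_id[si],
                   frac_external = fr$frac_a,
                   frac_catalog = fr$frac_b)[keep, ] |>
    dplyr::distinct() |>
    dplyr::arrange(.data$external_id, .data$enhancer_id)
  unmapped <- external[!external$external_id %in% mapped$external_id, ]
  list(mapped = mapped, unmapped = unmapped)
}
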