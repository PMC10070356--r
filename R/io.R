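# Readers/writers for the plain-text dialects the pipeline exchanges:
# BED4+ for enhancers and peaks, BED12 for gene models (blocks -> exons),
# TSV for eQTLs, curated links, screen results, feature matrices and scores.
# All readers emit 0-based half-open coordinates unchanged (BED is already
# 0-based half-open).

bed_cols <- c("chrom", "start", "end", "name", "score", "strand",
              "thick_start", "thick_end", "item_rgb", "block_count",
              "block_sizes", "block_starts")

read_bed_raw <- function(path, n_min = 3) {
  # read everything as character: BED12 block lists ("1000,5000,") must not
  # be parsed as grouped numbers
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < n_min) {
    abort(sprintf("%s: expected at least %d BED columns, found %d",
                  path, n_min, ncol(df)))
  }
  names(df) <- bed_cols[seq_len(ncol(df))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Read an enhancer catalog from BED4
#'
#' @param path Path to a BED file with at least `chrom start end name`.
#' @return Tibble `enhancer_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
read_enhancer_bed <- function(path) {
  df <- read_bed_raw(path, n_min = 4)
  out <- tibble(enhancer_id = as.character(df$name), chrom = df$chrom,
                start = df$start, end = df$end)
  check_intervals(out, path)
  out
}

#' Write an enhancer catalog as BED4
#' @param enhancers Tibble `enhancer_id`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enhancer_bed <- function(enhancers, path) {
  readr::write_tsv(dplyr::select(enhancers, "chrom", "start", "end",
                                 "enhancer_id"),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read ChIP-seq / accessibility peaks from BED5
#'
#' @param path BED file `chrom start end name score`.
#' @param assay Mark label to attach (e.g. `"H3K27ac"`, `"DNase"`).
#' @return Tibble `chrom`, `start`, `end`, `score`, `assay`.
#' @export
read_peak_bed <- function(path, assay) {
  df <- read_bed_raw(path, n_min = 3)
  score <- if ("score" %in% names(df)) as.numeric(df$score) else 0
  if (any(score < 0, na.rm = TRUE)) abort(sprintf("%s: negative peak scores", path))
  out <- tibble(chrom = df$chrom, start = df$start, end = df$end,
                score = score, assay = assay)
  check_intervals(out, path)
  out
}

#' Write peaks as BED5
#' @param peaks Tibble with `chrom`, `start`, `end`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_bed <- function(peaks, path) {
  out <- dplyr::mutate(peaks, name = sprintf("peak_%d", dplyr::row_number()))
  readr::write_tsv(dplyr::select(out, "chrom", "start", "end", "name", "score"),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from BED12
#'
#' Blocks become exons (absolute, 0-based half-open). The TSS is the body
#' start on `+` genes and `end - 1` on `-` genes.
#'
#' @param path BED12 file.
#' @return Gene tibble: `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`,
#'   and an `exons` list-column of tibbles with `start`/`end`.
#' @export
read_gene_bed12 <- function(path) {
  df <- read_bed_raw(path, n_min = 12)
  exons <- purrr::pmap(list(df$start, df$block_sizes, df$block_starts),
    function(s, sizes, starts) {
      sz <- as.integer(strsplit(as.character(sizes), ",")[[1]])
      st <- as.integer(strsplit(as.character(starts), ",")[[1]])
      tibble(start = s + st, end = s + st + sz)
    })
  out <- tibble(gene_id = as.character(df$name), chrom = df$chrom,
                start = df$start, end = df$end,
                strand = as.character(df$strand),
                tss = ifelse(df$strand == "+", df$start, df$end - 1L),
                exons = exons)
  check_intervals(out, path)
  if (!all(out$strand %in% c("+", "-"))) abort(sprintf("%s: strand must be + or -", path))
  out
}

#' Write gene models as BED12
#' @param genes Gene tibble as returned by [read_gene_bed12()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed12 <- function(genes, path) {
  rows <- purrr::pmap_chr(
    list(genes$chrom, genes$start, genes$end, genes$gene_id, genes$strand,
         genes$exons),
    function(chrom, s, e, id, strand, ex) {
      if (is.null(ex) || nrow(ex) == 0) ex <- tibble(start = s, end = e)
      paste(chrom, s, e, id, 0, strand, s, e, "0", nrow(ex),
            paste0(paste(ex$end - ex$start, collapse = ","), ","),
            paste0(paste(ex$start - s, collapse = ","), ","),
            sep = "\t")
    })
  writeLines(rows, path)
  invisible(path)
}

#' Read a cis-eQTL table
#'
#' Expected TSV columns: `chrom`, `position` (0-based bp), `gene_id`,
#' `p_value`, `slope`.
#'
#' @param path TSV path.
#' @return Tibble with those columns.
#' @export
read_eqtl_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "position", "gene_id", "p_value", "slope")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing eQTL column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (any(df$p_value <= 0 | df$p_value > 1)) {
    abort(sprintf("%s: eQTL p values must be in (0, 1]", path))
  }
  as_tibble(df[need])
}

#' Read a curated positive-link table
#'
#' Expected TSV columns: `chrom`, `start`, `end`, `gene_id`, `criterion`
#' (evidence class 1-5), `cell_type`; extra columns are kept.
#'
#' @param path TSV path.
#' @return Tibble of curated links.
#' @export
read_curated_links <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "criterion", "cell_type")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing curated-link column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  bad <- which(!(df$criterion %in% 1:5))
  if (length(bad)) {
    abort(sprintf("%s: criterion outside 1..5 at line(s) %s", path,
                  paste(bad + 1L, collapse = ", ")))
  }
  bad <- which(df$end <= df$start | df$start < 0)
  if (length(bad)) {
    abort(sprintf("%s: malformed coordinates at line(s) %s", path,
                  paste(bad + 1L, collapse = ", ")))
  }
  as_tibble(df)
}

#' Write a generic package TSV (feature matrices, score tables, reports)
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a package TSV written by [write_table_tsv()]
#' @param path TSV path.
#' @return Tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
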