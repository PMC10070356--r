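# Internal validators and coordinate helpers. All coordinates package-wide are
# 0-based, half-open [start, end) on named chromosomes (BED convention).

check_intervals <- function(df, what = "interval table", require = character()) {
  if (!is.data.frame(df)) {
    abort(sprintf("%s must be a data frame", what))
  }
  need <- c("chrom", "start", "end", require)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) {
    abort(sprintf("%s has negative start coordinates", what))
  }
  if (any(df$end <= df$start)) {
    abort(sprintf("%s has zero- or negative-length intervals (end must exceed start)",
                  what))
  }
  invisible(df)
}

# Convert a 0-based half-open interval table to GRanges (1-based closed).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Detect the identifier column of an element table.
element_id_col <- function(df) {
  cand <- intersect(c("enhancer_id", "gene_id", "id", "name"), names(df))
  if (!length(cand)) {
    abort("element table needs one of: enhancer_id, gene_id, id, name")
  }
  cand[[1]]
}

# Standard 0/1 label vector from assorted encodings.
as_label01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("positive", "negative"))
    if (length(bad)) {
      abort(sprintf("unrecognized label value(s): %s", paste(bad, collapse = ", ")))
    }
    return(as.integer(labels == "positive"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  abort("labels must be character positive/negative, logical, or 0/1")
}

pair_key <- function(df) {
  cell <- if ("cell_type" %in% names(df)) df$cell_type else ""
  paste(df$enhancer_id, df$gene_id, cell, sep = "\r")
}
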