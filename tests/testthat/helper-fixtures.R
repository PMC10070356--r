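# Shared in-code fixtures and independent brute-force oracles.

tiny_enhancers <- function() {
  tibble::tibble(
    enhancer_id = c("E1", "E2", "E3", "E4"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 5000L, 1200000L, 500L),
    end = c(600L, 5400L, 1200500L, 900L)
  )
}

# One + gene with two exons (intron 2000-4000 relative 1000..9000 body),
# one - gene, one exonless gene on chr2.
tiny_genes <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 50000L, 100L),
    end = c(9000L, 70000L, 5000L),
    strand = c("+", "-", "+"),
    tss = c(1000L, 69999L, 100L),
    exons = list(
      tibble::tibble(start = c(1000L, 4000L), end = c(2000L, 9000L)),
      tibble::tibble(start = c(50000L, 60000L), end = c(52000L, 70000L)),
      tibble::tibble(start = integer(), end = integer())
    )
  )
}

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(5000, n, replace = TRUE))
}

# O(n*m) all-pairs cis enumeration oracle.
brute_cis_pairs <- function(enhancers, genes, window = 1e6) {
  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    for (j in seq_len(nrow(genes))) {
      if (enhancers$chrom[i] != genes$chrom[j]) next
      lo <- max(0, genes$tss[j] - window)
      hi <- genes$tss[j] + window
      if (enhancers$start[i] < hi && enhancers$end[i] > lo) {
        out[[length(out) + 1]] <- tibble::tibble(
          enhancer_id = enhancers$enhancer_id[i], gene_id = genes$gene_id[j])
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), gene_id, enhancer_id)
}

# Threshold-enumeration AUPRC oracle (average precision, tied scores grouped).
brute_auprc <- function(scores, labels) {
  y <- as.integer(labels == "positive" | labels == 1 | labels == TRUE)
  P <- sum(y)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    prec <- tp / sum(pred)
    rec <- tp / P
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# All-pairs Mann-Whitney AUC oracle (ties count 1/2).
brute_auc <- function(scores, labels) {
  y <- as.integer(labels == "positive" | labels == 1 | labels == TRUE)
  sp <- scores[y == 1]
  sn <- scores[y == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Small, fast synthetic bundle shared across tests (built once per run).
small_config <- function(seed = 7, ...) {
  synthetic_config(n_chromosomes = 2, chrom_length = 3e6, n_genes = 30,
                   n_enhancers = 200, n_active_links = 20, seed = seed, ...)
}

.bundle_cache <- new.env(parent = emptyenv())
cached_small_bundle <- function() {
  if (is.null(.bundle_cache$b)) {
    .bundle_cache$b <- simulate_regulatory_genome(small_config())
  }
  .bundle_cache$b
}
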