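# Synthetic regulatory-genome generator. Produces a self-contained toy
# bundle (enhancer catalog, gene models with exons, accessibility peaks,
# per-cell-type histone/P300 peaks, eQTL tables, curated positive links and
# a ground-truth active-link list) with plantable signal, so every pipeline
# stage is testable without external data.

#' Configuration for the synthetic regulatory genome
#'
#' Active pairs receive each supporting mark/eQTL independently with
#' probability `signal_strength`; any element can pick up a spurious mark
#' with probability `background_rate`. Planted eQTLs draw p log-uniformly in
#' `[1e-8, 1e-3]` with Normal(0, 0.5) slopes; background eQTLs draw p
#' uniformly in `[0.05, 1]`. `inaccessible_fraction` of enhancers and genes
#' receive no accessibility peaks and seed the negative universe.
#'
#' @param n_chromosomes,chrom_length Genome shape (default two 5 Mb
#'   chromosomes).
#' @param n_genes,n_enhancers Element counts (default 60 genes, 400
#'   enhancers).
#' @param n_active_links Planted active pairs per cell type (default 40).
#' @param signal_strength,background_rate Planting probabilities (defaults
#'   0.9 / 0.05).
#' @param inaccessible_fraction Fraction of elements left without
#'   accessibility peaks (default 0.5).
#' @param n_cell_types Emulated cell types; each redraws its own active set
#'   and peaks over the shared coordinates (default 2).
#' @param window Cis window half-width in bp.
#' @param seed Integer seed (mandatory; the whole bundle is deterministic
#'   given the config).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 2, chrom_length = 5e6,
                             n_genes = 60, n_enhancers = 400,
                             n_active_links = 40,
                             signal_strength = 0.9, background_rate = 0.05,
                             inaccessible_fraction = 0.5,
                             n_cell_types = 2, window = 1e6, seed = 1L) {
  stopifnot(signal_strength >= 0, signal_strength <= 1,
            background_rate >= 0, background_rate <= 1,
            inaccessible_fraction >= 0, inaccessible_fraction < 1,
            n_genes >= 2, n_enhancers >= 2, n_cell_types >= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

runif_int <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1))

# Random gene models with 2-6 exons partitioning the body.
simulate_genes <- function(cfg, chroms) {
  len <- runif_int(cfg$n_genes, 5e3, 8e4)
  chrom <- sample(chroms, cfg$n_genes, replace = TRUE)
  start <- runif_int(cfg$n_genes, 1e4, cfg$chrom_length - max(len) - 1e4)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  exons <- lapply(seq_len(cfg$n_genes), function(i) {
    n_ex <- runif_int(1, 2, 6)
    cuts <- sort(sample(seq(200, len[i] - 200, by = 100), 2 * n_ex - 2))
    bounds <- c(0, cuts, len[i])
    s <- bounds[seq(1, length(bounds) - 1, by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    g0 <- start[i]
    tibble(start = g0 + s, end = g0 + e)
  })
  tibble(gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
         chrom = chrom, start = start, end = start + len, strand = strand,
         tss = ifelse(strand == "+", start, start + len - 1L),
         exons = exons)
}

simulate_enhancers <- function(cfg, chroms) {
  len <- runif_int(cfg$n_enhancers, 200, 2000)
  tibble(enhancer_id = sprintf("E%04d", seq_len(cfg$n_enhancers)),
         chrom = sample(chroms, cfg$n_enhancers, replace = TRUE),
         start = runif_int(cfg$n_enhancers, 0, cfg$chrom_length - 2100),
         end = NA_integer_) |>
    dplyr::mutate(end = .data$start + len)
}

# Peaks covering an element (>= 50% overlap guaranteed) with a score drawn
# from the signal or background regime.
peak_over <- function(iv, assay, score) {
  tibble(chrom = iv$chrom,
         start = pmax(0, iv$start - runif_int(nrow(iv), 0, 100)),
         end = iv$end + runif_int(nrow(iv), 0, 100),
         score = score, assay = assay)
}

#' Generate a synthetic fixture bundle
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_bundle`: `enhancers`, `genes`,
#'   `accessibility_peaks`, per-cell-type `cells` (each with `peaks`,
#'   `eqtls`, `curated_links`, `truth`), and `config`.
#' @export
simulate_regulatory_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  chroms <- sprintf("chrS%d", seq_len(config$n_chromosomes))
  genes <- simulate_genes(config, chroms)
  enhancers <- simulate_enhancers(config, chroms)

  inacc_e <- sample(enhancers$enhancer_id,
                    round(config$inaccessible_fraction * nrow(enhancers)))
  inacc_g <- sample(genes$gene_id,
                    round(config$inaccessible_fraction * nrow(genes) / 2))
  acc_e <- enhancers[!enhancers$enhancer_id %in% inacc_e, ]
  acc_g <- genes[!genes$gene_id %in% inacc_g, ]
  accessibility_peaks <- dplyr::bind_rows(
    peak_over(acc_e, "DNase", round(runif(nrow(acc_e), 1, 10), 2)),
    peak_over(acc_g[c("chrom", "start", "end")] |>
                dplyr::mutate(start = .data$start + 10,
                              end = pmin(.data$end - 10, .data$start + 2000)),
              "DNase", round(runif(nrow(acc_g), 1, 10), 2))
  )

  cis <- enumerate_cis_pairs(acc_e, acc_g, window = config$window)
  eligible <- cis |>
    dplyr::mutate(mid = (.data$enh_start + .data$enh_end) / 2) |>
    dplyr::filter(abs(.data$mid - .data$tss) <= config$window - 1e4)
  if (nrow(eligible) < config$n_active_links) {
    abort(sprintf("only %d feasible cis pairs for %d requested active links",
                  nrow(eligible), config$n_active_links))
  }

  make_cell <- function(cell) {
    # Prefer one active link per distinct gene so the gene-matched negative
    # draw (n per positive-set gene) reaches its nominal depth; spill over to
    # repeated genes only when there are fewer accessible genes than links.
    shuffled <- eligible[sample.int(nrow(eligible)), ]
    first <- shuffled[!duplicated(shuffled$gene_id), ]
    active <- head(first, config$n_active_links)
    if (nrow(active) < config$n_active_links) {
      rest <- shuffled[!paste(shuffled$enhancer_id, shuffled$gene_id) %in%
                         paste(active$enhancer_id, active$gene_id), ]
      active <- dplyr::bind_rows(
        active, head(rest, config$n_active_links - nrow(active)))
    }
    active_e <- enhancers[enhancers$enhancer_id %in% active$enhancer_id, ]
    active_g <- genes[genes$gene_id %in% unique(active$gene_id), ]
    prom <- promoter_region(active_g)
    sig_score <- function(n) round(runif(n, 8, 20), 2)
    bg_score <- function(n) round(runif(n, 0.5, 4), 2)
    plant <- function(iv, assay, p) {
      keep <- runif(nrow(iv)) < p
      peak_over(iv[keep, ], assay, sig_score(sum(keep)))
    }
    peaks <- dplyr::bind_rows(
      plant(active_e, "H3K27ac", config$signal_strength),
      plant(active_e, "H3K4me1", config$signal_strength),
      plant(active_e, "P300", config$signal_strength),
      plant(prom, "H3K4me3", config$signal_strength),
      plant(prom, "H3K27ac", config$signal_strength)
    )
    # Background marks on arbitrary elements (including inaccessible ones).
    bg <- function(iv, assay) {
      keep <- runif(nrow(iv)) < config$background_rate
      peak_over(iv[keep, ], assay, bg_score(sum(keep)))
    }
    all_prom <- promoter_region(genes)
    peaks <- dplyr::bind_rows(peaks,
      bg(enhancers, "H3K27ac"), bg(enhancers, "H3K4me1"), bg(enhancers, "P300"),
      bg(all_prom, "H3K4me3"), bg(all_prom, "H3K27ac"))

    # Planted eQTLs inside the active enhancer pointing to the linked gene.
    eq_sig <- purrr::pmap(active, function(enhancer_id, gene_id, chrom,
                                           enh_start, enh_end, ...) {
      if (runif(1) >= config$signal_strength) return(NULL)
      k <- runif_int(1, 1, 3)
      tibble(chrom = chrom,
             position = runif_int(k, enh_start, enh_end - 1),
             gene_id = gene_id,
             p_value = 10^runif(k, -8, -3),
             slope = rnorm(k, 0, 0.5))
    })
    # Background eQTLs: spurious weak associations to a random cis gene.
    bg_idx <- which(runif(nrow(enhancers)) < config$background_rate)
    eq_bg <- purrr::map(bg_idx, function(i) {
      g <- cis$gene_id[cis$enhancer_id == enhancers$enhancer_id[i]]
      g_all <- genes$gene_id[genes$chrom == enhancers$chrom[i]]
      tgt <- if (length(g)) sample(g, 1) else if (length(g_all)) sample(g_all, 1) else NA
      if (is.na(tgt)) return(NULL)
      tibble(chrom = enhancers$chrom[i],
             position = runif_int(1, enhancers$start[i], enhancers$end[i] - 1),
             gene_id = tgt,
             p_value = runif(1, 0.05, 1),
             slope = rnorm(1, 0, 0.5))
    })
    eqtls <- dplyr::bind_rows(purrr::compact(c(eq_sig, eq_bg)))

    # Curated links: jittered coordinates (<= 30% shift, so mapping at 33%
    # either-region overlap recovers the catalog enhancer).
    jitter <- function(s, e) {
      shift <- round(runif(length(s), -0.3, 0.3) * (e - s))
      tibble(start = pmax(0, s + shift), end = e + shift)
    }
    jit <- jitter(active$enh_start, active$enh_end)
    curated <- tibble(chrom = active$chrom, start = jit$start, end = jit$end,
                      gene_id = active$gene_id,
                      criterion = runif_int(nrow(active), 1, 5),
                      cell_type = cell)
    truth <- tibble(enhancer_id = active$enhancer_id,
                    gene_id = active$gene_id, cell_type = cell)
    list(peaks = peaks, eqtls = eqtls, curated_links = curated, truth = truth)
  }

  cells <- setNames(
    lapply(sprintf("cell_%d", seq_len(config$n_cell_types)), make_cell),
    sprintf("cell_%d", seq_len(config$n_cell_types)))
  structure(list(enhancers = enhancers, genes = genes,
                 accessibility_peaks = accessibility_peaks,
                 inaccessible_enhancers = inacc_e,
                 inaccessible_genes = inacc_g,
                 cells = cells, config = config),
            class = "synthetic_bundle")
}

#' Write a fixture bundle to disk in the pipeline's file dialects
#'
#' Emits `enhancers.bed`, `genes.bed12`, `accessibility.bed`, and per cell
#' type `<cell>_<assay>.bed`, `<cell>_eqtl.tsv`, `<cell>_curated.tsv`,
#' `<cell>_truth.tsv`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_enhancer_bed(bundle$enhancers, file.path(dir, "enhancers.bed"))
  write_gene_bed12(bundle$genes, file.path(dir, "genes.bed12"))
  write_peak_bed(bundle$accessibility_peaks, file.path(dir, "accessibility.bed"))
  for (cell in names(bundle$cells)) {
    cc <- bundle$cells[[cell]]
    for (assay in unique(cc$peaks$assay)) {
      write_peak_bed(cc$peaks[cc$peaks$assay == assay, ],
                     file.path(dir, sprintf("%s_%s.bed", cell, assay)))
    }
    write_table_tsv(cc$eqtls, file.path(dir, sprintf("%s_eqtl.tsv", cell)))
    write_table_tsv(cc$curated_links, file.path(dir, sprintf("%s_curated.tsv", cell)))
    write_table_tsv(cc$truth, file.path(dir, sprintf("%s_truth.tsv", cell)))
  }
  invisible(dir)
}

#' Run the dataset-assembly pipeline for one synthetic cell type
#'
#' Convenience wrapper chaining the full path from a fixture bundle to a
#' labeled dataset: cis-pair enumeration, feature construction, curated
#' positive mapping, inaccessibility calls, negative-universe construction,
#' gene-matched negative sampling, and assembly.
#'
#' @param bundle A `synthetic_bundle`.
#' @param cell Cell-type name within the bundle.
#' @param n_per_gene Negatives sampled per positive-set gene.
#' @param seed Sampling seed.
#' @param config A [feature_config()].
#' @param p300 Keep the P300 feature (set `FALSE` to emulate a cell type
#'   without P300 data).
#' @return An `eg_dataset`.
#' @export
build_cell_dataset <- function(bundle, cell, n_per_gene = 30, seed = 1L,
                               config = feature_config(), p300 = TRUE) {
  cc <- bundle$cells[[cell]]
  if (is.null(cc)) abort(sprintf("no cell type '%s' in bundle", cell))
  peaks <- cc$peaks
  if (!p300) peaks <- peaks[peaks$assay != "P300", ]
  pairs <- enumerate_cis_pairs(bundle$enhancers, bundle$genes,
                               window = bundle$config$window)
  feats <- build_feature_matrix(pairs, bundle$enhancers, bundle$genes,
                                peaks, cc$eqtls, config)
  pos <- load_curated_positives(cc$curated_links, bundle$enhancers)
  # A jittered curated interval can also map onto an overlapping neighbor
  # enhancer; keep only mapped pairs inside the cis universe.
  pos <- pos[paste(pos$enhancer_id, pos$gene_id) %in%
               paste(feats$enhancer_id, feats$gene_id), ]
  inacc_e <- find_inaccessible(bundle$enhancers, bundle$accessibility_peaks,
                               pad = 0)
  inacc_g <- find_inaccessible(bundle$genes, bundle$accessibility_peaks,
                               pad = 2000)
  universe <- build_negative_universe(pairs, inacc_e, inacc_g)
  neg <- suppressWarnings(
    sample_matched_negatives(universe, pos, n_per_gene = n_per_gene,
                             seed = seed))
  dsid <- if (p300) cell else paste0(cell, "_noP300")
  assemble_dataset(pos, neg, feats, cell_type = cell, id = dsid)
}

#' Build feature tables for every cell type in a bundle
#'
#' @inheritParams build_cell_dataset
#' @return Named list of feature tibbles, one per cell type.
#' @export
bundle_cell_features <- function(bundle, config = feature_config()) {
  pairs <- enumerate_cis_pairs(bundle$enhancers, bundle$genes,
                               window = bundle$config$window)
  purrr::map(bundle$cells, function(cc) {
    build_feature_matrix(pairs, bundle$enhancers, bundle$genes,
                         cc$peaks, cc$eqtls, config)
  })
}

#' Split a bundle into disjoint train/test datasets
#'
#' `"by-cell"` builds one dataset per emulated cell type (keys differ by the
#' cell-type tag, so train and test never share an observation);
#' `"by-region"` splits the first cell type's dataset by chromosome into two
#' region-disjoint datasets.
#'
#' @param bundle A `synthetic_bundle`.
#' @param scheme `"by-cell"` or `"by-region"`.
#' @param n_per_gene,seed Passed to [build_cell_dataset()].
#' @return Named list of two `eg_dataset` objects (`train`, `test`).
#' @export
train_test_split <- function(bundle, scheme = c("by-cell", "by-region"),
                             n_per_gene = 30, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "by-cell") {
    cells <- names(bundle$cells)
    if (length(cells) < 2) abort("by-cell split needs at least two cell types")
    return(list(train = build_cell_dataset(bundle, cells[[1]],
                                           n_per_gene = n_per_gene, seed = seed),
                test = build_cell_dataset(bundle, cells[[2]],
                                          n_per_gene = n_per_gene, seed = seed + 1L)))
  }
  ds <- build_cell_dataset(bundle, names(bundle$cells)[[1]],
                           n_per_gene = n_per_gene, seed = seed)
  chroms <- sort(unique(bundle$enhancers$chrom))
  half <- chroms[seq_len(ceiling(length(chroms) / 2))]
  enh_chrom <- setNames(bundle$enhancers$chrom, bundle$enhancers$enhancer_id)
  in_half <- enh_chrom[ds$pairs$enhancer_id] %in% half
  subset_ds <- function(keep, tag) {
    pr <- ds$pairs[keep, ]
    assemble_dataset(pr[pr$label == "positive", ], pr[pr$label == "negative", ],
                     ds$features_raw[keep, c("enhancer_id", "gene_id",
                                             setdiff(names(ds$features_raw),
                                                     c("enhancer_id", "gene_id",
                                                       "cell_type", "label")))],
                     cell_type = ds$cell_types[[1]],
                     id = paste0(ds$id, "_", tag))
  }
  list(train = subset_ds(in_half, "regionA"),
       test = subset_ds(!in_half, "regionB"))
}
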