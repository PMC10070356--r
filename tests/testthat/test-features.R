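test_that("combined_eqtl_z matches the standard-normal quantile oracle", {
  expect_equal(combined_eqtl_z(numeric()), 0)
  expect_equal(combined_eqtl_z(0.5), 0)
  # oracle: one-sided z for p = 0.05 is qnorm(0.95)
  expect_equal(combined_eqtl_z(0.05), qnorm(0.95), tolerance = 1e-10)
  expect_equal(round(combined_eqtl_z(0.05), 4), 1.6449)
  expect_equal(combined_eqtl_z(c(0.05, 0.05)), 2 * qnorm(0.95) / sqrt(2),
               tolerance = 1e-10)
  expect_equal(round(combined_eqtl_z(c(0.05, 0.05)), 4), 2.3262)
  expect_error(combined_eqtl_z(c(0.5, 0)), "p values")
  expect_error(combined_eqtl_z(1.2), "p values")
})

test_that("combined_eqtl_z is monotone in each p and dilutes by sqrt(k/(k+1))", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:5, 1))
    z <- combined_eqtl_z(p)
    p2 <- p; j <- sample(length(p), 1); p2[j] <- p2[j] * 0.5
    expect_gt(combined_eqtl_z(p2), z)
    expect_equal(combined_eqtl_z(c(p, 0.5)),
                 z * sqrt(length(p) / (length(p) + 1)), tolerance = 1e-12)
  }
  # fisher variant agrees in sign and direction
  expect_gt(combined_eqtl_z(c(1e-4, 1e-5), method = "fisher"), 3)
})

test_that("avg_abs_coeff averages absolute slopes with empty -> 0", {
  expect_equal(avg_abs_coeff(c(0.2, -0.4)), 0.3)
  expect_equal(avg_abs_coeff(-1.5), 1.5)
  expect_equal(avg_abs_coeff(numeric()), 0)
})

test_that("peak_feature applies the 50% either-region rule, max-score aggregation", {
  region <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L)
  covering <- tibble::tibble(chrom = "chr1", start = 900L, end = 2100L,
                             score = 7.2, assay = "H3K27ac")
  expect_equal(peak_feature(region, covering, "binary"), 1)
  expect_equal(peak_feature(region, covering, "continuous"), 7.2)
  # tiny peak fully inside the region passes via its own fraction
  tiny <- tibble::tibble(chrom = "chr1", start = 1400L, end = 1500L,
                         score = 2, assay = "H3K27ac")
  expect_equal(peak_feature(region, tiny, "binary"), 1)
  # 30% mutual overlap fails both fractions
  off <- tibble::tibble(chrom = "chr1", start = 1700L, end = 2700L,
                        score = 9, assay = "H3K27ac")
  expect_equal(peak_feature(region, off, "continuous"), 0)
  two <- dplyr::bind_rows(covering, dplyr::mutate(covering, score = 9.5))
  expect_equal(peak_feature(region, two, "continuous"), 9.5)
  expect_equal(peak_feature(region, NULL, "continuous"), 0)
})

test_that("binary and continuous peak features agree when scores are positive", {
  set.seed(9)
  regions <- rand_intervals(80)
  peaks <- rand_intervals(60)
  peaks$score <- runif(60, 0.5, 10)
  peaks$assay <- "H3K4me1"
  b <- peak_feature(regions, peaks, "binary")
  cont <- peak_feature(regions, peaks, "continuous")
  expect_equal(b == 1, cont > 0)
})

test_that("promoter_region is strand-aware and clipped at the chromosome start", {
  g <- tibble::tibble(gene_id = c("P", "M", "C"), chrom = "chr1",
                      strand = c("+", "-", "+"),
                      tss = c(10000L, 10000L, 500L))
  pr <- promoter_region(g)
  expect_equal(pr$start, c(9000L, 9000L, 0L))
  expect_equal(pr$end, c(11000L, 11000L, 1500L))
  # asymmetric extents mirror on the minus strand
  pr2 <- promoter_region(g[2, ], up = 2000, down = 500)
  expect_equal(c(pr2$start, pr2$end), c(9500L, 12000L))
})

test_that("interaction columns equal exact products of their factors", {
  set.seed(31)
  n <- 50
  main <- tibble::tibble(
    h3k27ac_enh = rbinom(n, 1, 0.5),
    h3k4me1_enh = runif(n, 0, 20),
    h3k4me3_prom = rbinom(n, 1, 0.5),
    p300_enh = runif(n, 0, 20),
    eqtl_z = rnorm(n, 2, 3),
    nearest_gene = rbinom(n, 1, 0.5),
    intronic = rbinom(n, 1, 0.5),
    eqtl_avg_abs_coef = runif(n),
    h3k27ac_prom = runif(n, 0, 20))
  fx <- compute_interactions(main)
  expect_identical(fx$h3k27ac_enh_x_h3k27ac_prom,
                   main$h3k27ac_enh * main$h3k27ac_prom)
  expect_identical(fx$h3k27ac_enh_x_h3k4me3_prom,
                   main$h3k27ac_enh * main$h3k4me3_prom)
  expect_identical(fx$h3k27ac_enh_x_h3k4me1_enh_x_h3k27ac_prom,
                   main$h3k27ac_enh * main$h3k4me1_enh * main$h3k27ac_prom)
  expect_identical(fx$h3k27ac_enh_x_h3k4me1_enh_x_h3k4me3_prom,
                   main$h3k27ac_enh * main$h3k4me1_enh * main$h3k4me3_prom)
  expect_identical(fx$eqtl_z_x_eqtl_avg_abs_coef,
                   main$eqtl_z * main$eqtl_avg_abs_coef)
  expect_identical(fx$h3k27ac_enh_x_h3k4me1_enh,
                   main$h3k27ac_enh * main$h3k4me1_enh)
  expect_error(compute_interactions(main[, -2]), "missing column")
})

test_that("build_feature_matrix attributes eQTLs by in-enhancer position and target gene", {
  enh <- tibble::tibble(enhancer_id = c("E1", "E2"), chrom = "chr1",
                        start = c(1000L, 8000L), end = c(2000L, 9000L))
  genes <- tibble::tibble(gene_id = c("G1", "G2"), chrom = "chr1",
                          start = c(3000L, 20000L), end = c(4000L, 30000L),
                          strand = "+", tss = c(3000L, 20000L),
                          exons = list(tibble::tibble(start = 3000L, end = 4000L),
                                       tibble::tibble(start = 20000L, end = 30000L)))
  pairs <- enumerate_cis_pairs(enh, genes)
  eqtls <- tibble::tibble(
    chrom = "chr1",
    position = c(1500L, 1501L, 1600L, 8500L, 2500L),
    gene_id = c("G1", "G1", "G2", "G1", "G1"),
    p_value = c(0.05, 0.05, 1e-4, 0.01, 1e-9),
    slope = c(0.2, -0.4, 1, 0.5, 2))
  peaks <- tibble::tibble(chrom = "chr1", start = 900L, end = 2100L,
                          score = 5, assay = "H3K27ac")
  fx <- build_feature_matrix(pairs, enh, genes, peaks, eqtls)
  row <- function(e, g) fx[fx$enhancer_id == e & fx$gene_id == g, ]
  # E1-G1: the two in-enhancer p = 0.05 eQTLs (position 2500 is outside E1)
  expect_equal(row("E1", "G1")$eqtl_z, combined_eqtl_z(c(0.05, 0.05)))
  expect_equal(row("E1", "G1")$eqtl_avg_abs_coef, 0.3)
  # E1-G2 picks up only the G2-targeted variant
  expect_equal(row("E1", "G2")$eqtl_z, combined_eqtl_z(1e-4))
  # E2-G1: variant inside E2
  expect_equal(row("E2", "G1")$eqtl_avg_abs_coef, 0.5)
  # no-evidence pair is all zeros on eQTL features
  expect_equal(row("E2", "G2")$eqtl_z, 0)
  expect_equal(row("E2", "G2")$eqtl_avg_abs_coef, 0)
  # P300 absent -> structurally missing, not zero
  expect_false(attr(fx, "p300_available"))
  expect_true(all(is.na(fx$p300_enh)))
  # interaction consistency on the computed table
  expect_equal(fx$eqtl_z_x_eqtl_avg_abs_coef, fx$eqtl_z * fx$eqtl_avg_abs_coef)
})

test_that("build_feature_matrix rejects irreconcilable chromosome names", {
  enh <- tiny_enhancers()
  genes <- tiny_genes()
  pairs <- enumerate_cis_pairs(enh, genes)
  bad_peaks <- tibble::tibble(chrom = "1", start = 0L, end = 100L,
                              score = 1, assay = "H3K27ac")
  expect_error(
    suppressWarnings(build_feature_matrix(pairs, enh, genes, bad_peaks)),
    "irreconcilable")
})

test_that("standardization fits on training rows and replays on new data", {
  df <- tibble::tibble(h3k4me1_enh = c(1, 2, 3), eqtl_z = c(0, 0, 0),
                       nearest_gene = c(0, 1, 1))
  expect_warning(params <- standardize_fit(df), "constant")
  out <- standardize_apply(df, params)
  expect_equal(out$h3k4me1_enh, c(-1, 0, 1))     # sample sd
  expect_equal(out$eqtl_z, c(0, 0, 0))           # constant passthrough
  expect_equal(out$nearest_gene, df$nearest_gene) # binary untouched
  # applying train params elsewhere does not recentre the new data
  new <- tibble::tibble(h3k4me1_enh = c(10, 20), eqtl_z = 1, nearest_gene = 0)
  out2 <- standardize_apply(new, params)
  expect_equal(out2$h3k4me1_enh, (c(10, 20) - 2) / 1)
  expect_gt(abs(mean(out2$h3k4me1_enh)), 1)
  # idempotence of fit-then-apply on the fitting set
  refit <- standardize_fit(out, cols = "h3k4me1_enh")
  expect_equal(standardize_apply(out, refit)$h3k4me1_enh, out$h3k4me1_enh,
               tolerance = 1e-12)
})
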