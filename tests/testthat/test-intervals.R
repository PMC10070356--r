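test_that("overlap_fraction handles symmetric, identical, adjacent and off-chromosome pairs", {
  iv <- function(s, e, chrom = "chr1") tibble::tibble(chrom = chrom, start = s, end = e)
  expect_equal(overlap_fraction(iv(10, 20), iv(15, 25)),
               tibble::tibble(frac_a = 0.5, frac_b = 0.5))
  expect_equal(overlap_fraction(iv(10, 20), iv(10, 20)),
               tibble::tibble(frac_a = 1, frac_b = 1))
  # half-open adjacency is disjoint
  expect_equal(overlap_fraction(iv(0, 10), iv(10, 20)),
               tibble::tibble(frac_a = 0, frac_b = 0))
  expect_equal(overlap_fraction(iv(0, 10), iv(0, 10, "chr2")),
               tibble::tibble(frac_a = 0, frac_b = 0))
  expect_error(overlap_fraction(iv(5, 5), iv(0, 10)), "length")
})

test_that("overlap_fraction is exchange-symmetric in intersection length", {
  set.seed(11)
  a <- rand_intervals(200)
  b <- rand_intervals(200)
  fr <- overlap_fraction(a, b)
  expect_equal(fr$frac_a * (a$end - a$start), fr$frac_b * (b$end - b$start))
  expect_true(all(fr$frac_a >= 0 & fr$frac_a <= 1))
  expect_true(all(fr$frac_b >= 0 & fr$frac_b <= 1))
})

test_that("meets_overlap_threshold implements either-region semantics", {
  iv <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e)
  # intersection 20 of [0,100) and [80,400): 0.20 / 0.0625 -> fails 33%
  expect_false(meets_overlap_threshold(iv(0, 100), iv(80, 400), 0.33))
  # intersection 40 of [0,100) and [60,1000): 0.40 of a -> passes
  expect_true(meets_overlap_threshold(iv(0, 100), iv(60, 1000), 0.33))
  expect_true(meets_overlap_threshold(iv(42, 77), iv(42, 77), 1))
  # reciprocal demands both fractions
  expect_false(meets_overlap_threshold(iv(0, 100), iv(60, 1000), 0.33,
                                       mode = "reciprocal"))
  expect_true(meets_overlap_threshold(iv(60, 1000), iv(0, 100), 0.33,
                                      mode = "of-first") ==
                (40 / 940 >= 0.33))
  expect_error(meets_overlap_threshold(iv(0, 10), iv(0, 10), 0), "threshold")
})

test_that("enumerate_cis_pairs applies the 1 Mb any-intersection window", {
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", start = 5e6,
                          end = 5.01e6, strand = "+", tss = 5e6)
  enh <- tibble::tibble(
    enhancer_id = c("in", "out", "edge"),
    chrom = "chr1",
    start = c(5900000, 6100000, 5999900),
    end = c(5900500, 6100500, 6000100))
  got <- enumerate_cis_pairs(enh, genes)
  expect_setequal(got$enhancer_id, c("in", "edge"))
  expect_equal(nrow(enumerate_cis_pairs(enh[0, ], genes)), 0)
})

test_that("enumerate_cis_pairs agrees with the brute-force all-pairs oracle", {
  set.seed(5)
  for (rep in 1:3) {
    enh <- rand_intervals(60, max_pos = 4e6)
    enh$enhancer_id <- sprintf("E%03d", seq_len(nrow(enh)))
    genes <- rand_intervals(40, max_pos = 4e6)
    genes$gene_id <- sprintf("G%03d", seq_len(nrow(genes)))
    genes$strand <- "+"
    genes$tss <- genes$start
    got <- enumerate_cis_pairs(enh, genes, window = 5e5)
    want <- brute_cis_pairs(enh, genes, window = 5e5)
    expect_equal(dplyr::arrange(got[c("enhancer_id", "gene_id")],
                                gene_id, enhancer_id),
                 want)
  }
})

test_that("nearest_gene uses midpoint-to-TSS distance with id tie-break", {
  enh <- tibble::tibble(enhancer_id = "E1", chrom = "chr1",
                        start = 900L, end = 1100L)  # mid = 1000
  genes <- tibble::tibble(gene_id = c("G2", "G1"), chrom = "chr1",
                          start = c(900L, 1100L), end = c(2000L, 3000L),
                          strand = "+", tss = c(900L, 1100L))
  # equidistant (100 bp): lexicographically smaller id wins
  expect_equal(nearest_gene(enh, genes)$nearest_gene_id, "G1")
  genes2 <- genes; genes2$tss <- c(900L, 5000L)
  expect_equal(nearest_gene(enh, genes2)$nearest_gene_id, "G2")
  expect_equal(nearest_gene(enh, genes2[2, ])$nearest_gene_id, "G1")
  expect_error(nearest_gene(enh, genes[genes$chrom == "chrX", ]), "no gene")
})

test_that("nearest_gene is invariant under gene-list permutation", {
  set.seed(21)
  enh <- rand_intervals(50)
  enh$enhancer_id <- sprintf("E%02d", 1:50)
  genes <- rand_intervals(30)
  genes$gene_id <- sprintf("G%02d", 1:30)
  genes$tss <- genes$start
  base <- nearest_gene(enh, genes)
  perm <- nearest_gene(enh, genes[sample.int(30), ])
  expect_equal(base, perm)
})

test_that("is_intronic requires body containment and exon avoidance", {
  genes <- tiny_genes()
  enh <- tibble::tibble(
    enhancer_id = c("intronic", "exonic", "upstream", "in_exonless"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(2500L, 1500L, 200L, 1000L),
    end = c(3500L, 2500L, 400L, 2000L))
  pairs <- tibble::tibble(enhancer_id = enh$enhancer_id,
                          gene_id = c("G1", "G1", "G1", "G3"))
  expect_warning(res <- is_intronic(pairs, enh, genes), "no exon annotation")
  expect_equal(res, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("map_external_enhancers applies the 33% either-region rule", {
  catalog <- tibble::tibble(enhancer_id = c("A", "B"), chrom = "chr1",
                            start = c(1000L, 2000L), end = c(1500L, 2600L))
  exact <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1500L)
  got <- map_external_enhancers(exact, catalog)
  expect_equal(got$mapped$enhancer_id, "A")
  expect_equal(nrow(got$unmapped), 0)
  # one external spanning both catalog enhancers fully -> both map
  wide <- tibble::tibble(chrom = "chr1", start = 900L, end = 2700L)
  expect_setequal(map_external_enhancers(wide, catalog)$mapped$enhancer_id,
                  c("A", "B"))
  # 10% overlap of both -> unmapped
  weak <- tibble::tibble(chrom = "chr1", start = 1450L, end = 1950L)
  got <- map_external_enhancers(weak, catalog)
  expect_equal(nrow(got$mapped), 0)
  expect_equal(nrow(got$unmapped), 1)
})

test_that("BED and BED12 round-trips preserve coordinates and exons", {
  dir <- withr::local_tempdir()
  enh <- tiny_enhancers()
  write_enhancer_bed(enh, file.path(dir, "e.bed"))
  expect_equal(read_enhancer_bed(file.path(dir, "e.bed")), enh)
  genes <- tiny_genes()
  write_gene_bed12(genes, file.path(dir, "g.bed12"))
  back <- read_gene_bed12(file.path(dir, "g.bed12"))
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$tss, as.integer(genes$tss))
  expect_equal(back$exons[[1]],
               dplyr::mutate(genes$exons[[1]], dplyr::across(dplyr::everything(),
                                                             as.integer)))
  # exonless gene serializes as a single whole-body block
  expect_equal(back$exons[[3]], tibble::tibble(start = 100L, end = 5000L))
  pk <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                       score = 3.5, assay = "H3K27ac")
  write_peak_bed(pk, file.path(dir, "p.bed"))
  expect_equal(read_peak_bed(file.path(dir, "p.bed"), "H3K27ac"), pk)
})
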