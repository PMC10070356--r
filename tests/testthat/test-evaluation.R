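test_that("pr_curve and auprc reproduce hand-enumerated cases", {
  # scores 0.9, 0.8, 0.7, 0.6 over labels 1,0,1,0:
  # thresholds give (R, P) = (0.5, 1), (0.5, 0.5), (1, 2/3), (1, 0.5)
  # AP = 0.5 * 1 + 0.5 * 2/3 = 5/6
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 5 / 6)
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  # all-equal scores collapse to one threshold at prevalence precision
  expect_equal(auprc(rep(0.3, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  pc <- pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(pc$recall, c(0.5, 0.5, 1, 1))
  expect_equal(pc$precision, c(1, 0.5, 2 / 3, 0.5))
  expect_true(all(diff(pc$recall) >= 0))
  expect_error(auprc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("roc_auc implements the tie-aware Mann-Whitney formulation", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 0, 0, 0, 0)), 0.5)
})

test_that("metrics match brute-force oracles on random instances", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    y <- c(1, 0, rbinom(n - 2, 1, runif(1, 0.1, 0.9)))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(auprc(s, y), brute_auprc(s, y))
    expect_equal(roc_auc(s, y), brute_auc(s, y))
  }
})

test_that("roc_auc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rbinom(150, 1, 0.3)
  y[1:2] <- c(0, 1)
  s <- round(runif(150), 2)
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = y, predictor = s, direction = "<",
              levels = c(0, 1), quiet = TRUE))))
  expect_equal(roc_auc(s, y), ref)
})

test_that("random scores land near the analytic baselines", {
  set.seed(123)
  ap <- replicate(200, {
    y <- c(1, 0, rbinom(58, 1, 0.2))
    auprc(runif(60), y)
  })
  y_prev <- mean(c(1, 0, rep(0.2, 58)))
  expect_lt(abs(mean(ap) - y_prev), 0.05)
  au <- replicate(100, {
    y <- c(1, 0, rbinom(58, 1, 0.2))
    roc_auc(runif(60), y)
  })
  expect_lt(abs(mean(au) - 0.5), 0.05)
})

test_that("random_baseline_auprc reproduces prevalence including printed cases", {
  expect_equal(random_baseline_auprc(c(rep(1, 23), rep(0, 360))), 23 / 383)
  expect_equal(round(random_baseline_auprc(c(rep(1, 6), rep(0, 1303))), 3), 0.005)
  expect_equal(random_baseline_auprc(rep(1, 5)), 1)
  expect_error(random_baseline_auprc(numeric()), "non-empty")
})

test_that("cross_cell_evaluate excludes any test set sharing training observations", {
  b <- cached_small_bundle()
  d1 <- suppressWarnings(build_cell_dataset(b, "cell_1", seed = 1))
  d2 <- suppressWarnings(build_cell_dataset(b, "cell_2", seed = 2))
  m1 <- train_model(d1, "knn")
  m2 <- train_model(d2, "ridge")
  w <- capture_warnings(
    rep <- cross_cell_evaluate(list(knn_c1 = m1, ridge_c2 = m2),
                               list(cell_1 = d1, cell_2 = d2)))
  expect_match(w, "shared training", all = TRUE)
  expect_length(w, 2)  # one skipped self-pairing per model
  # each model is evaluated only on the other cell type
  expect_equal(nrow(rep), 2)
  expect_equal(rep$test_dataset[rep$model_id == "knn_c1"], "cell_2")
  expect_equal(rep$test_dataset[rep$model_id == "ridge_c2"], "cell_1")
  expect_true(all(rep$auprc >= 0 & rep$auprc <= 1))
})

test_that("select_final_model applies the min+mean rule with the 0.10 disqualifier", {
  rep <- tibble::tibble(
    model_id = rep(c("X", "Y"), each = 2),
    algorithm = "knn",
    train_dataset = "A",
    test_dataset = rep(c("B", "C"), 2),
    auprc = c(0.5, 0.6, 0.05, 0.9),
    auc = c(0.8, 0.8, 0.99, 0.99))
  # Y has the higher mean but min 0.05 < 0.10 -> disqualified; X wins
  sel <- select_final_model(rep)
  expect_equal(sel$winner, "X")
  expect_true(tidy(sel)$disqualified[tidy(sel)$model_id == "Y"])
  # score arithmetic: Z (0.15 + 0.5 -> 0.975) beats X2 (0.2 + 0.2 -> 0.6)
  rep2 <- tibble::tibble(
    model_id = rep(c("X2", "Z"), each = 2),
    algorithm = "svm_rbf", train_dataset = "A",
    test_dataset = rep(c("B", "C"), 2),
    auprc = c(0.2, 0.2, 0.15, 0.5),
    auc = 0.9)
  expect_equal(select_final_model(rep2)$winner, "Z")
  # single qualified model selects itself
  expect_equal(select_final_model(rep[1:2, ])$winner, "X")
  # across training sets the candidate with the higher mean AUC wins
  rep3 <- dplyr::bind_rows(rep2,
    tibble::tibble(model_id = "W", algorithm = "knn", train_dataset = "D",
                   test_dataset = c("B", "C"), auprc = c(0.3, 0.3),
                   auc = c(0.95, 0.95)))
  expect_equal(select_final_model(rep3)$winner, "W")
  # all disqualified -> error
  expect_error(select_final_model(dplyr::mutate(rep, auprc = 0.01)),
               "disqualified")
})

test_that("select_final_model is invariant under report-row permutation", {
  set.seed(31)
  rep <- tibble::tibble(
    model_id = rep(sprintf("M%d", 1:6), each = 3),
    algorithm = "knn",
    train_dataset = rep(c("A", "B"), each = 9),
    test_dataset = rep(c("T1", "T2", "T3"), 6),
    auprc = round(runif(18, 0.05, 0.9), 2),
    auc = round(runif(18, 0.5, 1), 2))
  base <- select_final_model(rep)$winner
  for (i in 1:5) {
    expect_equal(select_final_model(rep[sample.int(18), ])$winner, base)
  }
})

test_that("feature ablation flags a planted useless feature and protects signal", {
  set.seed(17)
  n_pos <- 25; n_neg <- 75; n <- n_pos + n_neg
  make <- function(seed) {
    set.seed(seed)
    tibble::tibble(
      enhancer_id = sprintf("E%03d", 1:n), gene_id = "G1",
      h3k4me1_enh = c(rnorm(n_pos, 3), rnorm(n_neg, 0)),
      eqtl_z = rnorm(n),                      # pure noise
      h3k27ac_prom = rnorm(n))                # pure noise
  }
  build <- function(seed, cell) {
    f <- make(seed)
    assemble_dataset(f[1:n_pos, 1:2], f[(n_pos + 1):n, 1:2], f,
                     cell_type = cell)
  }
  train <- build(101, "tr")
  tests <- list(t1 = build(102, "t1"), t2 = build(103, "t2"))
  abl <- ablate_features(train, "knn", tests,
                         features = c("h3k4me1_enh", "eqtl_z", "h3k27ac_prom"))
  # dropping the informative feature is never the kept move
  kept <- abl$history$dropped[abl$history$kept]
  expect_false("h3k4me1_enh" %in% kept)
  expect_true("h3k4me1_enh" %in% abl$final_features)
  expect_gte(abl$final_auprc, abl$baseline_auprc)
  # dropping the only signal collapses toward prevalence
  m_noise <- train_model(train, "knn", features = c("eqtl_z", "h3k27ac_prom"))
  ap_noise <- auprc(predict_scores(m_noise, tests$t1), tests$t1$pairs$label)
  m_sig <- train_model(train, "knn", features = "h3k4me1_enh")
  ap_sig <- auprc(predict_scores(m_sig, tests$t1), tests$t1$pairs$label)
  expect_gt(ap_sig, 3 * tests$t1$prevalence)
  expect_lt(ap_noise, ap_sig)
})

test_that("ks_two_sample matches enumerated ECDF differences", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)
  res <- ks_two_sample(rnorm(50), rnorm(50, 5))
  expect_lt(res$p_value, 1e-6)
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
})
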