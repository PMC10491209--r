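test_that("the linear model reproduces the pooled-variance t-test", {
  ctrl <- c(96, 104, 100, 98, 102)
  cond <- c(50, 54, 46, 52, 48)
  fit <- fit_linear(c(ctrl, cond), rep(0:1, each = 5))
  expect_equal(fit$estimate, -50)
  expect_equal(fit$p_value, ttest_pooled_p(ctrl, cond), tolerance = 1e-12)
  expect_equal(fit$statistic^2,
               (fit$estimate / fit$std_error)^2, tolerance = 1e-12)

  # property: agreement with the closed form on random unbalanced draws
  set.seed(42)
  for (i in 1:20) {
    n0 <- sample(3:12, 1); n1 <- sample(3:12, 1)
    y0 <- rnorm(n0, 100, 8); y1 <- rnorm(n1, 95, 8)
    f <- fit_linear(c(y0, y1), rep(0:1, c(n0, n1)))
    expect_equal(f$p_value, ttest_pooled_p(y0, y1), tolerance = 1e-10)
    expect_equal(f$estimate, mean(y1) - mean(y0), tolerance = 1e-10)
  }
})

test_that("degenerate linear fits are flagged instead of erroring", {
  same <- fit_linear(rep(100, 6), rep(0:1, each = 3))
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  halved <- fit_linear(c(128, 128, 64, 64), c(0, 0, 1, 1), logscale = TRUE)
  expect_equal(halved$estimate, -1)   # log2(64/128)
  expect_true(halved$degenerate)
  expect_true(is.na(halved$p_value))

  expect_error(fit_linear(rep(100, 4), rep(0, 4)), "single condition")
})

test_that("linear-model p-values are shift-invariant and estimates antisymmetric", {
  set.seed(7)
  y <- rnorm(20, 500, 30)
  cond <- rep(0:1, each = 10)
  a <- fit_linear(y, cond)
  b <- fit_linear(y + 1000, cond)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  flipped <- fit_linear(y, 1 - cond)
  expect_equal(flipped$estimate, -a$estimate, tolerance = 1e-12)
  expect_equal(flipped$p_value, a$p_value, tolerance = 1e-12)
})

test_that("the mixed model reduces to the linear model without library variance", {
  # every library identical -> singular fit -> flagged fallback, same estimate
  libs <- rep(c("c1", "c2", "c3", "t1", "t2", "t3"), each = 4)
  cond <- rep(0:1, each = 12)
  y <- c(rep(c(100, 104, 96, 100), 3), rep(c(80, 84, 76, 80), 3))
  lmm <- fit_lmm(y, cond, libs)
  lin <- fit_linear(y, cond)
  expect_equal(lmm$estimate, lin$estimate, tolerance = 1e-3)
  expect_true(lmm$fallback_flag)
})

test_that("the mixed model refuses unidentifiable designs and flags the fallback", {
  libs <- rep(c("c1", "t1"), each = 10)
  set.seed(8)
  y <- rnorm(20, 300, 20)
  fit <- fit_lmm(y, rep(0:1, each = 10), libs)
  expect_true(fit$fallback_flag)
  expect_equal(fit$model_used, "ttest")
})

test_that("the mixed model recovers a known library effect and condition effect", {
  sc <- simulation_scenario(n_genes = 1, reads_per_library = 200,
                            shortening_proportion = 0.5, seed = 99)
  sim <- simulate_scenario(sc)
  ind <- as.integer(grepl("^case", sim$table$library_id))
  fit <- fit_lmm(sim$table$length, ind, sim$table$library_id, logscale = TRUE)
  expect_equal(fit$model_used, "lmm")
  expect_equal(fit$estimate, -1, tolerance = 0.35)  # one gene, 6 libraries
  expect_gt(fit$random_effect_sd, 0)
  # antisymmetry holds for the mixed model too
  flipped <- fit_lmm(sim$table$length, 1 - ind, sim$table$library_id, logscale = TRUE)
  expect_equal(flipped$estimate, -fit$estimate, tolerance = 1e-6)
  expect_equal(flipped$p_value, fit$p_value, tolerance = 1e-6)
})

test_that("the Wilcoxon test matches exact enumeration and rejects covariates", {
  sep <- fit_wilcoxon(c(10, 11, 12, 1, 2, 3), rep(0:1, each = 3))
  expect_equal(sep$p_value, 0.1)   # 2 of the 20 rank assignments as extreme
  expect_equal(sep$estimate, -9)

  tied <- fit_wilcoxon(c(5, 5), c(0, 1))
  expect_equal(tied$p_value, 1)

  expect_error(fit_wilcoxon(1:4, c(0, 0, 1, 1), covariates = matrix(1:4)),
               "covariates")

  set.seed(13)
  for (i in 1:30) {
    n0 <- sample(2:6, 1); n1 <- sample(2:6, 1)
    vals <- sample(1000, n0 + n1)   # distinct -> no ties
    f <- fit_wilcoxon(vals, rep(0:1, c(n0, n1)))
    expect_equal(f$p_value, wilcox_enum_p(vals[1:n0], vals[-(1:n0)]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(1), 1)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(21)
  for (i in 1:10) {
    p <- runif(sample(c(2, 5, 50, 500), 1))^sample(1:3, 1)
    adj <- adjust_bh(p)
    expect_equal(adj, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("the pipeline filters, tests, adjusts and sorts per transcript", {
  set.seed(31)
  spec <- list()
  for (tx in sprintf("null_%02d", 1:6)) {
    spec[[tx]] <- list(ctrl_1 = rnorm(12, 500, 25), ctrl_2 = rnorm(12, 500, 25),
                       case_1 = rnorm(12, 500, 25), case_2 = rnorm(12, 500, 25))
  }
  spec$shortened <- list(ctrl_1 = rnorm(12, 500, 25), ctrl_2 = rnorm(12, 500, 25),
                         case_1 = rnorm(12, 250, 12), case_2 = rnorm(12, 250, 12))
  spec$sparse <- list(ctrl_1 = rnorm(3, 500, 25), case_1 = rnorm(12, 500, 25))
  tab <- table_from_spec(spec)
  d <- new_design(c("ctrl_1", "ctrl_2", "case_1", "case_2"),
                  rep(c("control", "shortened"), each = 2),
                  reference = "control")
  res <- run_differential_length(tab, d, model = "ttest", logscale = TRUE,
                                 min_reads_per_condition = 10)
  expect_false("sparse" %in% res$transcript_id)   # fails the read filter
  expect_equal(res$transcript_id[1], "shortened") # sorted by p-value
  expect_true(all(diff(res$p_value) >= 0))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  expect_true(res$sig_adj[1])
  expect_equal(res$estimate[1], -1, tolerance = 0.15)

  expect_error(
    run_differential_length(tab, d, model = "wilcoxon", covariates = "batch"),
    "batch")
  d$batch <- c(1, 2, 1, 2)
  expect_error(
    run_differential_length(tab, d, model = "wilcoxon", covariates = "batch"),
    "covariates")

  expect_warning(
    empty <- run_differential_length(tab, d, min_reads_per_condition = 1000),
    "no transcripts")
  expect_equal(nrow(empty), 0)

  # results TSV round-trips through the documented columns
  path <- withr::local_tempfile(fileext = ".tsv")
  write_length_results(res, path)
  written <- utils::read.delim(path)
  expect_equal(names(written)[1:10],
               c("feature", "n_ctrl", "n_cond", "estimate", "se", "stat",
                 "pval", "padj", "model", "fallback"))
  expect_equal(written$feature, res$transcript_id)
})

test_that("read-level label permutation yields a uniform null for the pipeline", {
  sim <- simulate_scenario(simulation_scenario(n_genes = 200, reads_per_library = 30,
                                               shortening_proportion = 0.6, seed = 17))
  tab <- sim$table
  # permuting reads across libraries within each transcript destroys both the
  # condition effect and the library structure
  set.seed(18)
  idx <- unlist(lapply(split(seq_len(nrow(tab)), tab$transcript_id), sample))
  tab$library_id <- tab$library_id[idx]
  tab$read_id <- paste0(tab$read_id, "_p")
  res <- run_differential_length(tab, sim$design, model = "ttest",
                                 min_reads_per_condition = 10)
  fpr <- mean(res$sig_raw)
  ci <- 2.576 * sqrt(0.05 * 0.95 / nrow(res))
  expect_gt(fpr, 0.05 - ci)
  expect_lt(fpr, 0.05 + ci)
})
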