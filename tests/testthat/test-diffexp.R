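test_that("dispersion estimation recovers known alpha regimes", {
  sf1 <- function(m) setNames(rep(1, ncol(m)), colnames(m))
  pois <- sim_nb_matrix(400, 15, mu = 100, alpha = 0, seed = 1)
  dp <- estimate_dispersions(pois, sf1(pois), rep("all", 30))
  expect_lt(median(dp$alpha), 0.05)

  nb <- sim_nb_matrix(400, 15, mu = 100, alpha = 0.4, seed = 2)
  dn <- estimate_dispersions(nb, sf1(nb), rep("all", 30))
  expect_gt(median(dn$alpha), 0.2)
  expect_lt(median(dn$alpha), 0.6)
  expect_true(all(dn$alpha >= 0))

  const <- toy_counts(matrix(rep(c(5L, 9L, 30L), 4), 3))
  dc <- estimate_dispersions(const, sf1(const), rep("all", 4))
  expect_equal(dc$alpha_genewise, rep(0, 3))
  expect_equal(dc$alpha, rep(0, 3))  # all-constant matrix: trend is zero too

  zero <- toy_counts(rbind(matrix(5L, 3, 4), 0L))
  dz <- estimate_dispersions(zero, sf1(zero), rep("all", 4))
  expect_true(is.na(dz$alpha[4]))
})

test_that("Wald test is symmetric and well calibrated with good power", {
  y <- sim_nb_matrix(300, 15, mu = 100, alpha = 0.2, seed = 3)
  sheet <- two_group_sheet(y, 15)
  sf <- setNames(rep(1, 30), colnames(y))
  disp <- estimate_dispersions(y, sf, sheet$group)
  fwd <- wald_test(y, sheet, c("pSS", "HC"), sf, disp)
  rev <- wald_test(y, sheet, c("HC", "pSS"), sf, disp)
  expect_equal(fwd$log2_fold_change, -rev$log2_fold_change, tolerance = 1e-6)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-6)
  # null calibration (full-size check lives in the acceptance suite)
  expect_gt(mean(fwd$p_value < 0.05, na.rm = TRUE), 0.015)
  expect_lt(mean(fwd$p_value < 0.05, na.rm = TRUE), 0.095)

  pow <- sim_nb_matrix(150, 15, mu = 100, alpha = 0.1, lfc = 2, seed = 4)
  sheet_p <- two_group_sheet(pow, 15)
  disp_p <- estimate_dispersions(pow, sf, sheet_p$group)
  wp <- wald_test(pow, sheet_p, c("pSS", "HC"), sf, disp_p)
  expect_gt(mean(wp$p_value < 0.05, na.rm = TRUE), 0.9)
  expect_equal(mean(wp$log2_fold_change, na.rm = TRUE), 2, tolerance = 0.15)
})

test_that("Wald p-values agree with the exact conditional binomial oracle", {
  # Poisson counts, equal size factors: conditional on the total, the
  # group-A sum is Binomial(total, nA/(nA+nB)) under the null
  y <- sim_nb_matrix(200, 10, mu = 60, alpha = 0, seed = 5)
  sheet <- two_group_sheet(y, 10)
  sf <- setNames(rep(1, 20), colnames(y))
  disp <- data.frame(gene = rownames(y), alpha = 0)
  w <- wald_test(y, sheet, c("pSS", "HC"), sf, disp)
  p_oracle <- vapply(seq_len(nrow(y)), function(g) {
    sa <- sum(y[g, sheet$group == "pSS"])
    binom.test(sa, sa + sum(y[g, sheet$group == "HC"]), 0.5)$p.value
  }, numeric(1))
  expect_gt(cor(w$p_value, p_oracle, method = "spearman",
                use = "complete.obs"), 0.95)
})

test_that("Wald p-values track the DESeq2 oracle on a small fixture", {
  skip_if_not_installed("DESeq2")
  y <- sim_nb_matrix(150, 8, mu = 80, alpha = 0.15, lfc = 1, n_de = 30,
                     seed = 6)
  sheet <- two_group_sheet(y, 8)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      y, data.frame(group = factor(sheet$group, levels = c("HC", "pSS"))),
      ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("group", "pSS", "HC"))
  })
  w <- wald_test(y, sheet, c("pSS", "HC"))
  ok <- !is.na(w$p_value) & !is.na(ref$pvalue)
  expect_gt(cor(w$p_value[ok], ref$pvalue[ok], method = "spearman"), 0.9)
  expect_gt(cor(w$log2_fold_change[ok], ref$log2FoldChange[ok]), 0.95)
})

test_that("LRT matches Wald in two-group designs and is calibrated", {
  y <- sim_nb_matrix(300, 15, mu = 100, alpha = 0.2, seed = 7)
  sheet <- two_group_sheet(y, 15)
  sf <- setNames(rep(1, 30), colnames(y))
  disp <- estimate_dispersions(y, sf, sheet$group)
  w <- wald_test(y, sheet, c("pSS", "HC"), sf, disp)
  l <- lrt_test(y, sheet, sf, disp)
  expect_true(all(l$stat >= 0, na.rm = TRUE))
  ok <- !is.na(w$p_value) & !is.na(l$p_value) & w$base_mean > 50
  ratio <- w$p_value[ok] / l$p_value[ok]
  expect_gt(mean(ratio > 0.5 & ratio < 2), 0.95)
  expect_gt(mean(l$p_value < 0.05, na.rm = TRUE), 0.015)
  expect_lt(mean(l$p_value < 0.05, na.rm = TRUE), 0.095)
})

test_that("effect size drives the statistic monotonically", {
  sf <- setNames(rep(1, 30), sprintf("s%02d", 1:30))
  mean_stat <- vapply(c(0.5, 1, 2), function(lfc) {
    y <- sim_nb_matrix(100, 15, mu = 100, alpha = 0.1, lfc = lfc, seed = 8)
    sheet <- two_group_sheet(y, 15)
    disp <- estimate_dispersions(y, sf, sheet$group)
    mean(abs(wald_test(y, sheet, c("pSS", "HC"), sf, disp)$stat), na.rm = TRUE)
  }, numeric(1))
  expect_false(is.unsorted(mean_stat))
})

test_that("DEG calling is strict and unions comparisons", {
  res <- data.frame(gene = c("a", "b", "c"), comparison = "x",
                    log2_fold_change = 1, stat = 1,
                    p_value = c(0.049, 0.051, 0.5))
  expect_equal(call_degs(res), "a")
  res$p_value <- 0.5
  expect_length(call_degs(res), 0)
  res2 <- data.frame(gene = c("b", "d"), comparison = "LRT",
                     log2_fold_change = 1, stat = 1, p_value = c(0.01, NA))
  expect_setequal(call_degs(list(res, res2)), "b")
})
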