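ifn_genes <- c("IFI44L", "IFI44", "IFIT3", "LY6E", "MX1")

test_that("delta-Ct math and fold-change identities are exact", {
  tab <- make_ct_table(list(
    s1 = c(TARGET = 25),
    s2 = c(TARGET = 21)))
  d <- delta_ct(tab)
  expect_equal(d$delta_ct[d$sample == "s1"], 4)    # 25 - mean(20, 22)
  expect_equal(d$delta_ct[d$sample == "s2"], 0)
  # adding a sample-wide constant leaves delta-Ct unchanged
  tab_shift <- transform(tab, Ct = Ct + ifelse(sample == "s1", 3.7, 0))
  expect_equal(delta_ct(tab_shift)$delta_ct, d$delta_ct)
  # missing housekeeping excludes the sample with a warning
  tab_miss <- tab[!(tab$sample == "s1" & tab$gene == "GUSB"), ]
  expect_warning(d2 <- delta_ct(tab_miss), "s1")
  expect_false("s1" %in% d2$sample)

  expect_equal(fold_change(4, 4), 1)
  expect_equal(fold_change(3, 4), 2)     # delta-delta-Ct of -1
  expect_equal(fold_change(6, 4), 0.25)  # delta-delta-Ct of 2
  x <- rnorm(5)
  expect_equal(fold_change(x, x), rep(1, 5))
})

test_that("IFN-score is the mean healthy-control Z over the five genes", {
  # three HC samples with distinct per-gene delta-Ct patterns
  base <- list(
    HC1 = setNames(c(4, 5, 3, 6, 2), ifn_genes),
    HC2 = setNames(c(5, 6, 5, 7, 4), ifn_genes),
    HC3 = setNames(c(6, 7, 4, 8, 3), ifn_genes))
  hc_expr <- -do.call(rbind, base)
  mu <- colMeans(hc_expr)
  sdv <- apply(hc_expr, 2, sd)
  probes <- list(
    at_mean = setNames(-mu, ifn_genes),
    plus_sd = setNames(-(mu + sdv), ifn_genes))
  ct <- make_ct_table(c(lapply(base, function(x) x + 20), # Ct = dct + hk mean
                        lapply(probes, function(x) x + 20)),
                      housekeeping_ct = c(GAPDH = 19, GUSB = 21))
  sc <- ifn_score(delta_ct(ct), hc_samples = names(base))
  expect_equal(sc$score[sc$sample == "at_mean"], 0, tolerance = 1e-12)
  expect_equal(sc$score[sc$sample == "plus_sd"], 1, tolerance = 1e-12)

  # zero-SD gene is excluded and the divisor adjusted
  base_flat <- lapply(base, function(x) { x["MX1"] <- 5; x })
  probe2 <- probes["plus_sd"]
  probe2$plus_sd["MX1"] <- 5
  ct2 <- make_ct_table(c(lapply(base_flat, function(x) x + 20),
                         lapply(probe2, function(x) x + 20)),
                       housekeeping_ct = c(GAPDH = 19, GUSB = 21))
  expect_warning(sc2 <- ifn_score(delta_ct(ct2), hc_samples = names(base)),
                 "MX1")
  expect_false("Z_MX1" %in% colnames(sc2))
  z_cols <- grep("^Z_", colnames(sc2), value = TRUE)
  expect_length(z_cols, 4)
  expect_equal(sc2$score, rowMeans(sc2[, z_cols]))
})

test_that("planted qPCR shift is recovered near its analytic expectation", {
  ct_sd <- 0.4
  shift <- -2
  tab <- simulate_qpcr(n_hc = 80, n_patient = 80, shift_per_gene = shift,
                       ct_sd = ct_sd, seed = 12)
  sc <- ifn_score(delta_ct(tab),
                  hc_samples = grep("^HC", unique(tab$sample), value = TRUE))
  pt <- mean(sc$score[grepl("^PT", sc$sample)])
  # expression shift is -shift log2 units; HC delta-Ct SD is
  # sqrt(ct_sd^2 + ct_sd^2/2) (target noise + mean of two housekeeping)
  expected <- -shift / sqrt(1.5 * ct_sd^2)
  expect_equal(pt, expected, tolerance = 0.1 * expected)
})

test_that("positivity threshold defaults to HC mean + 2 SD", {
  sc <- data.frame(sample = c("h1", "h2", "h3", "p1", "p2"),
                   score = c(-1, 0, 1, 2.9, 3.1))
  pos <- ifn_positive(sc, hc_samples = c("h1", "h2", "h3"))
  expect_equal(attr(pos, "threshold"), 0 + 2 * 1)
  expect_equal(as.logical(pos), c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("Spearman association matches the enumeration oracle at n = 6", {
  x <- c(3.1, 1.2, 5.4, 2.2, 6.7, 4.0)
  y <- c(2.0, 1.1, 4.9, 3.3, 5.2, 6.1)
  res <- spearman_assoc(x, y)
  expect_equal(res$method, "exact")
  expect_equal(res$rho, cor(x, y, method = "spearman"))
  # oracle: all 720 permutations of y against x
  perms <- modrep:::all_permutations(6)
  null_rho <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  expect_equal(res$p_value, mean(abs(null_rho) >= abs(res$rho) - 1e-12))

  expect_equal(spearman_assoc(1:6, 1:6)$rho, 1)
  expect_equal(spearman_assoc(1:6, 6:1)$rho, -1)
  expect_equal(spearman_assoc(1:6, 1:6)$p_value, 2 / 720)  # two extremes
  expect_true(is.na(spearman_assoc(1:6, rep(1, 6))$rho))
  expect_error(spearman_assoc(1:3, 1:3), ">= 5")
  # t-approximation route at larger n
  set.seed(13)
  big <- spearman_assoc(rnorm(30), rnorm(30))
  expect_equal(big$method, "t-approximation")
  expect_gte(big$p_value, 0)
  expect_lte(big$p_value, 1)
  expect_warning(spearman_assoc(c(1, 1, 2, 3, 4, 5), c(2, 1, 3, 5, 4, 6)),
                 "ties")
})
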