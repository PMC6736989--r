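make_assign <- function(universe, modules) {
  lab <- setNames(rep("background", length(universe)), universe)
  for (m in names(modules)) lab[modules[[m]]] <- m
  lab
}

test_that("module overlap p-values equal the hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  a <- make_assign(universe, list(MA = universe[1:10]))
  b <- make_assign(universe, list(MB = universe[1:10]))
  ov <- module_overlap(a, b, universe)
  expect_equal(ov$overlap, 10L)
  expect_equal(ov$p_value, 1 / choose(100, 10), tolerance = 1e-10)
  expect_equal(ov$p_value, hyper_tail_oracle(10, 10, 10, 100),
               tolerance = 1e-10)

  b2 <- make_assign(universe, list(MB = universe[11:20]))   # disjoint
  expect_equal(module_overlap(a, b2, universe)$p_value, 1)

  # overlap at its expectation (|A||B|/N = 1): tail well inside (0.5, 1]
  b3 <- make_assign(universe, list(MB = universe[c(1, 30:38)]))
  p3 <- module_overlap(a, b3, universe)$p_value
  expect_equal(p3, hyper_tail_oracle(1, 10, 10, 100), tolerance = 1e-10)
  expect_gt(p3, 0.5)

  # independent route: fisher.test one-sided enrichment agrees
  for (ovl in c(2, 5, 8)) {
    bb <- make_assign(universe, list(MB = universe[c(1:ovl, 50:(59 - ovl))]))
    p <- module_overlap(a, bb, universe)$p_value
    tab <- matrix(c(ovl, 10 - ovl, 10 - ovl, 100 - 20 + ovl), 2)
    expect_equal(p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  expect_error(module_overlap(a, b, character(0)), "empty")
})

test_that("signature extraction respects thresholds, labels and merging", {
  universe <- sprintf("g%03d", 1:120)
  a <- make_assign(universe, list(M1 = universe[1:30], M2 = universe[31:50],
                                  M3 = universe[51:70]))
  b <- make_assign(universe, list(N1 = universe[c(1:28, 51:68)],
                                  N2 = universe[31:48]))
  de_tab <- function(genes, lfc) {
    data.frame(gene = genes, comparison = "pSS_vs_HC",
               log2_fold_change = lfc, stat = lfc * 5,
               p_value = 0.001, stringsAsFactors = FALSE)
  }
  lfc <- rep(c(1, -1), length.out = length(universe))
  degs_a <- de_tab(universe, lfc)
  degs_b <- de_tab(universe, lfc)
  ov <- module_overlap(a, b, universe)
  # M3:N1 overlap is 18/20 in a 120-gene universe: p ~ 1e-8
  sigs <- replicated_signatures(ov, a, b, degs_a, degs_b, p_threshold = 1e-5)
  # M1 and M3 both map onto N1 -> merged signature; M2:N2 separate
  expect_length(sigs, 2)
  merged <- sigs[[which(vapply(sigs, function(s) length(s$modules_a) == 2,
                               logical(1)))]]
  expect_setequal(merged$modules_a, c("M1", "M3"))
  expect_setequal(merged$members, universe[c(1:28, 51:68)])
  expect_true(all(merged$direction %in% c("up", "down")))

  # label-permutation invariance
  b_re <- b
  b_re[b_re == "N1"] <- "XX"
  sigs2 <- replicated_signatures(module_overlap(a, b_re, universe), a, b_re,
                                 degs_a, degs_b, p_threshold = 1e-5)
  expect_setequal(unname(unlist(lapply(sigs, `[[`, "members"))),
                  unname(unlist(lapply(sigs2, `[[`, "members"))))

  expect_length(replicated_signatures(ov, a, b, degs_a, degs_b,
                                      p_threshold = 0), 0)

  # members restricted to DEGs replicated in both cohorts
  degs_b2 <- degs_b
  degs_b2$p_value[degs_b2$gene %in% universe[1:5]] <- 0.5
  sigs3 <- replicated_signatures(ov, a, b, degs_a, degs_b2,
                                 p_threshold = 1e-5)
  mem3 <- unlist(lapply(sigs3, `[[`, "members"))
  expect_false(any(universe[1:5] %in% mem3))
})

test_that("hub selection uses strict signature-wise percentiles in both cohorts", {
  genes <- sprintf("g%d", 1:8)
  kn <- seq(0, 1, length.out = 8)
  conn <- data.frame(gene = genes, module = "M1", k_raw = kn, k_norm = kn)
  hubs <- hub_genes(conn, conn, genes, percentile = 75)
  # 75th percentile (type 7) of 8 equally spaced points is 0.75: top 2 exceed
  expect_setequal(hubs, c("g7", "g8"))

  conn_eq <- transform(conn, k_norm = 0.5)
  expect_length(hub_genes(conn_eq, conn_eq, genes), 0)

  expect_warning(h_small <- hub_genes(conn, conn, genes[1:3]), "fewer than 4")
  expect_length(h_small, 0)

  # monotone: raising the percentile never adds genes
  h90 <- hub_genes(conn, conn, genes, percentile = 90)
  expect_true(all(h90 %in% hubs))

  # independence null: expected hub fraction ~ 1/16
  set.seed(8)
  n <- 4000
  g <- sprintf("h%04d", 1:n)
  ca <- data.frame(gene = g, module = "M", k_raw = 0, k_norm = runif(n))
  cb <- data.frame(gene = g, module = "M", k_raw = 0, k_norm = runif(n))
  frac <- length(hub_genes(ca, cb, g)) / n
  expect_gt(frac, 0.045)
  expect_lt(frac, 0.082)
})

test_that("directionality concordance counts shared significant genes", {
  d <- data.frame(gene = sprintf("g%d", 1:50), comparison = "pSS_vs_HC",
                  log2_fold_change = rnorm(50), stat = 1,
                  p_value = rep(c(0.01, 0.5), 25))
  cc <- directionality_concordance(d, d)
  expect_equal(cc$fraction_same_sign, 1)
  expect_equal(cc$n, 25)
  d_neg <- transform(d, log2_fold_change = -log2_fold_change)
  expect_equal(directionality_concordance(d, d_neg)$fraction_same_sign, 0)
  d_other <- transform(d, gene = sprintf("x%d", 1:50))
  cc0 <- directionality_concordance(d, d_other)
  expect_equal(cc0$n, 0)
  expect_true(is.na(cc0$fraction_same_sign))
})
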