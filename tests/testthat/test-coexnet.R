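test_that("Spearman correlation matrix honors rank invariance", {
  x <- block_expr(10, 20, seed = 1)
  x <- rbind(x, dup = x[1, ], neg = -x[1, ], cube = x[1, ]^3)
  cm <- correlation_matrix(x)
  expect_equal(cm["g001", "dup"], 1)
  expect_equal(cm["g001", "neg"], -1)
  expect_equal(cm["g001", "cube"], 1)   # monotone transform
  expect_true(isSymmetric(unname(cm)))
  x2 <- rbind(x, flat = rep(2, ncol(x)))
  expect_warning(cm2 <- correlation_matrix(x2), "constant")
  expect_false("flat" %in% rownames(cm2))
  expect_error(correlation_matrix(x[, 1:3]), ">= 4 samples")
})

test_that("soft-threshold adjacency is the unsigned power transform", {
  cm <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0, -0.5, 0, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  a <- adjacency_matrix(cm, 6)
  expect_equal(a["a", "b"], 0.5^6)
  expect_equal(a["a", "c"], 0.5^6)   # unsigned: sign dropped
  expect_equal(diag(a), setNames(rep(1, 3), letters[1:3]))
  expect_equal(adjacency_matrix(matrix(c(1, 0, 0, 1), 2), 6)[1, 2], 0)
})

test_that("scale-free fit index detects power-law degree structure", {
  # construct an adjacency whose connectivities follow k^-2 exactly
  set.seed(2)
  n <- 300
  k <- round(10 * (1 - (1:n) / (n + 1))^(-1 / 1.5))  # inverse-cdf power law
  k <- k / max(k)
  a <- outer(k, k) / sum(k)
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  expect_gt(scale_free_fit(a), 0.9)

  flat <- matrix(0.2, 50, 50, dimnames = list(sprintf("g%02d", 1:50),
                                              sprintf("g%02d", 1:50)))
  diag(flat) <- 1
  expect_true(is.na(scale_free_fit(flat)))

  # raising beta improves the fit on module-structured data
  x <- block_expr(c(40, 40), 30, n_noise = 60, seed = 3)
  cm <- correlation_matrix(x)
  r2 <- vapply(c(1, 6), function(b) scale_free_fit(adjacency_matrix(cm, b)),
               numeric(1))
  expect_gt(r2[2], r2[1])
})

test_that("module detection recovers planted blocks and ignores noise", {
  x <- block_expr(c(50, 50), 40, loading = 0.9, noise_sd = 0.45, seed = 4)
  net <- build_network(x, rownames(x), beta = 6)
  truth <- rep(c("A", "B"), each = 50)
  found <- net$module_of[rownames(x)]
  expect_equal(length(setdiff(unique(found), "background")), 2)
  expect_gte(adjusted_rand_index(truth, found), 0.9)

  # permuting gene order: identical partition up to label renaming
  perm <- sample(nrow(x))
  net_p <- build_network(x[perm, ], rownames(x)[perm], beta = 6)
  expect_gte(adjusted_rand_index(net$module_of[rownames(x)],
                                 net_p$module_of[rownames(x)]), 0.999)

  noise <- block_expr(integer(0), 40, n_noise = 200, seed = 5)
  net_n <- build_network(noise, rownames(noise), beta = 6)
  expect_gte(mean(net_n$module_of == "background"), 0.9)
})

test_that("module eigengene is the oriented first principal component", {
  prof <- rnorm(25)
  x <- matrix(rep(prof, each = 6), 6, byrow = FALSE,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%02d", 1:25)))
  x <- x + matrix(rnorm(150, sd = 1e-6), 6)
  eg <- module_eigengene(x, rownames(x))
  zs <- as.numeric(scale(prof))
  expect_gt(cor(eg, zs), 0.999)
  expect_gt(sum(eg * zs), 0)          # oriented along the mean profile
  expect_equal(sum(eg^2), 1)          # unit norm
  # scaling all values leaves the standardized eigengene unchanged
  expect_equal(module_eigengene(2 * x, rownames(x)), eg, tolerance = 1e-6)

  # two anti-correlated halves: one factor still carries the module, and the
  # eigengene tracks it deterministically (orientation fixed by the data)
  set.seed(6)
  f <- rnorm(40)
  y <- rbind(matrix(rep(f, each = 10), 10, byrow = FALSE),
             matrix(rep(-f, each = 10), 10, byrow = FALSE)) +
    matrix(rnorm(800, sd = 0.05), 20)
  dimnames(y) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:40))
  eg2 <- module_eigengene(y, rownames(y))
  expect_gt(abs(cor(eg2, f)), 0.99)
  expect_identical(eg2, module_eigengene(y, rownames(y)))
})

test_that("intramodular connectivity normalizes each module to [0, 1]", {
  set.seed(7)
  n <- 12
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  mod <- setNames(rep(c("M1", "M2"), each = 6), rownames(a))
  k <- module_connectivity(a, mod)
  # oracle: affine map of the raw within-module sums
  for (m in c("M1", "M2")) {
    sub <- k[k$module == m, ]
    mg <- sub$gene
    raw <- rowSums(a[mg, mg]) - 1
    expect_equal(sub$k_raw, unname(raw))
    expect_equal(sub$k_norm, unname((raw - min(raw)) / (max(raw) - min(raw))))
    expect_equal(range(sub$k_norm), c(0, 1))
  }
  # degenerate all-equal connectivity maps to 0
  eq <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 1
  keq <- module_connectivity(eq, setNames(rep("M1", 4), letters[1:4]))
  expect_equal(keq$k_norm, rep(0, 4))
  # single-gene modules are excluded
  k1 <- module_connectivity(eq, setNames(c("M1", "M1", "M1", "M2"),
                                         letters[1:4]))
  expect_false("M2" %in% k1$module)
})
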