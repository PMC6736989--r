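# shared fixtures and independent oracles used across test files

toy_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  storage.mode(m) <- "integer"
  m
}

two_group_sheet <- function(counts, n1 = ncol(counts) %/% 2,
                            groups = c("HC", "pSS"), cohort = "discovery") {
  data.frame(sample_id = colnames(counts),
             group = rep(groups, c(n1, ncol(counts) - n1)),
             cohort = cohort, stringsAsFactors = FALSE)
}

# NB count matrix with a planted two-group log2 effect on the first
# `n_de` genes; alpha = 0 gives Poisson counts
sim_nb_matrix <- function(n_genes, n_per_group, mu = 100, alpha = 0.2,
                          lfc = 0, n_de = n_genes, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  mu_mat <- matrix(mu, n_genes, n)
  if (lfc != 0 && n_de > 0)
    mu_mat[seq_len(n_de), (n_per_group + 1):n] <- mu * 2^lfc
  draw <- function(m) if (alpha > 0) rnbinom(1, size = 1 / alpha, mu = m)
                      else rpois(1, m)
  y <- matrix(vapply(mu_mat, draw, numeric(1)), n_genes, n)
  toy_counts(y, genes = sprintf("g%04d", seq_len(n_genes)))
}

# Gaussian latent-factor expression matrix: one factor per block
block_expr <- function(block_sizes, n_samples, loading = 0.8, noise_sd = 0.6,
                       n_noise = 0, seed = 1) {
  set.seed(seed)
  ng <- sum(block_sizes) + n_noise
  x <- matrix(rnorm(ng * n_samples, sd = noise_sd), ng, n_samples)
  idx <- 1
  for (b in seq_along(block_sizes)) {
    f <- rnorm(n_samples)
    rows <- idx:(idx + block_sizes[b] - 1)
    x[rows, ] <- x[rows, ] + loading * matrix(f, length(rows), n_samples,
                                              byrow = TRUE)
    idx <- idx + block_sizes[b]
  }
  dimnames(x) <- list(sprintf("g%03d", seq_len(ng)),
                      sprintf("s%03d", seq_len(n_samples)))
  x
}

# adjusted Rand index between two labelings (independent closed form)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

# brute-force hypergeometric upper tail P(overlap >= ov)
hyper_tail_oracle <- function(ov, n_a, n_b, N) {
  ks <- ov:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(N - n_a, n_b - ks)) / choose(N, n_b)
}

# naive running-sum GSEA enrichment score (independent oracle)
es_oracle <- function(scores, in_set, weight = 1) {
  N <- length(scores)
  stopifnot(any(in_set), !all(in_set))
  inc <- rep(-1 / (N - sum(in_set)), N)
  w <- abs(scores[in_set])^weight
  if (sum(w) == 0) w <- rep(1, sum(in_set))
  inc[in_set] <- w / sum(w)
  run <- cumsum(inc)
  hi <- max(run)
  lo <- min(run)
  if (round(hi, 12) >= round(-lo, 12)) hi else lo
}

# exact delta-Ct table builder: one row per sample x gene
make_ct_table <- function(ct_by_sample, housekeeping_ct = c(GAPDH = 20, GUSB = 22)) {
  rows <- list()
  for (s in names(ct_by_sample)) {
    tg <- ct_by_sample[[s]]
    rows[[s]] <- data.frame(
      sample = s, gene = c(names(tg), names(housekeeping_ct)),
      Ct = c(unname(tg), unname(housekeeping_ct)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
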