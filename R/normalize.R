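#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed as the median, over genes
#' expressed in every sample, of the ratio of each sample's count to the
#' gene's geometric mean across samples. This makes factors robust to a
#' minority of differentially expressed genes, unlike total-count scaling.
#'
#' @param counts integer matrix, genes x samples.
#' @return positive numeric vector, one factor per sample (named).
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has nonzero counts in every sample; filter samples or genes first")
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)                       # log geometric mean per gene
  sf <- apply(lc, 2, function(x) exp(stats::median(x - ref)))
  stats::setNames(sf, colnames(counts))
}

#' Remove one (or k) unwanted-variation factors from counts
#'
#' Estimates hidden factors (batch, processing date, handler) from the
#' residual structure that the known group design does not explain: a
#' negative-binomial GLM of each gene's counts on group (with a log
#' size-factor offset) is fitted, the per-gene deviance residuals are
#' stacked into a genes x samples matrix, and the first `k` right singular
#' vectors of that matrix are taken as the unwanted factors. The factors are
#' then regressed out of the log-scale counts (protecting the group effects),
#' and counts are returned on the original depth scale, rounded and floored
#' at zero.
#'
#' @param counts integer matrix, genes x samples.
#' @param samples sample sheet with `sample_id` and `group`, rows matching
#'   `colnames(counts)`.
#' @param k number of unwanted factors (default 1).
#' @param dispersions optional per-gene dispersion vector; estimated
#'   internally when missing.
#' @return list with `corrected` (integer matrix, same shape), `factors`
#'   (samples x k matrix of estimated unwanted factors) and `size_factors`.
#' @export
remove_unwanted_variation <- function(counts, samples, k = 1,
                                      dispersions = NULL) {
  validate_counts(counts)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (anyNA(samples$sample_id)) stop("sample sheet does not cover all samples")
  if (k < 1) stop("k must be >= 1")
  if (k >= ncol(counts)) stop("k must be smaller than the number of samples")
  sf <- size_factors(counts)
  off <- log(sf)
  keep <- rowSums(counts) > 0
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, sf, samples$group)$alpha
  X <- group_design(samples$group)
  res <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (g in which(keep)) {
    a <- if (is.finite(dispersions[g])) dispersions[g] else 0
    fit <- nb_irls(counts[g, ], X, offset = off, alpha = a)
    res[g, ] <- nb_deviance_residuals(counts[g, ], fit$mu, a)
  }
  sv <- svd(res[keep, , drop = FALSE], nu = 0, nv = k)
  W <- sv$v[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(counts)
  colnames(W) <- paste0("W", seq_len(k))

  # regress factors out of log2 counts while protecting the group design
  y <- log2(counts + 0.5)
  D <- cbind(X, W)
  H <- solve(t(D) %*% D, t(D))
  B <- y %*% t(H)                           # genes x (p + k) coefficients
  adj <- y - B[, ncol(X) + seq_len(k), drop = FALSE] %*% t(W)
  corrected <- round(pmax(2^adj - 0.5, 0))
  storage.mode(corrected) <- "integer"
  list(corrected = corrected, factors = W, size_factors = sf)
}

#' Variance-stabilizing transformation (shifted log)
#'
#' `log2(count / size_factor + pseudocount)`: monotone within each sample and
#' approximately variance-stabilizing for overdispersed counts, adequate for
#' the rank-based (Spearman) network analysis downstream. This is a simpler,
#' documented alternative to a dispersion-calibrated transform.
#'
#' @param counts integer matrix, genes x samples.
#' @param sf per-sample size factors; computed via [size_factors()] when NULL.
#' @param pseudocount positive shift (default 1).
#' @return numeric matrix of the same shape.
#' @export
vst_transform <- function(counts, sf = NULL, pseudocount = 1) {
  validate_counts(counts)
  stopifnot(pseudocount > 0)
  if (is.null(sf)) sf <- size_factors(counts)
  stopifnot(all(sf > 0), length(sf) == ncol(counts))
  log2(sweep(counts, 2, sf, `/`) + pseudocount)
}

#' Drop genes with no counts anywhere
#'
#' @param counts integer matrix.
#' @param min_total minimum total count across samples to keep a gene
#'   (default 1, i.e. drop only all-zero genes).
#' @return the filtered matrix.
#' @export
filter_zero_genes <- function(counts, min_total = 1) {
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}
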