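#' Estimate per-gene negative-binomial dispersions
#'
#' Gene-wise method-of-moments estimates on size-factor-normalized counts,
#' computed within groups so that real group differences do not inflate the
#' dispersion, floored at zero, then shrunk 50% toward a robustly fitted
#' mean-dispersion trend `alpha(mu) = a0 + a1 / mu`. All-zero genes get
#' `NA` and are flagged.
#'
#' For a gene with true mean `mu` and dispersion `alpha`,
#' `Var(count / s) ~ mu * E(1/s) + alpha * mu^2`, which the moment estimator
#' inverts.
#'
#' @param counts integer matrix, genes x samples.
#' @param sf per-sample size factors (default [size_factors()]).
#' @param group group label per sample.
#' @return data.frame: gene, alpha (shrunk), alpha_genewise, method.
#' @export
estimate_dispersions <- function(counts, sf = NULL, group = NULL) {
  validate_counts(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(group)) group <- rep("all", ncol(counts))
  group <- as.character(group)
  q <- sweep(counts, 2, sf, `/`)
  xi <- mean(1 / sf)
  glev <- unique(group)
  n <- ncol(counts)
  mu_hat <- rowMeans(q)
  # pooled within-group variance
  ss <- 0
  df <- 0
  for (g in glev) {
    j <- group == g
    if (sum(j) < 2) next
    m <- rowMeans(q[, j, drop = FALSE])
    ss <- ss + rowSums((q[, j, drop = FALSE] - m)^2)
    df <- df + sum(j) - 1
  }
  if (df < 1) stop("need at least 2 samples in some group")
  v <- ss / df
  raw <- pmax((v - mu_hat * xi) / mu_hat^2, 0)
  raw[mu_hat == 0] <- NA_real_

  ok <- is.finite(raw) & mu_hat > 0
  alpha <- raw
  method <- rep("gene-wise", nrow(counts))
  if (sum(ok) >= 10) {
    fit <- tryCatch(
      MASS::rlm(raw[ok] ~ I(1 / mu_hat[ok]), maxit = 50),
      error = function(e) NULL, warning = function(w) NULL)
    co <- if (is.null(fit)) {
      stats::coef(stats::lm(raw[ok] ~ I(1 / mu_hat[ok])))
    } else stats::coef(fit)
    trend <- pmax(co[1] + co[2] / mu_hat, 1e-8)
    alpha[ok] <- 0.5 * raw[ok] + 0.5 * trend[ok]
    method[ok] <- "trend-shrunk"
  }
  data.frame(gene = rownames(counts), alpha = alpha, alpha_genewise = raw,
             method = method, row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise Wald test for differential expression
#'
#' Per gene, fits a negative-binomial GLM (log link) of counts on a group
#' indicator with a log size-factor offset, restricted to the two contrasted
#' groups; the Wald statistic is the group coefficient divided by its
#' standard error, with a two-sided p-value from the standard normal.
#'
#' @param counts integer matrix, genes x samples.
#' @param samples sample sheet (`sample_id`, `group`).
#' @param contrast length-2 character vector `c(groupA, groupB)`; the reported
#'   `log2_fold_change` is A relative to B (e.g. `c("pSS","HC")` gives
#'   pSS vs HC).
#' @param sf size factors over ALL samples (default computed).
#' @param dispersions data.frame from [estimate_dispersions()] (default
#'   computed on the full matrix).
#' @param covariates optional numeric matrix (samples x q) of extra
#'   covariates, e.g. the estimated unwanted-variation factor.
#' @return data.frame: gene, comparison, base_mean, log2_fold_change, stat,
#'   p_value. Non-converged or all-zero genes have `NA` statistics.
#' @export
wald_test <- function(counts, samples, contrast, sf = NULL,
                      dispersions = NULL, covariates = NULL) {
  validate_counts(counts)
  stopifnot(length(contrast) == 2)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, sf, samples$group)
  j <- samples$group %in% contrast
  if (sum(samples$group == contrast[1]) < 2 || sum(samples$group == contrast[2]) < 2)
    stop("both contrasted groups need >= 2 samples")
  y <- counts[, j, drop = FALSE]
  off <- log(sf[j])
  # reference = contrast[2] so the coefficient is log(A) - log(B)
  grp <- factor(samples$group[j], levels = c(contrast[2], contrast[1]))
  covj <- if (!is.null(covariates)) as.matrix(covariates)[j, , drop = FALSE] else NULL
  X <- group_design(grp, covj)
  ci <- match(contrast[1], colnames(X))
  alpha <- dispersions$alpha[match(rownames(counts), dispersions$gene)]
  comparison <- paste0(contrast[1], "_vs_", contrast[2])
  n_g <- nrow(y)
  lfc <- st <- pv <- rep(NA_real_, n_g)
  bm <- rowMeans(sweep(y, 2, sf[j], `/`))
  for (g in seq_len(n_g)) {
    if (all(y[g, ] == 0) || !is.finite(alpha[g])) next
    fit <- nb_irls(y[g, ], X, offset = off, alpha = alpha[g])
    if (!fit$converged || !is.finite(fit$se[ci]) || fit$se[ci] <= 0) next
    lfc[g] <- fit$beta[ci] / log(2)
    st[g] <- fit$beta[ci] / fit$se[ci]
    pv[g] <- 2 * stats::pnorm(-abs(st[g]))
  }
  data.frame(gene = rownames(y), comparison = comparison, base_mean = bm,
             log2_fold_change = lfc, stat = st, p_value = pv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-group likelihood-ratio test
#'
#' Per gene, compares the full NB GLM (`~ group`, plus any covariates) to the
#' reduced model without group; the statistic `2 * (ll_full - ll_reduced)` is
#' referred to a chi-square with `n_groups - 1` degrees of freedom.
#'
#' @inheritParams wald_test
#' @return data.frame: gene, comparison ("LRT"), base_mean,
#'   log2_fold_change (pSS vs HC when both present, else last vs first
#'   group), stat, p_value.
#' @export
lrt_test <- function(counts, samples, sf = NULL, dispersions = NULL,
                     covariates = NULL) {
  validate_counts(counts)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, sf, samples$group)
  glev <- unique(samples$group)
  if (length(glev) < 2) stop("LRT needs >= 2 groups")
  # orient the reported fold change at pSS vs HC when available
  ref <- if ("HC" %in% glev) "HC" else glev[1]
  alt <- if ("pSS" %in% glev) "pSS" else glev[length(glev)]
  grp <- factor(samples$group, levels = c(ref, setdiff(glev, ref)))
  covm <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  Xf <- group_design(grp, covm)
  Xr <- group_design(factor(rep("all", ncol(counts))), covm)
  ci <- match(alt, colnames(Xf))
  off <- log(sf)
  alpha <- dispersions$alpha[match(rownames(counts), dispersions$gene)]
  df <- length(glev) - 1
  n_g <- nrow(counts)
  lfc <- st <- pv <- rep(NA_real_, n_g)
  bm <- rowMeans(sweep(counts, 2, sf, `/`))
  for (g in seq_len(n_g)) {
    if (all(counts[g, ] == 0) || !is.finite(alpha[g])) next
    ff <- nb_irls(counts[g, ], Xf, offset = off, alpha = alpha[g])
    fr <- nb_irls(counts[g, ], Xr, offset = off, alpha = alpha[g])
    if (!ff$converged || !fr$converged) next
    st[g] <- max(2 * (ff$loglik - fr$loglik), 0)
    pv[g] <- stats::pchisq(st[g], df = df, lower.tail = FALSE)
    if (!is.na(ci)) lfc[g] <- ff$beta[ci] / log(2)
  }
  data.frame(gene = rownames(counts), comparison = "LRT", base_mean = bm,
             log2_fold_change = lfc, stat = st, p_value = pv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes at a nominal p-value
#'
#' Strict `p < alpha`, no multiple-testing correction: the design relies on
#' cross-cohort replication rather than FDR control, so nominal p-values are
#' used deliberately.
#'
#' @param results one or more DE result data.frames (rbind-compatible).
#' @param alpha nominal threshold (default 0.05).
#' @return character vector of gene ids significant in at least one of the
#'   supplied comparisons.
#' @export
call_degs <- function(results, alpha = 0.05) {
  if (is.data.frame(results)) results <- list(results)
  res <- do.call(rbind, results)
  unique(res$gene[!is.na(res$p_value) & res$p_value < alpha])
}

#' Run all pairwise Wald tests plus the multi-group LRT for one cohort
#'
#' Convenience wrapper producing the network input rule: the union of genes
#' differentially expressed (p < alpha) in any pairwise Wald comparison or in
#' the multi-group LRT.
#'
#' @inheritParams wald_test
#' @param alpha nominal DEG threshold.
#' @return list with `tables` (named list of DE data.frames, one per pairwise
#'   comparison plus `"LRT"`), `degs` (the union), `dispersions`, `sf`.
#' @export
run_de <- function(counts, samples, sf = NULL, dispersions = NULL,
                   covariates = NULL, alpha = 0.05) {
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, sf, samples$group)
  glev <- unique(samples$group)
  ord <- c("pSS", "nSS", "HC")
  glev <- c(intersect(ord, glev), setdiff(glev, ord))
  tables <- list()
  if (length(glev) >= 2) {
    prs <- utils::combn(glev, 2, simplify = FALSE)
    for (p in prs) {
      tb <- wald_test(counts, samples, contrast = p, sf = sf,
                      dispersions = dispersions, covariates = covariates)
      tables[[tb$comparison[1]]] <- tb
    }
  }
  if (length(glev) > 2)
    tables[["LRT"]] <- lrt_test(counts, samples, sf = sf,
                                dispersions = dispersions,
                                covariates = covariates)
  list(tables = tables, degs = call_degs(tables, alpha),
       dispersions = dispersions, sf = sf)
}
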