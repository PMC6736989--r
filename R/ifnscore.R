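#' Delta-Ct normalization against housekeeping genes
#'
#' `delta_Ct = Ct_target - mean(Ct_housekeeping)` per sample and target gene.
#' Samples missing any housekeeping gene are excluded with a warning.
#' Because the housekeeping mean is subtracted, adding a constant to all Ct
#' values of a sample (e.g. from input amount) leaves delta-Ct unchanged.
#'
#' @param ct data.frame with columns sample, gene, Ct (duplicate wells
#'   already averaged).
#' @param housekeeping housekeeping gene ids (default GAPDH and GUSB).
#' @return data.frame: sample, gene, delta_ct (target genes only).
#' @export
delta_ct <- function(ct, housekeeping = c("GAPDH", "GUSB")) {
  stopifnot(all(c("sample", "gene", "Ct") %in% colnames(ct)))
  out <- list()
  for (s in unique(ct$sample)) {
    sub <- ct[ct$sample == s, ]
    hk <- sub$Ct[match(housekeeping, sub$gene)]
    if (anyNA(hk)) {
      warning("sample ", s, " lacks housekeeping measurement(s); excluded")
      next
    }
    tg <- sub[!(sub$gene %in% housekeeping), ]
    out[[s]] <- data.frame(sample = s, gene = tg$gene,
                           delta_ct = tg$Ct - mean(hk),
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), gene = character(),
                      delta_ct = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' qPCR relative fold change
#'
#' `FC = 2^-(delta_Ct_sample - delta_Ct_reference)`: one fewer cycle than the
#' reference means twice the expression.
#'
#' @param dct_sample,dct_reference delta-Ct values (vectorized).
#' @return fold change(s).
#' @export
fold_change <- function(dct_sample, dct_reference) {
  2^-(dct_sample - dct_reference)
}

#' Composite five-gene interferon score
#'
#' For each of the five interferon-induced genes (by default IFI44L, IFI44,
#' IFIT3, LY6E, MX1), expression is taken as `-delta_Ct` (log2 relative
#' expression, so higher expression gives a higher value), standardized
#' against the healthy-control samples (`Z = (x - mean_HC) / sd_HC`), and the
#' score is the mean of the per-gene Z values — the sum divided by the number
#' of genes measured. Genes whose HC standard deviation is zero are excluded
#' and the divisor adjusted, with a warning.
#'
#' @param dct data.frame from [delta_ct()].
#' @param hc_samples sample ids of the healthy-control reference group
#'   (>= 2 required).
#' @param genes the score's target genes.
#' @return data.frame: sample, score, plus one `Z_<gene>` column per gene.
#' @export
ifn_score <- function(dct, hc_samples,
                      genes = c("IFI44L", "IFI44", "IFIT3", "LY6E", "MX1")) {
  stopifnot(length(hc_samples) >= 2)
  dct <- dct[dct$gene %in% genes, ]
  wide <- stats::reshape(dct, idvar = "sample", timevar = "gene",
                         direction = "wide")
  colnames(wide) <- sub("^delta_ct\\.", "", colnames(wide))
  miss <- setdiff(genes, colnames(wide))
  if (length(miss) > 0) stop("missing score gene(s): ", paste(miss, collapse = ", "))
  expr <- -as.matrix(wide[, genes, drop = FALSE])   # log2 relative expression
  rownames(expr) <- wide$sample
  hc <- expr[rownames(expr) %in% hc_samples, , drop = FALSE]
  if (nrow(hc) < 2) stop("need >= 2 HC samples with complete measurements")
  mu <- colMeans(hc)
  sd_hc <- apply(hc, 2, stats::sd)
  use <- sd_hc > 0
  if (!all(use)) {
    warning("zero HC standard deviation for ",
            paste(genes[!use], collapse = ", "), "; excluded from score")
  }
  z <- sweep(sweep(expr[, use, drop = FALSE], 2, mu[use]), 2, sd_hc[use], `/`)
  score <- rowMeans(z)
  out <- data.frame(sample = rownames(expr), score = score,
                    stringsAsFactors = FALSE)
  zdf <- as.data.frame(z)
  colnames(zdf) <- paste0("Z_", colnames(zdf))
  rownames(out) <- NULL
  cbind(out, zdf, row.names = NULL)
}

#' Interferon-signature positivity calls
#'
#' The study's positivity cutoff is not published; the default here is the
#' healthy-control mean plus two HC standard deviations of the score,
#' configurable — an assumption recorded in the output attributes.
#'
#' @param scores data.frame from [ifn_score()].
#' @param hc_samples HC sample ids.
#' @param n_sd number of HC standard deviations above the HC mean (default 2).
#' @return logical vector named by sample, with attribute `"threshold"`.
#' @export
ifn_positive <- function(scores, hc_samples, n_sd = 2) {
  hc <- scores$score[scores$sample %in% hc_samples]
  thr <- mean(hc) + n_sd * stats::sd(hc)
  structure(stats::setNames(scores$score > thr, scores$sample),
            threshold = thr)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Spearman's rho with a two-sided p-value: for `n <= 9` without ties the
#' p-value is exact, from full enumeration of all `n!` rank permutations;
#' otherwise the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom is
#' used (with a warning when ties prevented the exact route).
#'
#' @param x,y paired numeric vectors, `n >= 5`.
#' @return list: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need >= 5 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "degenerate"))
  rho <- stats::cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    rx <- rank(x)
    ry <- rank(y)
    perms <- all_permutations(n)
    # rho for each permutation of y-ranks against fixed x-ranks (no ties)
    denom <- n * (n^2 - 1)
    null_rho <- apply(perms, 1, function(p) 1 - 6 * sum((rx - ry[p])^2) / denom)
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    return(list(rho = rho, p_value = p, n = n, method = "exact"))
  }
  if (n <= 9 && ties)
    warning("ties present; falling back to t-approximation for the p-value")
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p_value = min(p, 1), n = n, method = "t-approximation")
}

# all permutations of 1..n as an (n! x n) matrix; n <= 9
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}
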