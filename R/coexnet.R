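#' Spearman correlation matrix between genes
#'
#' Rank correlation (ties mid-ranked) between the rows of a
#' variance-stabilized expression matrix. Constant genes have undefined
#' correlation and are dropped with a warning.
#'
#' @param vsd numeric matrix, genes x samples.
#' @param genes optional subset of gene ids (rows) to use.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(vsd, genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(vsd))
    if (length(missing) > 0)
      stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    vsd <- vsd[genes, , drop = FALSE]
  }
  if (ncol(vsd) < 4) stop("need >= 4 samples for a rank correlation network")
  cons <- apply(vsd, 1, function(x) stats::sd(x) == 0)
  if (any(cons)) {
    warning(sum(cons), " constant gene(s) dropped from correlation matrix")
    vsd <- vsd[!cons, , drop = FALSE]
  }
  cm <- stats::cor(t(vsd), method = "spearman")
  diag(cm) <- 1
  cm
}

#' Soft-threshold adjacency
#'
#' Unsigned adjacency `a_ij = |cor_ij|^beta`. Raising the absolute
#' correlation to a power suppresses weak (noise) correlations while
#' preserving strong ones, pushing the network toward scale-free topology.
#'
#' @param cor_mat symmetric correlation matrix in `[-1, 1]`.
#' @param beta soft-threshold power (default 6).
#' @return adjacency matrix in `[0, 1]`, unit diagonal.
#' @export
adjacency_matrix <- function(cor_mat, beta = 6) {
  stopifnot(beta > 0, isSymmetric(unname(cor_mat)))
  a <- abs(cor_mat)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit index
#'
#' Whole-network connectivities `k_i = sum_{j != i} a_ij` are binned (10
#' equal-width bins); the fit is the R-squared of the linear regression of
#' `log10(p(k))` on `log10(mean k)` over non-empty bins. Returns `NA` when
#' the degree distribution is degenerate (all connectivities equal).
#'
#' @param adj adjacency matrix.
#' @param n_bins number of connectivity bins (default 10).
#' @return R-squared in `[0, 1]`, or `NA`.
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  stopifnot(nrow(adj) >= 20)
  k <- rowSums(adj) - diag(adj)
  if (max(k) - min(k) < sqrt(.Machine$double.eps)) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tabulate(bin, nbins = n_bins) / length(k)
  keep <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  summary(fit)$r.squared
}

#' Topological overlap similarity
#'
#' For an unsigned adjacency `A` (diagonal ignored),
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L = A %*% A` on the zero-diagonal matrix: two genes are similar when they
#' are connected AND share neighbors, which is far more robust to single
#' noisy correlations than the adjacency alone.
#'
#' @param adj adjacency matrix.
#' @return symmetric TOM similarity matrix, unit diagonal.
#' @export
tom_similarity <- function(adj) {
  A <- adj
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' TOM dissimilarity (`1 - TOM`) is clustered by average-linkage hierarchical
#' clustering and the dendrogram is cut adaptively (a simplified dynamic tree
#' cut): candidate cut heights spanning the merge-height distribution are
#' scanned, and at each height every branch of at least `min_module_size`
#' genes is quality-checked — its mean within-branch TOM similarity must
#' exceed `quality_ratio` times its mean TOM to the rest of the network
#' (this rejects the single diffuse branch that pure-noise networks
#' produce). The cut retained is the one yielding the most quality-passing
#' branches (ties: more genes assigned, then the lower height). Finally,
#' modules whose eigengenes correlate above `1 - merge_height` are merged,
#' which re-joins accidental splits of one co-expression factor. All
#' remaining genes are labeled `"background"`. Module labels are assigned in
#' decreasing size order (`M1`, `M2`, ...), so the partition is invariant to
#' gene order up to label names.
#'
#' @param adj adjacency matrix (genes x genes, named).
#' @param vsd expression matrix used for eigengene-based module merging.
#' @param min_module_size smallest accepted module (default 30).
#' @param merge_height eigengene dissimilarity below which two modules merge
#'   (default 0.25, i.e. eigengene correlation > 0.75).
#' @param quality_ratio minimum ratio of a module's mean within TOM to its
#'   mean TOM toward non-members (default 2).
#' @param n_heights number of candidate cut heights scanned (default 60).
#' @param kme_threshold minimum absolute eigengene correlation for the final
#'   gene-to-module assignment stage (default 0.5); genes below it go to the
#'   background.
#' @return list with `module_of` (named character vector, `"background"`
#'   allowed), `eigengenes` (samples x modules matrix), `tom`.
#' @export
detect_modules <- function(adj, vsd, min_module_size = 30,
                           merge_height = 0.25, quality_ratio = 2,
                           n_heights = 60, kme_threshold = 0.5) {
  genes <- rownames(adj)
  if (nrow(adj) < min_module_size) {
    return(list(module_of = stats::setNames(rep("background", nrow(adj)), genes),
                eigengenes = NULL, tom = NULL))
  }
  tom <- tom_similarity(adj)
  d <- 1 - tom
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  lab <- rep("background", nrow(adj))
  names(lab) <- genes

  good_branches <- function(cl) {
    kept <- list()
    for (cc in names(which(table(cl) >= min_module_size))) {
      idx <- which(cl == as.integer(cc))
      if (length(idx) == nrow(tom)) {
        between <- mean(tom[upper.tri(tom)])   # no outside genes
      } else {
        between <- mean(tom[idx, -idx, drop = FALSE])
      }
      sub <- tom[idx, idx]
      within <- mean(sub[upper.tri(sub)])
      if (within > quality_ratio * between) kept[[length(kept) + 1]] <- idx
    }
    kept
  }
  hts <- unique(stats::quantile(hc$height, probs = seq(0.02, 0.999,
                                                       length.out = n_heights),
                                names = FALSE))
  best <- list()
  best_score <- c(-1, -1, Inf)       # (#modules, #genes, -height preference)
  for (h in hts) {
    kept <- good_branches(stats::cutree(hc, h = h))
    score <- c(length(kept), sum(lengths(kept)), h)
    better <- score[1] > best_score[1] ||
      (score[1] == best_score[1] && score[2] > best_score[2]) ||
      (score[1] == best_score[1] && score[2] == best_score[2] &&
         score[3] < best_score[3])
    if (better) { best <- kept; best_score <- score }
  }
  kept <- best
  if (length(kept) == 0) {
    return(list(module_of = lab, eigengenes = NULL, tom = tom))
  }
  # merge close modules by eigengene correlation
  repeat {
    if (length(kept) < 2) break
    eg <- vapply(kept, function(idx) module_eigengene(vsd, genes[idx]),
                 numeric(ncol(vsd)))
    ec <- stats::cor(eg)
    diag(ec) <- -Inf
    mx <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (ec[mx[1], mx[2]] < 1 - merge_height) break
    kept[[mx[1]]] <- c(kept[[mx[1]]], kept[[mx[2]]])
    kept[[mx[2]]] <- NULL
  }
  # kME assignment stage (PAM-like): every network gene goes to the module
  # whose eigengene it correlates with most strongly (absolute correlation,
  # matching the unsigned network), provided |kME| >= kme_threshold; the
  # signed eigengene correlation disambiguates anti-correlated modules that
  # the unsigned adjacency cannot tell apart.
  egs <- vapply(kept, function(idx) module_eigengene(vsd, genes[idx]),
                numeric(ncol(vsd)))
  kme <- stats::cor(t(vsd), egs)
  bestm <- max.col(abs(kme), ties.method = "first")
  bestv <- abs(kme)[cbind(seq_len(nrow(kme)), bestm)]
  assign <- ifelse(bestv >= kme_threshold, bestm, NA_integer_)
  kept <- lapply(seq_along(kept), function(m) which(!is.na(assign) & assign == m))
  kept <- kept[lengths(kept) >= min_module_size]
  if (length(kept) == 0) {
    return(list(module_of = lab, eigengenes = NULL, tom = tom))
  }
  kept <- kept[order(lengths(kept), decreasing = TRUE)]
  for (m in seq_along(kept)) lab[kept[[m]]] <- sprintf("M%d", m)
  egs <- vapply(kept, function(idx) module_eigengene(vsd, genes[idx]),
                numeric(ncol(vsd)))
  colnames(egs) <- sprintf("M%d", seq_along(kept))
  rownames(egs) <- colnames(vsd)
  list(module_of = lab, eigengenes = egs, tom = tom)
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix, returned
#' per sample with unit norm. The sign is oriented so the eigengene
#' correlates positively with the module's mean standardized expression
#' profile, making the orientation deterministic.
#'
#' @param vsd expression matrix, genes x samples.
#' @param module_genes gene ids of the module (>= 2).
#' @return numeric vector, one value per sample, unit norm.
#' @export
module_eigengene <- function(vsd, module_genes) {
  stopifnot(length(module_genes) >= 2, ncol(vsd) >= 2)
  sub <- vsd[module_genes, , drop = FALSE]
  z <- t(scale(t(sub)))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  mref <- colMeans(z)
  if (sum(eg * mref) < 0) eg <- -eg
  stats::setNames(eg, colnames(vsd))
}

#' Intramodular connectivity
#'
#' Per gene, the raw connectivity is the sum of adjacency weights to its
#' module co-members (self excluded); the normalized connectivity maps each
#' module's range to `[0, 1]` (maximum -> 1, minimum -> 0). When all raw
#' connectivities in a module are equal the normalized value is 0 by
#' convention. Background and single-gene-module genes are excluded.
#'
#' @param adj adjacency matrix.
#' @param module_of named character vector mapping gene to module label.
#' @return data.frame: gene, module, k_raw, k_norm.
#' @export
module_connectivity <- function(adj, module_of) {
  genes <- rownames(adj)
  if (!all(genes %in% names(module_of)))
    stop("module assignment does not cover all adjacency genes")
  mods <- setdiff(unique(module_of[genes]), "background")
  out <- list()
  for (m in mods) {
    mg <- genes[module_of[genes] == m]
    if (length(mg) < 2) next
    sub <- adj[mg, mg, drop = FALSE]
    k <- rowSums(sub) - diag(sub)
    rng <- max(k) - min(k)
    kn <- if (rng < sqrt(.Machine$double.eps)) rep(0, length(k))
          else (k - min(k)) / rng
    out[[m]] <- data.frame(gene = mg, module = m, k_raw = unname(k),
                           k_norm = unname(kn), stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(gene = character(), module = character(),
                      k_raw = numeric(), k_norm = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a cohort co-expression network end to end
#'
#' Correlation -> soft-threshold adjacency -> module detection ->
#' connectivity, on a chosen gene set (typically the DEG union).
#'
#' @param vsd expression matrix, genes x samples.
#' @param genes gene subset entering the network.
#' @param beta soft-threshold power.
#' @param ... passed to [detect_modules()].
#' @return list: `module_of`, `eigengenes`, `connectivity`, `adjacency`,
#'   `scale_free_r2`.
#' @export
build_network <- function(vsd, genes, beta = 6, ...) {
  cm <- correlation_matrix(vsd, genes)
  adj <- adjacency_matrix(cm, beta)
  det <- detect_modules(adj, vsd[rownames(adj), , drop = FALSE], ...)
  conn <- module_connectivity(adj, det$module_of)
  r2 <- if (nrow(adj) >= 20) scale_free_fit(adj) else NA_real_
  list(module_of = det$module_of, eigengenes = det$eigengenes,
       connectivity = conn, adjacency = adj, scale_free_r2 = r2)
}
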