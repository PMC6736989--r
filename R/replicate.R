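#' Cross-cohort module overlap table with Fisher exact p-values
#'
#' For every pair of non-background modules from the two cohorts, counts the
#' shared genes over a common universe and computes the one-sided
#' (enrichment) Fisher exact p-value from the 2x2 table
#' (in-A / not-in-A x in-B / not-in-B), i.e. the upper hypergeometric tail
#' `P(overlap >= observed)`. Only overlap EXCESS is meaningful here, hence
#' one-sided.
#'
#' @param assign_a,assign_b named character vectors gene -> module label
#'   (`"background"` allowed) for the two cohorts.
#' @param universe gene universe; default the intersection of the two
#'   assignments' gene sets. Assignments are restricted to it.
#' @return data.frame: module_a, module_b, n_a, n_b, overlap, p_value,
#'   universe (N).
#' @export
module_overlap <- function(assign_a, assign_b, universe = NULL) {
  if (is.null(universe))
    universe <- intersect(names(assign_a), names(assign_b))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  a <- assign_a[intersect(names(assign_a), universe)]
  b <- assign_b[intersect(names(assign_b), universe)]
  mods_a <- setdiff(unique(a), "background")
  mods_b <- setdiff(unique(b), "background")
  N <- length(universe)
  rows <- list()
  for (ma in mods_a) {
    ga <- names(a)[a == ma]
    for (mb in mods_b) {
      gb <- names(b)[b == mb]
      ov <- length(intersect(ga, gb))
      p <- stats::phyper(ov - 1, length(ga), N - length(ga), length(gb),
                         lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module_a = ma, module_b = mb, n_a = length(ga), n_b = length(gb),
        overlap = ov, p_value = p, universe = N, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(module_a = character(), module_b = character(),
                      n_a = integer(), n_b = integer(), overlap = integer(),
                      p_value = numeric(), universe = integer()))
  do.call(rbind, rows)
}

#' Extract replicated cross-cohort gene signatures
#'
#' Module pairs whose overlap p-value is below `p_threshold` are linked;
#' connected components of that bipartite link graph form one signature each
#' (so two discovery modules mapping onto one replication module merge into
#' a single signature). A signature's members are the union of the pairwise
#' module intersections, restricted to genes called differentially expressed
#' in BOTH cohorts; each member's direction is the sign of its fold change
#' when the two cohorts agree (`"discordant"` otherwise).
#'
#' @param overlap data.frame from [module_overlap()].
#' @param assign_a,assign_b module assignments (named vectors).
#' @param degs_a,degs_b DE tables (data.frames with gene, log2_fold_change,
#'   p_value — typically the pSS-vs-HC Wald table) or plain character vectors
#'   of replicated DEG ids.
#' @param p_threshold overlap significance cutoff (default 1e-20).
#' @param alpha DEG threshold used when `degs_*` are DE tables.
#' @return list of signatures; each has `label`, `members`, `direction`
#'   (named per-member: "up"/"down"/"discordant"), `modules_a`, `modules_b`,
#'   `overall_direction`.
#' @export
replicated_signatures <- function(overlap, assign_a, assign_b,
                                  degs_a, degs_b, p_threshold = 1e-20,
                                  alpha = 0.05) {
  sig_pairs <- overlap[overlap$p_value < p_threshold, , drop = FALSE]
  if (nrow(sig_pairs) == 0) return(list())
  deg_set <- function(d) {
    if (is.character(d)) d else call_degs(d, alpha)
  }
  fc_of <- function(d) {
    if (is.character(d)) return(NULL)
    if (is.list(d) && !is.data.frame(d)) d <- do.call(rbind, d)
    stats::setNames(d$log2_fold_change, d$gene)
  }
  set_a <- deg_set(if (is.list(degs_a) && !is.data.frame(degs_a))
    do.call(rbind, degs_a) else degs_a)
  set_b <- deg_set(if (is.list(degs_b) && !is.data.frame(degs_b))
    do.call(rbind, degs_b) else degs_b)
  fca <- fc_of(degs_a)
  fcb <- fc_of(degs_b)
  replicated <- intersect(set_a, set_b)

  # connected components over the bipartite module-pair graph
  nodes <- unique(c(paste0("A:", sig_pairs$module_a),
                    paste0("B:", sig_pairs$module_b)))
  comp <- stats::setNames(seq_along(nodes), nodes)
  for (i in seq_len(nrow(sig_pairs))) {
    na <- paste0("A:", sig_pairs$module_a[i])
    nb <- paste0("B:", sig_pairs$module_b[i])
    old <- comp[nb]
    comp[comp == old] <- comp[na]
  }
  sigs <- list()
  for (cid in unique(comp)) {
    members_nodes <- names(comp)[comp == cid]
    ma <- sub("^A:", "", grep("^A:", members_nodes, value = TRUE))
    mb <- sub("^B:", "", grep("^B:", members_nodes, value = TRUE))
    pr <- sig_pairs[sig_pairs$module_a %in% ma & sig_pairs$module_b %in% mb, ]
    mem <- character()
    for (i in seq_len(nrow(pr))) {
      ga <- names(assign_a)[assign_a == pr$module_a[i]]
      gb <- names(assign_b)[assign_b == pr$module_b[i]]
      mem <- union(mem, intersect(ga, gb))
    }
    mem <- sort(intersect(mem, replicated))
    dirn <- NULL
    overall <- NA_character_
    if (!is.null(fca) && !is.null(fcb) && length(mem) > 0) {
      sa <- sign(fca[mem])
      sb <- sign(fcb[mem])
      dirn <- ifelse(is.na(sa) | is.na(sb) | sa != sb | sa == 0, "discordant",
                     ifelse(sa > 0, "up", "down"))
      names(dirn) <- mem
      tab <- table(factor(dirn, levels = c("up", "down")))
      overall <- names(tab)[which.max(tab)]
    }
    sigs[[length(sigs) + 1]] <- list(
      label = paste0(paste(ma, collapse = "+"), ":", paste(mb, collapse = "+")),
      members = mem, direction = dirn, modules_a = ma, modules_b = mb,
      overall_direction = overall)
  }
  names(sigs) <- vapply(sigs, `[[`, character(1), "label")
  sigs[order(vapply(sigs, function(s) length(s$members), integer(1)),
             decreasing = TRUE)]
}

#' Hub genes of a replicated signature
#'
#' Genes whose normalized intramodular connectivity STRICTLY exceeds the
#' signature-wise 75th percentile (linear-interpolation sample quantile) in
#' BOTH cohorts. The percentile is computed over the signature's members,
#' within each cohort separately.
#'
#' @param conn_a,conn_b connectivity data.frames from
#'   [module_connectivity()] for the two cohorts.
#' @param signature_genes character vector of signature members.
#' @param percentile percentile cutoff (default 75).
#' @return character vector of hub gene ids (possibly empty).
#' @export
hub_genes <- function(conn_a, conn_b, signature_genes, percentile = 75) {
  ka <- stats::setNames(conn_a$k_norm, conn_a$gene)[signature_genes]
  kb <- stats::setNames(conn_b$k_norm, conn_b$gene)[signature_genes]
  ok <- !is.na(ka) & !is.na(kb)
  if (length(signature_genes) < 4 || sum(ok) < 4) {
    warning("signature has fewer than 4 genes with connectivity in both cohorts; no hubs called")
    return(character())
  }
  ka <- ka[ok]; kb <- kb[ok]
  qa <- stats::quantile(ka, percentile / 100, type = 7, names = FALSE)
  qb <- stats::quantile(kb, percentile / 100, type = 7, names = FALSE)
  names(ka)[ka > qa & kb > qb]
}

#' Directionality concordance of shared differentially expressed genes
#'
#' Over the genes significant in both DE tables, the fraction whose fold
#' changes have the same sign; genes with a zero fold change are excluded.
#'
#' @param degs_a,degs_b DE tables (gene, log2_fold_change, p_value).
#' @param alpha significance threshold for inclusion (default 0.05).
#' @return list: `n` shared DEGs considered, `fraction_same_sign` (NA when
#'   `n == 0`), `comparison`.
#' @export
directionality_concordance <- function(degs_a, degs_b, alpha = 0.05) {
  sig_a <- degs_a[!is.na(degs_a$p_value) & degs_a$p_value < alpha, ]
  sig_b <- degs_b[!is.na(degs_b$p_value) & degs_b$p_value < alpha, ]
  shared <- intersect(sig_a$gene, sig_b$gene)
  fa <- stats::setNames(sig_a$log2_fold_change, sig_a$gene)[shared]
  fb <- stats::setNames(sig_b$log2_fold_change, sig_b$gene)[shared]
  keep <- !is.na(fa) & !is.na(fb) & fa != 0 & fb != 0
  n <- sum(keep)
  frac <- if (n == 0) NA_real_ else mean(sign(fa[keep]) == sign(fb[keep]))
  cmp <- unique(c(degs_a$comparison, degs_b$comparison))
  list(n = n, fraction_same_sign = frac,
       comparison = paste(cmp, collapse = " / "))
}
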