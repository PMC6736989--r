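#' Simulation configuration for the two-cohort generator
#'
#' Builds the configuration object consumed by [simulate_cohort()] and
#' [simulate_study()]. Defaults mirror the emulated study design: two
#' independent cohorts of 31 donors in three groups (healthy controls `HC`,
#' non-Sjogren sicca `nSS`, primary Sjogren `pSS`), four planted co-expression
#' modules of 50-150 genes among 3,000, group effects largest in `pSS` with
#' `nSS` at half the `pSS` effect, a one-dimensional batch factor, and
#' log-normal library sizes.
#'
#' Counts are drawn from a negative binomial with
#' `mean = libsize * 2^(baseline + loading * factor + group_effect + batch)`
#' and gene-wise dispersion `alpha` (`variance = mu + alpha * mu^2`). Each
#' planted module is driven by one standard-normal latent factor per sample;
#' group effects shift that factor's mean, so a gene's log2 effect is its
#' loading times the factor shift.
#'
#' @param n_genes total number of genes.
#' @param module_sizes integer vector, one planted module per entry; must sum
#'   to at most `n_genes`.
#' @param n_per_group named integer vector of samples per group
#'   (names `HC`, `nSS`, `pSS`).
#' @param pss_shift numeric vector (recycled over modules): shift of the module
#'   latent factor in `pSS` relative to `HC`, log2-factor scale. Signs
#'   alternate by default so both up- and down-regulated modules are planted.
#' @param nss_fraction `nSS` shift as a fraction of the `pSS` shift
#'   (default 0.5: the intermediate phenotype).
#' @param loading_range range of per-gene factor loadings (uniform).
#' @param baseline_log2_range range of per-gene baseline log2 mean expression.
#' @param dispersion_a0,dispersion_a1 gene dispersion `alpha = a0 + a1 / mu`
#'   evaluated at the gene's baseline mean; set both to 0 for Poisson counts.
#' @param batch_strength standard deviation of per-gene batch coefficients;
#'   the batch factor itself is standard normal per sample. 0 disables batch.
#' @param libsize_lognormal_sigma sigma of the log-normal library-size factor.
#' @param seed integer seed; every random draw in the generator flows from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 3000,
                       module_sizes = c(150, 120, 80, 50),
                       n_per_group = c(HC = 8L, nSS = 9L, pSS = 14L),
                       pss_shift = c(2, -2, 2, -2),
                       nss_fraction = 0.5,
                       loading_range = c(0.5, 0.9),
                       baseline_log2_range = c(3, 9),
                       dispersion_a0 = 0.05,
                       dispersion_a1 = 2,
                       batch_strength = 0.5,
                       libsize_lognormal_sigma = 0.3,
                       seed = 1L) {
  stopifnot(n_genes >= 1, all(module_sizes >= 1),
            dispersion_a0 >= 0, dispersion_a1 >= 0,
            batch_strength >= 0, libsize_lognormal_sigma >= 0,
            all(n_per_group >= 1))
  if (sum(module_sizes) > n_genes)
    stop("module_sizes sum (", sum(module_sizes),
         ") exceeds n_genes (", n_genes, ")")
  if (is.null(names(n_per_group)) || !setequal(names(n_per_group), c("HC", "nSS", "pSS")))
    stop("n_per_group must be named with HC, nSS, pSS")
  pss_shift <- rep_len(pss_shift, length(module_sizes))
  structure(list(
    n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    n_per_group = as.integer(n_per_group[c("HC", "nSS", "pSS")]) |>
      stats::setNames(c("HC", "nSS", "pSS")),
    pss_shift = pss_shift,
    nss_fraction = nss_fraction,
    loading_range = loading_range,
    baseline_log2_range = baseline_log2_range,
    dispersion_a0 = dispersion_a0,
    dispersion_a1 = dispersion_a1,
    batch_strength = batch_strength,
    libsize_lognormal_sigma = libsize_lognormal_sigma,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate one synthetic cohort
#'
#' Draws a gene-by-sample count matrix plus its sample sheet and the planted
#' ground truth. Deterministic: the same `config` and `cohort` always produce
#' the same output (the cohort label is folded into the seed stream so the two
#' cohorts of a study are independent draws of the same design).
#'
#' Gene-level structure (baselines, loadings, module membership, dispersions,
#' batch coefficients) is drawn from `config$seed` only, so it is SHARED across
#' cohorts — this is what makes modules and effects replicable, matching a
#' design where the same biology is assayed in two donor sets.
#'
#' @param config a [sim_config()] object.
#' @param cohort cohort label, e.g. `"discovery"` or `"replication"`.
#' @return list with `counts` (integer matrix, genes x samples), `samples`
#'   (data.frame: sample_id, group, cohort), `truth` (list: `module_of`,
#'   `loading_of`, `de_genes` with signed log2 effects for pSS vs HC,
#'   `batch_values`, `group_of`, `cohort_of`, `factor_scores`).
#' @export
simulate_cohort <- function(config, cohort = "discovery") {
  stopifnot(inherits(config, "sim_config"))
  gene_str <- gene_structure(config)
  n_s <- sum(config$n_per_group)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  sample_ids <- sprintf("%s_S%02d", substr(cohort, 1, 3), seq_len(n_s))

  # cohort-specific stream: offset keeps the two cohorts independent but
  # reproducible under one root seed
  set.seed(config$seed + 1000L * cohort_offset(cohort))
  n_mod <- length(config$module_sizes)

  shift_pss <- config$pss_shift
  shift_of <- cbind(HC = rep(0, n_mod),
                    nSS = shift_pss * config$nss_fraction,
                    pSS = shift_pss)
  # latent factor per module x sample: N(group shift, 1)
  fac <- matrix(stats::rnorm(n_mod * n_s), n_mod, n_s)
  for (m in seq_len(n_mod)) fac[m, ] <- fac[m, ] + shift_of[m, groups]

  batch <- stats::rnorm(n_s)
  libsize <- stats::rlnorm(n_s, meanlog = 0, sdlog = config$libsize_lognormal_sigma)

  log2mu <- matrix(gene_str$baseline, config$n_genes, n_s)
  in_mod <- gene_str$module_of != "background"
  if (any(in_mod)) {
    midx <- match(gene_str$module_of[in_mod], gene_str$module_labels)
    log2mu[in_mod, ] <- log2mu[in_mod, ] +
      gene_str$loading[in_mod] * fac[midx, , drop = FALSE]
  }
  if (config$batch_strength > 0)
    log2mu <- log2mu + outer(gene_str$batch_coef, batch)
  mu <- sweep(2^log2mu, 2, libsize, `*`)

  counts <- matrix(0L, config$n_genes, n_s,
                   dimnames = list(gene_str$gene_ids, sample_ids))
  alpha <- gene_str$alpha
  for (g in seq_len(config$n_genes)) {
    counts[g, ] <- if (alpha[g] > 0)
      stats::rnbinom(n_s, size = 1 / alpha[g], mu = mu[g, ])
    else stats::rpois(n_s, mu[g, ])
  }
  storage.mode(counts) <- "integer"

  samples <- data.frame(sample_id = sample_ids, group = groups,
                        cohort = cohort, stringsAsFactors = FALSE)
  de_effect <- gene_str$loading * shift_of[, "pSS"][match(gene_str$module_of,
                                                          gene_str$module_labels)]
  de_effect[!in_mod] <- 0
  truth <- list(
    module_of = stats::setNames(gene_str$module_of, gene_str$gene_ids),
    loading_of = stats::setNames(gene_str$loading, gene_str$gene_ids),
    de_genes = stats::setNames(de_effect[in_mod], gene_str$gene_ids[in_mod]),
    batch_values = stats::setNames(batch, sample_ids),
    group_of = stats::setNames(groups, sample_ids),
    cohort_of = stats::setNames(rep(cohort, n_s), sample_ids),
    factor_scores = fac
  )
  list(counts = counts, samples = samples, truth = truth)
}

#' Generate a full two-cohort study
#'
#' @param config a [sim_config()] object (shared gene structure across cohorts).
#' @param n_per_group_replication optional named vector overriding the
#'   replication cohort's group sizes (default `c(HC=9, nSS=11, pSS=11)` when
#'   `config` uses the default discovery sizes, else same as discovery).
#' @return list with `discovery` and `replication`, each as in
#'   [simulate_cohort()].
#' @export
simulate_study <- function(config = sim_config(),
                           n_per_group_replication = NULL) {
  disc <- simulate_cohort(config, "discovery")
  conf2 <- config
  if (is.null(n_per_group_replication)) {
    if (identical(unname(config$n_per_group), c(8L, 9L, 14L)))
      n_per_group_replication <- c(HC = 9L, nSS = 11L, pSS = 11L)
    else n_per_group_replication <- config$n_per_group
  }
  conf2$n_per_group <- stats::setNames(
    as.integer(n_per_group_replication[c("HC", "nSS", "pSS")]),
    c("HC", "nSS", "pSS"))
  repl <- simulate_cohort(conf2, "replication")
  list(discovery = disc, replication = repl)
}

# gene-level structure drawn from the root seed only (shared across cohorts)
gene_structure <- function(config) {
  set.seed(config$seed)
  n_g <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n_g))
  module_labels <- sprintf("M%d", seq_along(config$module_sizes))
  module_of <- rep("background", n_g)
  idx <- 1L
  for (m in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[m]
    module_of[idx:(idx + sz - 1L)] <- module_labels[m]
    idx <- idx + sz
  }
  loading <- ifelse(module_of == "background", 0,
                    stats::runif(n_g, config$loading_range[1], config$loading_range[2]))
  baseline <- stats::runif(n_g, config$baseline_log2_range[1],
                           config$baseline_log2_range[2])
  alpha <- config$dispersion_a0 + config$dispersion_a1 / (2^baseline)
  batch_coef <- if (config$batch_strength > 0)
    stats::rnorm(n_g, 0, config$batch_strength) else rep(0, n_g)
  list(gene_ids = gene_ids, module_labels = module_labels,
       module_of = module_of, loading = loading, baseline = baseline,
       alpha = alpha, batch_coef = batch_coef)
}

cohort_offset <- function(cohort) {
  # stable small integer per label; keeps derived seeds well below 2^31
  (sum(utf8ToInt(cohort) * seq_along(utf8ToInt(cohort))) %% 1000L) + 1L
}

#' Generate a synthetic qPCR Ct table for the IFN-score
#'
#' Produces Ct values for the five interferon-induced target genes
#' (IFI44L, IFI44, IFIT3, LY6E, MX1) and two housekeeping genes
#' (GAPDH, GUSB) for healthy controls and patients. Patients' per-gene
#' delta-Ct is shifted by `shift_per_gene` (delta-Ct units; a NEGATIVE shift
#' means fewer cycles, i.e. HIGHER expression, fold change `2^-shift`).
#'
#' @param n_hc,n_patient sample counts.
#' @param shift_per_gene numeric scalar or length-5 vector of patient
#'   delta-Ct shifts for the five IFN genes.
#' @param ct_sd technical noise SD on each Ct measurement (cycles).
#' @param seed integer seed.
#' @return data.frame with columns sample, gene, Ct, role, group.
#' @export
simulate_qpcr <- function(n_hc = 10, n_patient = 10, shift_per_gene = -2,
                          ct_sd = 0.4, seed = 1L) {
  ifn <- c("IFI44L", "IFI44", "IFIT3", "LY6E", "MX1")
  hk <- c("GAPDH", "GUSB")
  shift <- rep_len(shift_per_gene, length(ifn))
  set.seed(seed)
  base_ct <- stats::setNames(stats::runif(length(ifn), 24, 28), ifn)
  hk_ct <- stats::setNames(c(19, 21), hk)
  samples <- c(sprintf("HC%02d", seq_len(n_hc)),
               sprintf("PT%02d", seq_len(n_patient)))
  grp <- rep(c("HC", "patient"), c(n_hc, n_patient))
  rows <- list()
  for (i in seq_along(samples)) {
    # sample-wide offset (input amount); cancels in delta-Ct
    off <- stats::rnorm(1, 0, 0.5)
    tg_shift <- if (grp[i] == "patient") shift else rep(0, length(ifn))
    rows[[i]] <- data.frame(
      sample = samples[i],
      gene = c(ifn, hk),
      Ct = c(base_ct + tg_shift, hk_ct) + off +
        stats::rnorm(length(ifn) + length(hk), 0, ct_sd),
      role = c(rep("target", length(ifn)), rep("housekeeping", length(hk))),
      group = grp[i],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
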