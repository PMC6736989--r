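#' Run the full two-cohort discovery/replication pipeline
#'
#' Orchestrates, per cohort: size factors, removal of one unwanted-variation
#' factor, variance-stabilizing transformation, negative-binomial
#' differential expression (pairwise Wald tests plus multi-group LRT, with
#' the estimated unwanted factor as covariate), and the co-expression network
#' on the DEG union. Across cohorts: Fisher-exact module overlap, replicated
#' signature extraction, hub genes and directionality concordance. Optionally
#' directional GSEA of the discovery pSS-vs-HC profile against supplied gene
#' sets, and the pSS-vs-HC classifier with confidence-based stratification of
#' the nSS group (fitted on the jointly corrected cohorts).
#'
#' @param cohorts named list with `discovery` and `replication`, each a list
#'   holding `counts` (matrix) and `samples` (sample sheet) — the shape
#'   returned by [simulate_study()].
#' @param gene_sets optional named list of gene sets for the GSEA stage.
#' @param out_dir optional directory; when given, stage outputs (TSV/CSV/
#'   GMT/JSON) and a run manifest with file hashes are written there.
#' @param seed root integer seed; every stochastic stage derives its stream
#'   from it.
#' @param ruv_k unwanted-variation factors to remove (default 1).
#' @param alpha nominal DEG threshold (default 0.05).
#' @param beta soft-threshold power (default 6).
#' @param min_module_size minimum module size (default 30).
#' @param p_threshold module-overlap replication cutoff (default 1e-20).
#' @param hub_percentile hub connectivity percentile (default 75).
#' @param n_perm GSEA permutations (default 10000).
#' @param cv_folds classifier cross-validation folds (default 10).
#' @param confidence_threshold stratification cutoff (default 0.75).
#' @param select optional backward feature selection before the classifier
#'   (default FALSE: uses signature genes directly).
#' @return list with per-stage results (`normalize`, `de`, `network`,
#'   `overlap`, `signatures`, `hubs`, `concordance`, `gsea`, `stratify`) and
#'   a `manifest`.
#' @export
run_pipeline <- function(cohorts, gene_sets = NULL, out_dir = NULL,
                         seed = 1L, ruv_k = 1, alpha = 0.05, beta = 6,
                         min_module_size = 30, p_threshold = 1e-20,
                         hub_percentile = 75, n_perm = 10000,
                         cv_folds = 10, confidence_threshold = 0.75,
                         select = FALSE) {
  stopifnot(all(c("discovery", "replication") %in% names(cohorts)))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stages <- character()
  norm <- de <- net <- list()
  for (nm in c("discovery", "replication")) {
    counts <- filter_zero_genes(validate_counts(cohorts[[nm]]$counts))
    samples <- cohorts[[nm]]$samples
    ruv <- remove_unwanted_variation(counts, samples, k = ruv_k)
    # the network and classifier stages see batch-corrected expression
    vsd <- vst_transform(ruv$corrected, ruv$size_factors)
    norm[[nm]] <- list(sf = ruv$size_factors, factors = ruv$factors, vsd = vsd)
    de[[nm]] <- run_de(counts, samples, sf = ruv$size_factors,
                       covariates = ruv$factors, alpha = alpha)
    net[[nm]] <- build_network(vsd, de[[nm]]$degs, beta = beta,
                               min_module_size = min_module_size)
  }
  stages <- c(stages, "normalize", "diffexp", "coexnet")

  universe <- intersect(de$discovery$degs, de$replication$degs)
  overlap <- module_overlap(net$discovery$module_of,
                            net$replication$module_of, universe)
  wald_disc <- de$discovery$tables[["pSS_vs_HC"]]
  wald_repl <- de$replication$tables[["pSS_vs_HC"]]
  sigs <- replicated_signatures(overlap, net$discovery$module_of,
                                net$replication$module_of,
                                de$discovery$tables, de$replication$tables,
                                p_threshold = p_threshold, alpha = alpha)
  # per-gene directions from the pSS-vs-HC contrast for reporting
  hubs <- lapply(sigs, function(s)
    tryCatch(hub_genes(net$discovery$connectivity, net$replication$connectivity,
                       s$members, percentile = hub_percentile),
             warning = function(w) character()))
  concord <- directionality_concordance(wald_disc, wald_repl, alpha = alpha)
  stages <- c(stages, "replicate")

  gsea_res <- NULL
  if (!is.null(gene_sets)) {
    gsea_res <- gsea_directional(wald_disc, gene_sets, n_perm = n_perm,
                                 seed = seed + 7L)
    stages <- c(stages, "gsea")
  }

  strat <- NULL
  sig_genes <- unique(unlist(lapply(sigs, `[[`, "members")))
  if (length(sig_genes) >= 2) {
    joint_counts <- joint_count_matrix(cohorts)
    joint_samples <- rbind(cohorts$discovery$samples,
                           cohorts$replication$samples)
    ruv_j <- remove_unwanted_variation(joint_counts, joint_samples, k = ruv_k)
    vsd_j <- vst_transform(ruv_j$corrected, ruv_j$size_factors)
    is_tr <- joint_samples$group %in% c("pSS", "HC")
    labels <- stats::setNames(joint_samples$group[is_tr],
                              joint_samples$sample_id[is_tr])
    feats <- sig_genes[sig_genes %in% rownames(vsd_j)]
    if (select && length(feats) > 2) {
      sel <- select_features(vsd_j[, names(labels), drop = FALSE],
                             as.character(labels), feats,
                             folds = cv_folds, seed = seed + 11L)
      feats <- sel$features
    }
    cv <- fit_predict_cv(vsd_j[, names(labels), drop = FALSE],
                         as.character(labels), feats,
                         folds = cv_folds, seed = seed + 13L)
    nss <- joint_samples$sample_id[joint_samples$group == "nSS"]
    cls <- classify_intermediate(vsd_j, labels, nss, feats,
                                 threshold = confidence_threshold)
    strat <- list(features = feats, cv = cv, stratification = cls)
    stages <- c(stages, "stratify")
  }

  manifest <- list(seed = seed,
                   parameters = list(ruv_k = ruv_k, alpha = alpha, beta = beta,
                                     min_module_size = min_module_size,
                                     p_threshold = p_threshold,
                                     hub_percentile = hub_percentile,
                                     n_perm = n_perm, cv_folds = cv_folds,
                                     confidence_threshold = confidence_threshold),
                   stages = stages,
                   n_signatures = length(sigs))
  res <- list(normalize = norm, de = de, network = net, overlap = overlap,
              signatures = sigs, hubs = hubs, concordance = concord,
              gsea = gsea_res, stratify = strat, manifest = manifest)
  if (!is.null(out_dir)) res$manifest <- write_pipeline_outputs(res, out_dir)
  res
}

joint_count_matrix <- function(cohorts) {
  shared <- intersect(rownames(cohorts$discovery$counts),
                      rownames(cohorts$replication$counts))
  cbind(cohorts$discovery$counts[shared, , drop = FALSE],
        cohorts$replication$counts[shared, , drop = FALSE])
}

write_pipeline_outputs <- function(res, out_dir) {
  paths <- character()
  for (nm in c("discovery", "replication")) {
    p <- file.path(out_dir, paste0(nm, "_vsd.tsv"))
    utils::write.table(
      data.frame(gene = rownames(res$normalize[[nm]]$vsd),
                 res$normalize[[nm]]$vsd, check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    for (cmp in names(res$de[[nm]]$tables)) {
      p <- file.path(out_dir, paste0(nm, "_de_", cmp, ".tsv"))
      utils::write.table(res$de[[nm]]$tables[[cmp]], p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    p <- file.path(out_dir, paste0(nm, "_modules.tsv"))
    utils::write.table(
      data.frame(gene = names(res$network[[nm]]$module_of),
                 module = unname(res$network[[nm]]$module_of)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, paste0(nm, "_connectivity.tsv"))
    utils::write.table(res$network[[nm]]$connectivity, p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "module_overlap.tsv")
  utils::write.table(res$overlap, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  if (length(res$signatures) > 0) {
    sets <- lapply(res$signatures, `[[`, "members")
    p <- file.path(out_dir, "signatures.gmt")
    write_gmt(sets, p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "concordance.json")
  jsonlite::write_json(res$concordance, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  manifest <- res$manifest
  manifest$files <- as.list(tools::md5sum(paths))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

#' Command-line interface
#'
#' Thin dispatcher used by the `inst/cli/modrep.R` script; exposed as a
#' function so the CLI surface is testable in-process. Subcommands:
#' `simulate` (write a synthetic study), `run-all` (simulate or load, then
#' run the pipeline), `version`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
modrep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: modrep <simulate|run-all|version> [--seed N] [--out DIR]",
    "  simulate: write counts TSV + sample CSV + truth JSON per cohort",
    "  run-all : simulate (or --counts-a/--samples-a/--counts-b/--samples-b)",
    "            then run the full pipeline into --out", sep = "\n")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(opt[["seed"]] %||% 1L)
  out <- opt[["out"]] %||% "modrep_out"
  if (cmd == "version") {
    cat("modrep", as.character(utils::packageVersion("modrep")), "\n")
    return(invisible(0L))
  }
  if (cmd == "simulate") {
    study <- simulate_study(sim_config(seed = seed))
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    for (nm in names(study)) {
      write_counts(study[[nm]]$counts, file.path(out, paste0(nm, "_counts.tsv")))
      write_sample_sheet(study[[nm]]$samples,
                         file.path(out, paste0(nm, "_samples.csv")))
      tr <- study[[nm]]$truth
      tr$factor_scores <- NULL
      jsonlite::write_json(tr, file.path(out, paste0(nm, "_truth.json")),
                           auto_unbox = FALSE, digits = NA)
    }
    return(invisible(0L))
  }
  if (cmd == "run-all") {
    if (!is.null(opt[["counts-a"]])) {
      cohorts <- list(
        discovery = list(counts = read_counts(opt[["counts-a"]]),
                         samples = read_sample_sheet(opt[["samples-a"]])),
        replication = list(counts = read_counts(opt[["counts-b"]]),
                           samples = read_sample_sheet(opt[["samples-b"]])))
    } else {
      cohorts <- simulate_study(sim_config(seed = seed))
    }
    res <- run_pipeline(cohorts, out_dir = out, seed = seed)
    cat("completed stages:", paste(res$manifest$stages, collapse = ", "), "\n")
    return(invisible(0L))
  }
  message("unknown subcommand: ", cmd, "\n", usage)
  invisible(1L)
}

parse_cli_args <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opt[[key]] <- args[i + 1]
        i <- i + 2
      } else {
        opt[[key]] <- TRUE
        i <- i + 1
      }
    } else i <- i + 1
  }
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
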