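# End-to-end orchestration: simulate (or load) -> batch-correct -> cluster
# the checkpoint panel -> enrichment scores -> signature genes + ICscore +
# cutpoint -> survival tables -> mutation/CNV summaries, with one global
# seed fanned out to fixed per-stage substreams and a tabular report
# bundle written to disk.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Exactly one of `simulate` (a [sim_config()]) or `paths` (named list
#' with `expression`, `clinical`, and optionally `maf`, `cnv`, `gmt`)
#' must be supplied.
#'
#' @param simulate optional [sim_config()] describing a synthetic cohort.
#' @param paths optional named list of input file paths.
#' @param seed mandatory integer seed; every stochastic stage draws from a
#'   substream derived from it.
#' @param k_grid candidate cluster numbers for the checkpoint-panel pass.
#' @param force_k_patterns optional fixed k for the panel pass (grid
#'   selection skipped).
#' @param k_genes k for the signature-gene clustering pass (default 2).
#' @param n_resamples,item_fraction consensus-clustering settings.
#' @param ssgsea_alpha,ssgsea_normalize enrichment settings.
#' @param fdr DEG significance threshold (BH-adjusted).
#' @param minprop minimum group proportion for the cutpoint search.
#' @param ties Cox tie handling.
#' @param covariates extra clinical columns for the multivariable Cox
#'   model (the ICscore group is always included).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, seed,
                            k_grid = 2:6, force_k_patterns = NULL,
                            k_genes = 2L, n_resamples = 1000L,
                            item_fraction = 0.8, ssgsea_alpha = 0.25,
                            ssgsea_normalize = "minmax", fdr = 0.05,
                            minprop = 0.1, ties = "efron",
                            covariates = character()) {
  if (missing(seed)) abort_icp("seed is mandatory")
  if (is.null(simulate) == is.null(paths))
    abort_icp("supply exactly one of a simulate block or input paths")
  structure(list(simulate = simulate, paths = paths, seed = as.integer(seed),
                 k_grid = k_grid, force_k_patterns = force_k_patterns,
                 k_genes = k_genes, n_resamples = n_resamples,
                 item_fraction = item_fraction,
                 ssgsea_alpha = ssgsea_alpha,
                 ssgsea_normalize = ssgsea_normalize, fdr = fdr,
                 minprop = minprop, ties = ties, covariates = covariates),
            class = "pipeline_config")
}

#' Run the full immune-checkpoint pattern pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage's tables are
#'   written there as TSV plus a JSON run manifest.
#' @return list of class `report_bundle`: cohort data, pattern
#'   assignments and k-selection, enrichment scores (per set and
#'   ESTIMATE-style), DEG result, ICscore result with cutpoint and
#'   groups, survival tables, genomics tables, the per-sample crosswalk,
#'   and (for synthetic cohorts) recovery diagnostics against the planted
#'   truth.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    abort_icp("config must be a pipeline_config")
  seed <- config$seed

  ## -- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- stage_seed(seed, "simulate")
    cohort <- simulate_cohort(sim_cfg)
    expr <- cohort$expression
    clinical <- cohort$clinical
    maf <- cohort$maf
    cnv <- cohort$cnv
    gene_sets <- cohort$gene_sets
    truth <- cohort$truth
  } else {
    p <- config$paths
    expr <- read_expression_matrix(p$expression)
    clinical <- read_clinical(p$clinical)
    if (!is.null(clinical$batch))
      attr(expr, "batch") <- stats::setNames(
        clinical$batch, clinical$sample_id)[colnames(expr)]
    maf <- if (!is.null(p$maf)) read_maf(p$maf) else NULL
    cnv <- if (!is.null(p$cnv)) read_cnv(p$cnv) else NULL
    gene_sets <- if (!is.null(p$gmt)) read_gmt(p$gmt) else NULL
    truth <- NULL
  }
  ids <- colnames(expr)

  ## -- batch correction ---------------------------------------------------
  batch <- attr(expr, "batch")
  if (!is.null(batch) && length(unique(batch)) > 1L) {
    expr <- combat_adjust(expr)$corrected
  }

  ## -- checkpoint-panel pattern discovery ---------------------------------
  panel <- intersect(icg_genes(), rownames(expr))
  if (length(panel) < 2L) abort_icp("expression matrix lacks the ICG panel")
  panel_expr <- expr[panel, , drop = FALSE]
  kseed <- stage_seed(seed, "cluster_icg")
  if (is.null(config$force_k_patterns)) {
    grid_fits <- lapply(config$k_grid, function(k)
      consensus_cluster(panel_expr, k, config$n_resamples,
                        config$item_fraction, seed = kseed + k))
    ksel <- select_k(grid_fits)
    icg_fit <- grid_fits[[match(ksel$chosen_k, config$k_grid)]]
  } else {
    icg_fit <- consensus_cluster(panel_expr, config$force_k_patterns,
                                 config$n_resamples, config$item_fraction,
                                 seed = kseed + config$force_k_patterns)
    ksel <- NULL
  }
  pattern <- canonicalize_patterns(icg_fit$assignments, panel_expr)
  embedding <- pca_embed(panel_expr, d = 2L)

  ## -- immune enrichment --------------------------------------------------
  enrich <- estimate <- NULL
  if (!is.null(gene_sets)) {
    cell_sets <- gene_sets[setdiff(names(gene_sets),
                                   c("IMMUNE_SIGNATURE", "STROMAL_SIGNATURE"))]
    if (length(cell_sets))
      enrich <- ssgsea(expr, cell_sets, alpha = config$ssgsea_alpha,
                       normalize = config$ssgsea_normalize)
    if (all(c("IMMUNE_SIGNATURE", "STROMAL_SIGNATURE") %in% names(gene_sets)))
      estimate <- estimate_scores(expr,
                                  gene_sets[["STROMAL_SIGNATURE"]],
                                  gene_sets[["IMMUNE_SIGNATURE"]],
                                  alpha = config$ssgsea_alpha)
  }

  ## -- signature genes, geneCluster, ICscore, cutpoint --------------------
  degs <- cluster_degs(expr, pattern, fdr_threshold = config$fdr)
  sig_genes <- degs$intersection
  if (length(sig_genes) < 2L)
    abort_icp("signature stage: fewer than 2 intersection DEGs")
  gene_fit <- consensus_cluster(expr[sig_genes, , drop = FALSE],
                                config$k_genes, config$n_resamples,
                                config$item_fraction,
                                seed = stage_seed(seed, "cluster_genes"))
  gene_cluster <- canonicalize_patterns(gene_fit$assignments,
                                        expr[sig_genes, , drop = FALSE])
  ic <- derive_icscore(expr, sig_genes)
  cl_idx <- match(ids, clinical$sample_id)
  cut <- dichotomize_by_cutpoint(ic$score, clinical$os_time[cl_idx],
                                 clinical$os_event[cl_idx],
                                 minprop = config$minprop)

  ## -- survival -----------------------------------------------------------
  os_time <- clinical$os_time[cl_idx]; os_event <- clinical$os_event[cl_idx]
  km_by_group <- lapply(split(seq_along(ids), cut$groups), function(ix)
    km_estimate(os_time[ix], os_event[ix]))
  lr_groups <- logrank_test(os_time, os_event, cut$groups)
  lr_pattern <- logrank_test(os_time, os_event, pattern)
  surv5 <- vapply(km_by_group, km_survival_at, 0, t = 60)
  cox_data <- data.frame(os_time = os_time, os_event = os_event,
                         icscore_group = cut$groups,
                         clinical[cl_idx, setdiff(names(clinical),
                                                  c("sample_id", "os_time",
                                                    "os_event")),
                                  drop = FALSE])
  cox <- cox_fit(cox_data, c("icscore_group", config$covariates),
                 ties = config$ties)

  ## -- genomics -----------------------------------------------------------
  genomics <- NULL
  if (!is.null(maf)) {
    tmb <- compute_tmb(maf, ids)
    tmb_cor <- correlate(tmb$tmb, unname(ic$score[ids]), "spearman")
    mut_genes <- sort(unique(maf$Hugo_Symbol[
      maf$Variant_Classification %in% nonsyn_classes()]))
    freq_all <- mutation_frequency(maf, mut_genes, ids)
    by_group <- lapply(split(ids, cut$groups[ids]), function(s)
      mutation_frequency(maf, mut_genes, s))
    top <- utils::head(freq_all$gene[order(-freq_all$frequency)], 15L)
    cooc <- if (length(top) >= 2L)
      suppressMessages(cooccurrence(maf, top, ids)) else NULL
    genomics <- list(tmb = tmb, tmb_icscore_spearman = tmb_cor,
                     mutation_frequency = freq_all,
                     mutation_frequency_by_group = by_group,
                     cooccurrence = cooc,
                     cnv_frequency = if (!is.null(cnv)) cnv_frequency(cnv)
                                     else NULL)
  }

  ## -- crosswalk + recovery ----------------------------------------------
  crosswalk <- data.frame(
    sample_id = ids, icg_cluster = unname(pattern[ids]),
    gene_cluster = unname(gene_cluster[ids]),
    icscore = unname(ic$score[ids]),
    icscore_group = unname(cut$groups[ids]),
    os_time = os_time, os_event = os_event,
    stringsAsFactors = FALSE)

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- list(
      pattern_ari = adjusted_rand_index(truth$pattern[ids], pattern[ids]),
      chosen_k = if (!is.null(ksel)) ksel$chosen_k
                 else config$force_k_patterns,
      mean_icscore_by_true_pattern =
        tapply(ic$score[ids], truth$pattern[ids], mean))
  }

  bundle <- structure(list(
    config = config, seed = seed,
    expression = expr, clinical = clinical,
    pattern = pattern, k_selection = ksel, consensus = icg_fit,
    embedding = embedding, enrichment = enrich, estimate = estimate,
    degs = degs, signature_genes = sig_genes, gene_cluster = gene_cluster,
    icscore = ic, cutpoint = cut,
    survival = list(km_by_group = km_by_group, logrank_groups = lr_groups,
                    logrank_patterns = lr_pattern,
                    five_year_survival = surv5, cox = cox),
    genomics = genomics, crosswalk = crosswalk, recovery = recovery),
    class = "report_bundle")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle's tables to a directory
#'
#' Emits the per-sample crosswalk, pattern assignments, k-selection
#' statistics, enrichment and ESTIMATE-style scores, DEG/signature lists,
#' ICscore table, survival tables, genomics tables and a JSON run
#' manifest. Output is plain TSV/JSON and deterministic for a fixed
#' config and seed.
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    df
  }
  write_tsv(fmt(bundle$crosswalk), file.path(out_dir, "crosswalk.tsv"))
  if (!is.null(bundle$k_selection)) {
    ks <- bundle$k_selection
    write_tsv(data.frame(k = ks$k_grid, pac = signif(unname(ks$pac), 10),
                         area = signif(unname(ks$area), 10),
                         delta_area = signif(unname(ks$delta_area), 10)),
              file.path(out_dir, "kselect.tsv"))
  }
  if (!is.null(bundle$enrichment)) {
    sc <- data.frame(set = rownames(bundle$enrichment),
                     signif(bundle$enrichment, 10), check.names = FALSE)
    write_tsv(sc, file.path(out_dir, "enrichment_scores.tsv"))
  }
  if (!is.null(bundle$estimate))
    write_tsv(fmt(bundle$estimate), file.path(out_dir, "estimate.tsv"))
  writeLines(bundle$signature_genes,
             file.path(out_dir, "signature_genes.txt"))
  write_tsv(fmt(bundle$survival$cox$coef), file.path(out_dir, "cox.tsv"))
  lr <- bundle$survival$logrank_groups
  write_tsv(data.frame(contrast = c("icscore_group", "icg_cluster"),
                       statistic = signif(c(lr$statistic,
                                 bundle$survival$logrank_patterns$statistic), 10),
                       df = c(lr$df, bundle$survival$logrank_patterns$df),
                       p_value = signif(c(lr$p_value,
                                 bundle$survival$logrank_patterns$p_value), 10)),
            file.path(out_dir, "logrank.tsv"))
  if (!is.null(bundle$genomics)) {
    write_tsv(fmt(bundle$genomics$tmb), file.path(out_dir, "tmb.tsv"))
    write_tsv(fmt(bundle$genomics$mutation_frequency),
              file.path(out_dir, "mutfreq.tsv"))
    if (!is.null(bundle$genomics$cooccurrence))
      write_tsv(fmt(bundle$genomics$cooccurrence),
                file.path(out_dir, "cooccur.tsv"))
    if (!is.null(bundle$genomics$cnv_frequency))
      write_tsv(fmt(bundle$genomics$cnv_frequency),
                file.path(out_dir, "cnvfreq.tsv"))
  }
  manifest <- list(
    seed = bundle$seed,
    package_version = as.character(utils::packageVersion("icpattern")),
    n_samples = nrow(bundle$crosswalk),
    n_signature_genes = length(bundle$signature_genes),
    cutpoint = bundle$cutpoint$cutpoint,
    config = unclass(bundle$config))
  if (!is.null(manifest$config$simulate))
    manifest$config$simulate <- unclass(manifest$config$simulate)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
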