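# Synthetic multi-batch cohort generator. Emits linked expression /
# clinical / mutation / CNV / gene-set data with the statistical structure
# the downstream analysis assumes: three planted expression patterns over
# the 31-gene checkpoint panel driven by a latent "immune-hot" axis
# (pattern A hot, C cold, B intermediate), pattern-associated background
# DEGs, immune-cell gene sets whose true abundance tracks the axis,
# exponential survival with a protective immune axis, TMB positively
# correlated with the axis, and pattern-dependent clinical subtypes.

IMMUNE_CELL_TYPES <- c(
  "Activated_B_cell", "Activated_CD4_T_cell", "Activated_CD8_T_cell",
  "Central_memory_CD4_T_cell", "Central_memory_CD8_T_cell",
  "Effector_memory_CD4_T_cell", "Effector_memory_CD8_T_cell",
  "Gamma_delta_T_cell", "Immature_B_cell", "Memory_B_cell",
  "Regulatory_T_cell", "T_follicular_helper_cell", "Type_1_T_helper_cell",
  "Type_17_T_helper_cell", "Type_2_T_helper_cell",
  "Activated_dendritic_cell", "CD56bright_natural_killer_cell",
  "CD56dim_natural_killer_cell", "Eosinophil", "Immature_dendritic_cell",
  "Macrophage", "Mast_cell", "MDSC", "Monocyte", "Natural_killer_cell",
  "Natural_killer_T_cell", "Neutrophil", "Plasmacytoid_dendritic_cell")

#' Simulation configuration for a synthetic checkpoint cohort
#'
#' All defaults encode the study conditions the pipeline is exercised
#' under; the generator is a pure function of `(config, seed)`.
#'
#' @param n_per_pattern samples per planted pattern A/B/C.
#' @param n_batches number of batches; samples are assigned balanced
#'   across patterns.
#' @param batch_sd sd of the additive per-(gene,batch) location shift
#'   (log2 units).
#' @param batch_scale_sd sd of the per-(gene,batch) log scale factor
#'   multiplying residual noise.
#' @param n_background_genes background genes; the first
#'   `n_signature_genes` of them are truly pattern-associated.
#' @param n_signature_genes pattern-associated background genes.
#' @param signature_effect log2 shift per unit of latent axis for the
#'   pattern-associated background genes.
#' @param icg_effect log2 shift per unit of latent axis for the 31 panel
#'   genes (axis means are +1/0/-1 for A/B/C, so the A-vs-C mean gap is
#'   `2 * icg_effect`).
#' @param icg_reversed panel genes whose pattern effect is reversed
#'   (high in the cold pattern), mirroring the CD276/VTCN1 exception.
#' @param residual_sd residual noise sd (log2 units).
#' @param axis_sd within-pattern sd of the latent immune axis (pattern
#'   means are fixed at +1/0/-1).
#' @param n_immune_sets,immune_set_size immune-cell gene sets: count and
#'   genes per set.
#' @param n_neutral_sets of the immune sets, how many get a negligible or
#'   slightly negative axis effect (so "majority up in A" is a real
#'   majority, not unanimity).
#' @param hazard_lambda0 baseline exponential event rate per month.
#' @param hazard_beta log-hazard decrease per sd of the latent axis
#'   (positive = immune-hot protective).
#' @param censor_rate target marginal censoring fraction in \[0, 1).
#' @param tmb_mean baseline mean nonsynonymous mutation count per sample.
#' @param tmb_log_effect log-linear TMB increase per unit of latent axis.
#' @param n_mutation_genes size of the simulated mutation panel (three of
#'   which - ARID1A/PIK3CA/TP53 stand-ins - get pattern-dependent
#'   probabilities).
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_pattern = c(A = 80L, B = 80L, C = 80L),
                       n_batches = 3L,
                       batch_sd = 0.5,
                       batch_scale_sd = 0.15,
                       n_background_genes = 2000L,
                       n_signature_genes = 300L,
                       signature_effect = 0.8,
                       icg_effect = 1.5,
                       icg_reversed = c("CD276", "VTCN1"),
                       residual_sd = 1.0,
                       axis_sd = 0.5,
                       n_immune_sets = 28L,
                       immune_set_size = 30L,
                       n_neutral_sets = 4L,
                       hazard_lambda0 = 0.008,
                       hazard_beta = log(2),
                       censor_rate = 0.3,
                       tmb_mean = 8,
                       tmb_log_effect = 0.4,
                       n_mutation_genes = 100L,
                       seed = 1L) {
  cfg <- list(n_per_pattern = n_per_pattern, n_batches = n_batches,
              batch_sd = batch_sd, batch_scale_sd = batch_scale_sd,
              n_background_genes = n_background_genes,
              n_signature_genes = n_signature_genes,
              signature_effect = signature_effect, icg_effect = icg_effect,
              icg_reversed = icg_reversed, residual_sd = residual_sd,
              axis_sd = axis_sd, n_immune_sets = n_immune_sets,
              immune_set_size = immune_set_size,
              n_neutral_sets = n_neutral_sets,
              hazard_lambda0 = hazard_lambda0, hazard_beta = hazard_beta,
              censor_rate = censor_rate, tmb_mean = tmb_mean,
              tmb_log_effect = tmb_log_effect,
              n_mutation_genes = n_mutation_genes, seed = seed)
  if (any(cfg$n_per_pattern <= 0) || cfg$n_batches <= 0 ||
      cfg$n_background_genes <= 0 || cfg$n_immune_sets <= 0)
    abort_icp("all counts in the simulation config must be positive")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    abort_icp("censor_rate must be in [0, 1)")
  if (cfg$n_signature_genes > cfg$n_background_genes)
    abort_icp("n_signature_genes cannot exceed n_background_genes")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate survival times with exponential hazards and calibrated censoring
#'
#' Event times are exponential with rate `lambda0 * exp(linear_predictor)`;
#' censoring is independent Uniform(0, b) with b solved so the expected
#' marginal censored fraction equals `censor_rate`.
#'
#' @param linear_predictor per-sample log relative hazard (finite).
#' @param lambda0 baseline rate (> 0).
#' @param censor_rate target marginal censoring fraction in \[0, 1).
#' @param seed optional integer seed (omit to use the current RNG stream).
#' @return data.frame with `os_time` and `os_event` (1 = event).
#' @export
simulate_survival <- function(linear_predictor, lambda0, censor_rate,
                              seed = NULL) {
  if (!all(is.finite(linear_predictor))) abort_icp("non-finite predictors")
  if (censor_rate >= 1 || censor_rate < 0)
    abort_icp("censor_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  rate <- lambda0 * exp(linear_predictor)
  n <- length(rate)
  t_event <- stats::rexp(n, rate)
  if (censor_rate == 0) {
    return(data.frame(os_time = t_event, os_event = 1L))
  }
  # P(censored | rate, Unif(0,b)) = (1 - exp(-rate*b)) / (rate*b)
  marg <- function(b) mean((1 - exp(-rate * b)) / (rate * b)) - censor_rate
  upper <- 1 / min(rate)
  while (marg(upper) > 0) upper <- upper * 4
  b <- stats::uniroot(marg, c(1e-8, upper), tol = 1e-10)$root
  t_cens <- stats::runif(n, 0, b)
  data.frame(os_time = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens))
}

#' Simulate a linked synthetic cohort
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort` with elements `expression`
#'   (genes x samples matrix, per-sample batch in `attr(, "batch")`),
#'   `clinical` (data.frame including `true_pattern` and
#'   `true_immune_axis`), `maf`, `cnv` (31-gene calls over \{-1,0,1\}),
#'   `gene_sets` (28 immune-cell sets plus `IMMUNE_SIGNATURE` /
#'   `STROMAL_SIGNATURE`), and `truth` (planted parameters).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) abort_icp("config must be a sim_config")
  set.seed(cfg$seed)

  patterns <- rep(c("A", "B", "C"), times = cfg$n_per_pattern)
  n <- length(patterns)
  ids <- sprintf("S%03d", seq_len(n))
  axis_mu <- c(A = 1, B = 0, C = -1)[patterns]
  axis <- stats::rnorm(n, axis_mu, cfg$axis_sd)
  batch <- paste0("batch", (seq_len(n) - 1L) %% cfg$n_batches + 1L)

  reg <- load_icg_registry()
  icg <- reg$gene
  icg_dir <- ifelse(icg %in% cfg$icg_reversed, -1, 1)

  n_sig <- cfg$n_signature_genes
  n_null <- cfg$n_background_genes - n_sig
  bg_sig <- sprintf("BGS%04d", seq_len(n_sig))
  bg_null <- if (n_null > 0) sprintf("BGN%04d", seq_len(n_null)) else character()

  n_sets <- cfg$n_immune_sets
  set_names <- if (n_sets <= length(IMMUNE_CELL_TYPES)) {
    IMMUNE_CELL_TYPES[seq_len(n_sets)]
  } else {
    c(IMMUNE_CELL_TYPES,
      sprintf("Immune_set_%02d", seq_len(n_sets - length(IMMUNE_CELL_TYPES))))
  }
  imm_genes <- lapply(seq_len(n_sets), function(k)
    sprintf("IMM%02d_G%02d", k, seq_len(cfg$immune_set_size)))
  # majority of sets respond positively to the axis; a few stay flat/negative
  neutral <- if (cfg$n_neutral_sets > 0)
    seq(n_sets, by = -1L, length.out = min(cfg$n_neutral_sets, n_sets))
  else integer()
  set_effect <- stats::runif(n_sets, 0.6, 1.2)
  set_effect[neutral] <- stats::runif(length(neutral), -0.3, 0.1)

  estim_imm <- sprintf("IMMSIG_G%02d", 1:50)
  estim_str <- sprintf("STRSIG_G%02d", 1:50)

  genes <- c(icg, bg_sig, bg_null, unlist(imm_genes), estim_imm, estim_str)
  # panel genes carry a discrete per-pattern mean shift (+/- icg_effect for
  # A/C, 0 for B); all other planted genes respond to the continuous axis
  effect <- c(rep(0, 31L),
              sample(c(-1, 1), n_sig, replace = TRUE) * cfg$signature_effect,
              rep(0, n_null),
              rep(set_effect, each = cfg$immune_set_size),
              rep(1.0, 50),   # immune signature tracks the axis
              rep(0.25, 50))  # stromal signature only weakly
  base <- stats::runif(length(genes), 2, 8)

  g <- length(genes)
  # per-gene effect magnitudes vary around icg_effect (genes differ in
  # dynamic range); the mean shift over the panel stays at +/- icg_effect
  icg_mag <- icg_dir * stats::runif(31L, 1 / 3, 5 / 3) * cfg$icg_effect
  pat_shift <- c(A = 1, B = 0, C = -1)[patterns]
  signal <- base + outer(effect, axis)
  signal[seq_len(31L), ] <- signal[seq_len(31L), ] + outer(icg_mag, pat_shift)
  eps <- matrix(stats::rnorm(g * n, 0, cfg$residual_sd), g, n)
  gamma <- matrix(stats::rnorm(g * cfg$n_batches, 0, cfg$batch_sd),
                  g, cfg$n_batches)
  delta <- matrix(exp(stats::rnorm(g * cfg$n_batches, 0,
                                   cfg$batch_scale_sd)), g, cfg$n_batches)
  bidx <- as.integer(factor(batch))
  expr <- signal + gamma[, bidx] + delta[, bidx] * eps
  dimnames(expr) <- list(genes, ids)
  attr(expr, "batch") <- stats::setNames(batch, ids)

  # survival: hot (high axis) protective
  axis_std <- as.numeric(scale(axis))
  lp <- -cfg$hazard_beta * axis_std
  surv <- simulate_survival(lp, cfg$hazard_lambda0, cfg$censor_rate)

  # clinical categoricals with pattern-dependent proportions
  msi_p <- list(A = c(0.50, 0.30, 0.20), B = c(0.25, 0.35, 0.40),
                C = c(0.10, 0.25, 0.65))
  msi <- vapply(patterns, function(p)
    sample(c("MSI-H", "MSI-L", "MSS"), 1L, prob = msi_p[[p]]), "")
  stage_p <- list(A = c(0.30, 0.30, 0.25, 0.15), B = c(0.2, 0.3, 0.3, 0.2),
                  C = c(0.15, 0.25, 0.30, 0.30))
  stage <- vapply(patterns, function(p)
    sample(c("I", "II", "III", "IV"), 1L, prob = stage_p[[p]]), "")
  nstage_p <- list(A = c(0.45, 0.25, 0.20, 0.10), B = c(0.3, 0.3, 0.25, 0.15),
                   C = c(0.20, 0.25, 0.30, 0.25))
  n_stage <- vapply(patterns, function(p)
    sample(c("N0", "N1", "N2", "N3"), 1L, prob = nstage_p[[p]]), "")
  recur_p <- c(A = 0.15, B = 0.30, C = 0.45)
  recurrence <- ifelse(stats::runif(n) < recur_p[patterns], "yes", "no")

  clinical <- data.frame(
    sample_id = ids, os_time = surv$os_time, os_event = surv$os_event,
    stage = stage, n_stage = n_stage, msi_subtype = msi,
    recurrence = recurrence, batch = batch,
    true_pattern = patterns, true_immune_axis = axis,
    stringsAsFactors = FALSE)

  # mutations: background Poisson load scaling with the axis plus three
  # focal genes with pattern-dependent mutation probabilities
  mut_bg <- sprintf("MUT%03d", seq_len(max(cfg$n_mutation_genes - 3L, 1L)))
  focal <- c("ARID1A", "PIK3CA", "TP53")
  focal_p <- rbind(ARID1A = c(A = 0.55, B = 0.35, C = 0.15),
                   PIK3CA = c(A = 0.40, B = 0.25, C = 0.10),
                   TP53   = c(A = 0.35, B = 0.40, C = 0.45))
  nonsyn <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
              "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del",
              "In_Frame_Ins")
  nonsyn_p <- c(0.70, 0.10, 0.05, 0.05, 0.05, 0.025, 0.025)
  mu <- cfg$tmb_mean * exp(cfg$tmb_log_effect * axis)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    k <- stats::rpois(1L, mu[i])
    gsym <- if (k > 0) sample(mut_bg, k, replace = TRUE) else character()
    vc <- if (k > 0) sample(nonsyn, k, replace = TRUE, prob = nonsyn_p)
          else character()
    hit <- stats::runif(3) < focal_p[, patterns[i]]
    gsym <- c(gsym, focal[hit])
    vc <- c(vc, rep("Missense_Mutation", sum(hit)))
    ks <- stats::rpois(1L, 0.25 * mu[i])   # silent passengers
    if (ks > 0) {
      gsym <- c(gsym, sample(mut_bg, ks, replace = TRUE))
      vc <- c(vc, rep("Silent", ks))
    }
    if (length(gsym))
      rec[[i]] <- data.frame(Hugo_Symbol = gsym, Tumor_Sample_Barcode = ids[i],
                             Variant_Classification = vc,
                             stringsAsFactors = FALSE)
  }
  maf <- do.call(rbind, rec[!vapply(rec, is.null, TRUE)])
  rownames(maf) <- NULL

  # CNV calls over the 31-gene panel, gain/loss-prone genes as reported
  gain_prone <- c("LGALS9", "CD160", "KIR3DL1", "VSIR", "TNFSF4",
                  "TNFSF18", "CD40", "CD40LG")
  loss_prone <- c("PDCD1", "VTCN1", "TNFSF9", "CD70", "TNFSF14")
  gain_p <- ifelse(icg %in% gain_prone, 0.25,
                   ifelse(icg %in% loss_prone, 0.03, 0.08))
  loss_p <- ifelse(icg %in% loss_prone, 0.25,
                   ifelse(icg %in% gain_prone, 0.03, 0.08))
  u <- matrix(stats::runif(31L * n), 31L, n)
  cnv <- matrix(0L, 31L, n, dimnames = list(icg, ids))
  cnv[u < gain_p] <- 1L
  cnv[u > 1 - loss_p] <- -1L

  gene_sets <- c(imm_genes, list(estim_imm, estim_str))
  names(gene_sets) <- c(set_names, "IMMUNE_SIGNATURE", "STROMAL_SIGNATURE")
  attr(gene_sets, "description") <-
    stats::setNames(c(rep("immune cell type", n_sets),
                      "immune content signature", "stromal content signature"),
                    names(gene_sets))

  out <- list(
    expression = expr, clinical = clinical, maf = maf, cnv = cnv,
    gene_sets = gene_sets,
    truth = list(config = cfg, pattern = stats::setNames(patterns, ids),
                 immune_axis = stats::setNames(axis, ids),
                 set_effect = stats::setNames(set_effect, set_names),
                 signature_genes = bg_sig, focal_probs = focal_p,
                 linear_predictor = stats::setNames(lp, ids)))
  class(out) <- "synthetic_cohort"
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `expression.tsv`, `clinical.tsv`, `mutations.maf`, `cnv.tsv`,
#' `sets.gmt` and `truth.json` under `dir`.
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_maf(cohort$maf, file.path(dir, "mutations.maf"))
  cnv <- data.frame(gene = rownames(cohort$cnv), cohort$cnv,
                    check.names = FALSE)
  utils::write.table(cnv, file.path(dir, "cnv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "sets.gmt"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
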