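# Mutation-landscape summaries from a MAF: tumor mutation burden, per-gene
# mutation frequency, pairwise co-occurrence / mutual exclusivity, and
# CNV gain/loss frequencies from thresholded calls.

#' Default nonsynonymous variant classes
#' @return character vector of MAF `Variant_Classification` values counted
#'   as nonsynonymous.
#' @export
nonsyn_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
    "Translation_Start_Site", "Nonstop_Mutation")
}

#' Tumor mutation burden per sample
#'
#' Counts MAF records whose variant class is in `classes` for every
#' requested sample; samples without records get 0. Reported as a raw
#' count by default; supply `capture_mb` for a per-megabase rate.
#'
#' @param maf data.frame from [read_maf()].
#' @param sample_ids samples to report (zero-record samples included).
#' @param classes counted variant classes (default [nonsyn_classes()]).
#' @param capture_mb optional capture size in Mb.
#' @return data.frame: `sample_id`, `tmb` (integer count), and `tmb_per_mb`
#'   when `capture_mb` is given.
#' @export
compute_tmb <- function(maf, sample_ids, classes = nonsyn_classes(),
                        capture_mb = NULL) {
  keep <- maf$Variant_Classification %in% classes
  counts <- table(factor(maf$Tumor_Sample_Barcode[keep],
                         levels = sample_ids))
  out <- data.frame(sample_id = sample_ids,
                    tmb = as.integer(counts[sample_ids]),
                    stringsAsFactors = FALSE)
  if (!is.null(capture_mb)) out$tmb_per_mb <- out$tmb / capture_mb
  out
}

# per-sample mutated indicator matrix (genes x samples), nonsynonymous
# records only, multiple hits collapsed
mutated_matrix <- function(maf, genes, sample_ids,
                           classes = nonsyn_classes()) {
  keep <- maf$Variant_Classification %in% classes &
    maf$Hugo_Symbol %in% genes
  m <- matrix(FALSE, length(genes), length(sample_ids),
              dimnames = list(genes, sample_ids))
  if (any(keep)) {
    hits <- unique(maf[keep, c("Hugo_Symbol", "Tumor_Sample_Barcode")])
    hits <- hits[hits$Tumor_Sample_Barcode %in% sample_ids, ]
    m[cbind(hits$Hugo_Symbol, hits$Tumor_Sample_Barcode)] <- TRUE
  }
  m
}

#' Per-gene mutation frequency
#'
#' Fraction of samples carrying at least one nonsynonymous record in the
#' gene (multiple hits in one sample count once).
#'
#' @inheritParams compute_tmb
#' @param genes genes to report (genes absent from the MAF get 0).
#' @return data.frame: `gene`, `n_mutated`, `frequency`.
#' @export
mutation_frequency <- function(maf, genes, sample_ids,
                               classes = nonsyn_classes()) {
  m <- mutated_matrix(maf, genes, sample_ids, classes)
  data.frame(gene = genes, n_mutated = rowSums(m),
             frequency = rowSums(m) / length(sample_ids),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise mutation co-occurrence / mutual exclusivity
#'
#' For every unordered gene pair, a Fisher exact test on the 2x2
#' mutated/wild-type cross-tab, BH adjustment across all pairs, and a
#' label: co-occurring (OR > 1), exclusive (OR < 1) when the adjusted p
#' falls below `fdr`, otherwise none. Odds ratios are sample ORs with
#' Haldane-Anscombe correction on zero cells; exact p-values come from
#' the uncorrected table. Genes mutated in zero samples are skipped with
#' a note.
#'
#' @inheritParams mutation_frequency
#' @param fdr BH threshold for the labels (default 0.05).
#' @return data.frame per pair: `gene1`, `gene2`, `n11` (both mutated),
#'   `n10`, `n01`, `n00`, `odds_ratio`, `p`, `fdr`, `label`.
#' @export
cooccurrence <- function(maf, genes, sample_ids, fdr = 0.05,
                         classes = nonsyn_classes()) {
  if (length(genes) < 2L) abort_icp("need >= 2 genes")
  m <- mutated_matrix(maf, genes, sample_ids, classes)
  never <- rowSums(m) == 0L
  if (any(never)) {
    message("skipping gene(s) mutated in zero samples: ",
            paste(genes[never], collapse = ", "))
    m <- m[!never, , drop = FALSE]
  }
  if (nrow(m) < 2L) abort_icp("fewer than 2 genes with mutations")
  pairs <- utils::combn(rownames(m), 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    g1 <- m[pr[1L], ]; g2 <- m[pr[2L], ]
    tab <- matrix(c(sum(g1 & g2), sum(g1 & !g2),
                    sum(!g1 & g2), sum(!g1 & !g2)), 2L, 2L)
    data.frame(gene1 = pr[1L], gene2 = pr[2L],
               n11 = tab[1, 1], n10 = tab[1, 2],
               n01 = tab[2, 1], n00 = tab[2, 2],
               odds_ratio = sample_odds_ratio(tab),
               p = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$label <- "none"
  out$label[out$fdr < fdr & out$odds_ratio > 1] <- "co-occurring"
  out$label[out$fdr < fdr & out$odds_ratio < 1] <- "exclusive"
  out
}

#' CNV gain/loss frequency per gene
#'
#' @param cnv genes x samples matrix over \{-1, 0, 1\} (see [read_cnv()]).
#' @param genes genes to report; unknown genes are an error.
#' @return data.frame: `gene`, `gain_freq`, `loss_freq` (each in \[0,1\],
#'   summing to <= 1).
#' @export
cnv_frequency <- function(cnv, genes = rownames(cnv)) {
  miss <- setdiff(genes, rownames(cnv))
  if (length(miss)) abort_icp("gene(s) absent from the CNV table: ",
                              paste(miss, collapse = ", "))
  sub <- cnv[genes, , drop = FALSE]
  data.frame(gene = genes,
             gain_freq = rowMeans(sub == 1L),
             loss_freq = rowMeans(sub == -1L),
             row.names = NULL, stringsAsFactors = FALSE)
}
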