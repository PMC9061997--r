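#' The 31-gene immune checkpoint panel
#'
#' Returns the fixed panel of 31 immune checkpoint genes (ICGs) used for
#' pattern discovery, with each gene annotated by its role in the
#' ligand/receptor pair and its functional class (costimulatory or
#' coinhibitory). The panel comprises 12 costimulatory and 19 coinhibitory
#' molecules; 17 are ligands and 14 receptors.
#'
#' @return A data.frame with columns `gene` (character, unique symbols),
#'   `role` (factor: `"ligand"`/`"receptor"`) and `class` (factor:
#'   `"costimulatory"`/`"coinhibitory"`), 31 rows. Integrity of the
#'   partitions is asserted at load time.
#' @examples
#' reg <- load_icg_registry()
#' table(reg$role, reg$class)
#' @export
load_icg_registry <- function() {
  costim <- c("CD27", "CD28", "CD40", "CD40LG", "ICOS", "ICOSLG",
              "TNFRSF18", "TNFRSF4", "TNFRSF9", "TNFSF18", "TNFSF4",
              "TNFSF9")
  coinhib <- c("ADORA2A", "BTLA", "CD160", "CD274", "CD276", "CD70",
               "CD80", "CD86", "CTLA4", "HAVCR2", "KIR3DL1", "LAG3",
               "LGALS9", "PDCD1", "PDCD1LG2", "TNFRSF14", "TNFSF14",
               "VSIR", "VTCN1")
  ligands <- c("CD160", "CD274", "CD276", "CD40LG", "CD70", "CD80",
               "CD86", "ICOSLG", "LGALS9", "PDCD1LG2", "TNFRSF14",
               "TNFSF14", "TNFSF18", "TNFSF4", "TNFSF9", "VSIR", "VTCN1")
  receptors <- c("ADORA2A", "BTLA", "CD27", "CD28", "CD40", "CTLA4",
                 "HAVCR2", "ICOS", "KIR3DL1", "LAG3", "PDCD1",
                 "TNFRSF18", "TNFRSF4", "TNFRSF9")

  genes <- c(costim, coinhib)
  reg <- data.frame(
    gene = genes,
    role = factor(ifelse(genes %in% ligands, "ligand", "receptor"),
                  levels = c("ligand", "receptor")),
    class = factor(ifelse(genes %in% costim, "costimulatory",
                          "coinhibitory"),
                   levels = c("costimulatory", "coinhibitory")),
    stringsAsFactors = FALSE
  )
  reg <- reg[order(reg$gene), , drop = FALSE]
  rownames(reg) <- NULL

  # integrity: partitions must tile the panel exactly
  stopifnot(
    nrow(reg) == 31L,
    anyDuplicated(reg$gene) == 0L,
    sum(reg$role == "ligand") == 17L,
    sum(reg$role == "receptor") == 14L,
    sum(reg$class == "costimulatory") == 12L,
    sum(reg$class == "coinhibitory") == 19L,
    setequal(genes, union(ligands, receptors)),
    length(intersect(ligands, receptors)) == 0L
  )
  reg
}

#' @rdname load_icg_registry
#' @return `icg_genes()` returns just the 31 gene symbols, sorted.
#' @export
icg_genes <- function() load_icg_registry()$gene
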