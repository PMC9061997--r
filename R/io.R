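# Readers and writers for the plain-text formats the pipeline touches:
# expression (TSV / GCT v1.2), clinical tables (TSV), somatic mutations
# (MAF), thresholded CNV calls (TSV), gene sets (GMT). Gene symbols are the
# join key everywhere; expression is a genes x samples numeric matrix with
# an optional per-sample "batch" attribute.

#' Read a gene-by-sample expression matrix
#'
#' @param path file path. TSV dialect: first column gene symbols (any header
#'   name), remaining columns one per sample. GCT v1.2: `#1.2` line,
#'   dimension line, then `Name`/`Description` columns before the samples.
#' @param format `"tsv"` or `"gct"`.
#' @param log2 if `TRUE`, apply `log2(x + 1)` after reading (for raw TPM
#'   input; the pipeline otherwise assumes values are already log2 scale).
#' @return numeric matrix, genes in rows (unique symbols), samples in
#'   columns. Duplicate gene rows are collapsed by keeping the row with the
#'   largest mean.
#' @export
read_expression_matrix <- function(path, format = c("tsv", "gct"),
                                   log2 = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_icp("file not found: ", path)
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !startsWith(header[1L], "#1.2"))
      abort_icp("malformed GCT header (expected '#1.2'): ", path)
    tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L || !identical(tolower(names(tab)[1:2]),
                                     c("name", "description")))
      abort_icp("malformed GCT table: expected Name and Description columns")
    genes <- as.character(tab[[1L]])
    vals <- tab[, -(1:2), drop = FALSE]
  } else {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L) abort_icp("malformed expression header: ", path)
    hdr_samples <- header[-1L]
    if (anyDuplicated(hdr_samples))
      abort_icp("duplicate sample id(s): ",
                paste(unique(hdr_samples[duplicated(hdr_samples)]),
                      collapse = ", "))
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    vals <- tab[, -1L, drop = FALSE]
    colnames(vals) <- hdr_samples
  }
  samples <- colnames(vals)
  if (anyDuplicated(samples))
    abort_icp("duplicate sample id(s): ",
              paste(unique(samples[duplicated(samples)]), collapse = ", "))
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) != is.na(col) | is.na(col))[1L]
      if (!is.na(bad) && length(bad))
        abort_icp("non-numeric value '", col[bad], "' at gene row ", bad,
                  ", sample column '", samples[j], "'")
      vals[[j]] <- num
    }
    if (anyNA(vals[[j]])) {
      bad <- which(is.na(vals[[j]]))[1L]
      abort_icp("non-numeric value 'NA' at gene row ", bad,
                ", sample column '", samples[j], "'")
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- genes
  x <- collapse_duplicate_genes(x)
  if (log2) x <- log2(x + 1)
  if (!all(is.finite(x))) abort_icp("non-finite expression values in ", path)
  x
}

# duplicate gene rows: keep the one with the largest row mean
collapse_duplicate_genes <- function(x) {
  if (!anyDuplicated(rownames(x))) return(x)
  means <- rowMeans(x)
  ord <- order(rownames(x), -means)
  x <- x[ord, , drop = FALSE]
  x <- x[!duplicated(rownames(x)), , drop = FALSE]
  x[order(match(rownames(x), unique(rownames(x)))), , drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()] for the TSV dialect; full-precision
#' values so a read/write round trip is bit-identical.
#' @param x genes x samples numeric matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with one row per sample. Requires `sample_id`, `os_time` (months,
#' non-negative) and `os_event` (0/1); any further columns (stage, N stage,
#' MSI/molecular subtype, batch, ...) are kept as-is.
#' @param path file path.
#' @return data.frame keyed by unique `sample_id`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort_icp("clinical table lacks column(s): ",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) abort_icp("duplicate sample_id values")
  if (!all(tab$os_event %in% c(0, 1))) abort_icp("os_event must be 0/1")
  if (any(tab$os_time < 0)) abort_icp("negative os_time")
  tab
}

#' Read a MAF mutation table
#'
#' Requires `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`; all other columns are preserved untouched.
#' Lines starting with `#` are skipped.
#' @param path file path.
#' @return data.frame with one row per mutation record.
#' @export
read_maf <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort_icp("MAF lacks required column(s): ",
                              paste(miss, collapse = ", "))
  tab
}

#' @rdname read_maf
#' @param maf data.frame as returned by `read_maf()`.
#' @export
write_maf <- function(maf, path) {
  utils::write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read thresholded per-gene CNV calls
#'
#' TSV with genes in rows, samples in columns, integer calls. GISTIC-like
#' -2..2 input is collapsed to \{-1, 0, 1\} (deep and shallow events merged)
#' because only gain/loss frequencies are consumed downstream.
#' @param path file path.
#' @return integer matrix over \{-1, 0, 1\}.
#' @export
read_cnv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  x <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(x) <- as.character(tab[[1L]])
  if (!all(x %in% -2:2)) abort_icp("CNV calls must be integers in -2..2")
  x <- sign(x)
  storage.mode(x) <- "integer"
  x
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB ...`.
#' Empty gene fields (trailing tabs) are dropped.
#' @param path file path.
#' @return named list of character vectors; set descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) abort_icp("GMT line ", short[1L],
                               " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    abort_icp("duplicate gene-set name(s): ",
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    g[nzchar(g)]
  })
  if (any(lengths(sets) == 0L)) abort_icp("empty gene set in ", path)
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)),
                                             names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
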