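## Brain-vs-periphery enrichment of candidate genes in a genes x tissues
## TPM table: tissues overexpress a gene when their TPM strictly exceeds the
## gene's across-tissue median; two genes are compared by a 2x2 chi-squared
## on brain vs non-brain membership among their overexpressing tissues.

#' Validate and normalize a tissue table
#' @keywords internal
#' @noRd
check_tissue_table <- function(table) {
  stopifnot(is.list(table), !is.null(table$tpm), !is.null(table$labels))
  if (anyDuplicated(table$labels$tissue)) stop("duplicate tissue ids")
  if (any(table$tpm < 0, na.rm = TRUE)) stop("TPM must be >= 0")
  if (sum(table$labels$is_brain) < 2 || sum(!table$labels$is_brain) < 2)
    stop("need >= 2 brain and >= 2 non-brain tissues")
  if (!identical(colnames(table$tpm), table$labels$tissue))
    stop("tpm columns must match the label table's tissues")
  table
}

#' Tissues overexpressing a gene
#'
#' A tissue overexpresses a gene when its expression strictly exceeds the
#' gene's median across all tissues (the median of an even-length vector is
#' the mean of the two central order statistics; ties at the median do not
#' count). Missing expression for any tissue is an error, mirroring the rule
#' that only tissues with data for all analyzed genes are included.
#'
#' @param table A tissue table: list with `tpm` (genes x tissues) and
#'   `labels` (data.frame: tissue, is_brain).
#' @param gene Gene id (row of `tpm`).
#' @return Character vector of overexpressing tissue ids.
#' @export
overexpressing_tissues <- function(table, gene) {
  table <- check_tissue_table(table)
  if (!gene %in% rownames(table$tpm)) stop("gene not in table: ", gene)
  x <- table$tpm[gene, ]
  if (any(is.na(x))) stop("missing expression value(s) for gene ", gene)
  colnames(table$tpm)[x > stats::median(x)]
}

#' Brain enrichment of one gene versus another
#'
#' Builds the 2x2 table (rows = genes, columns = brain / non-brain) of each
#' gene's overexpressing tissues and tests homogeneity by chi-squared
#' (Yates continuity correction on by default for this 2x2).
#'
#' @param table A tissue table (see [overexpressing_tissues()]).
#' @param gene_a,gene_b Gene ids to compare.
#' @param continuity Apply the Yates continuity correction.
#' @return A list with `counts` (2x2 matrix), `chi2`, `df`, `p`.
#' @export
brain_enrichment_compare <- function(table, gene_a, gene_b,
                                     continuity = TRUE) {
  table <- check_tissue_table(table)
  brain <- table$labels$tissue[table$labels$is_brain]
  rows <- lapply(c(gene_a, gene_b), function(g) {
    over <- overexpressing_tissues(table, g)
    if (!length(over))
      stop("gene ", g, " overexpresses in no tissue; test undefined")
    c(brain = sum(over %in% brain), other = sum(!over %in% brain))
  })
  counts <- do.call(rbind, rows)
  rownames(counts) <- c(gene_a, gene_b)
  test <- chi2_2x2(counts, continuity = continuity)
  list(counts = counts, chi2 = test$chi2, df = test$df, p = test$p)
}

#' Brain enrichment of one gene versus the tissue background
#'
#' One-vs-rest variant: 2x2 of overexpressing / non-overexpressing tissues
#' by brain / non-brain for a single gene.
#'
#' @inheritParams brain_enrichment_compare
#' @param gene Gene id.
#' @return A list with `counts`, `chi2`, `df`, `p`.
#' @export
brain_enrichment_vs_rest <- function(table, gene, continuity = TRUE) {
  table <- check_tissue_table(table)
  over <- overexpressing_tissues(table, gene)
  if (!length(over)) stop("gene ", gene,
                          " overexpresses in no tissue; test undefined")
  brain <- table$labels$tissue[table$labels$is_brain]
  all_t <- table$labels$tissue
  counts <- rbind(
    over = c(brain = sum(over %in% brain), other = sum(!over %in% brain)),
    rest = c(brain = sum(!brain %in% over),
             other = sum(!(setdiff(all_t, brain) %in% over)))
  )
  test <- chi2_2x2(counts, continuity = continuity)
  list(counts = counts, chi2 = test$chi2, df = test$df, p = test$p)
}

#' Read a tissue table from TSV files
#'
#' @param tpm_path Genes x tissues TSV (first column = gene id).
#' @param labels_path TSV with columns `tissue` and `is_brain`.
#' @return A tissue table list (`tpm`, `labels`).
#' @export
read_tissue_table <- function(tpm_path, labels_path) {
  tpm_df <- read_tsv_stamped(tpm_path)
  tpm <- as.matrix(tpm_df[, -1, drop = FALSE])
  rownames(tpm) <- tpm_df[[1]]
  labels <- read_tsv_stamped(labels_path)
  labels$is_brain <- as.logical(labels$is_brain)
  check_tissue_table(list(tpm = tpm, labels = labels))
}
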