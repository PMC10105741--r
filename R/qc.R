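#' Filter cells on detected genes and mitochondrial content
#'
#' A cell is retained iff `min_genes <= n_genes_detected <= max_genes` and
#' `mito_fraction <= max_mito`. Both gene bounds and the mitochondrial bound
#' are inclusive: the exclusion criteria are read strictly ("fewer than",
#' "more than", "greater than"), so a cell at exactly 3000 or 9000 detected
#' genes or exactly 20% mitochondrial content survives. Removal counts per
#' criterion are logged.
#'
#' @param mat an ExpressionMatrix.
#' @param ann per-cell annotation covering every cell.
#' @param min_genes,max_genes detected-gene bounds (defaults 3000 / 9000).
#' @param max_mito maximum mitochondrial fraction (default 0.20).
#' @return list with filtered `matrix` and `annotation`.
#' @export
filter_cells <- function(mat, ann, min_genes = 3000L, max_genes = 9000L,
                         max_mito = 0.20) {
  stopifnot(min_genes < max_genes, max_mito > 0, max_mito <= 1)
  ann <- validate_annotation(ann, cell_ids = mat$cell_ids)
  low <- ann$n_genes_detected < min_genes
  high <- ann$n_genes_detected > max_genes
  mito <- ann$mito_fraction > max_mito
  keep <- !(low | high | mito)
  log_info("filter_cells: %d -> %d cells (removed: %d low-genes, %d high-genes, %d high-mito)",
           length(keep), sum(keep), sum(low), sum(high), sum(mito))
  if (!any(keep))
    stop(sprintf("all cells removed (low-genes %d, high-genes %d, high-mito %d)",
                 sum(low), sum(high), sum(mito)))
  cells <- mat$cell_ids[keep]
  ann_kept <- ann[keep, , drop = FALSE]
  rownames(ann_kept) <- NULL
  list(matrix = subset_matrix(mat, cells = cells), annotation = ann_kept)
}

#' Filter genes detected in too few cells
#'
#' A gene is retained iff it has a nonzero count in at least `min_cells`
#' cells ("detected in less than five cells" excluded, so detection in
#' exactly five cells survives). Apply after [filter_cells()].
#'
#' @param mat an ExpressionMatrix.
#' @param min_cells minimum number of cells with a nonzero count (default 5).
#' @return filtered ExpressionMatrix.
#' @export
filter_genes <- function(mat, min_cells = 5L) {
  stopifnot(length(mat$gene_ids) > 0L)
  ncell <- rowSums(mat$counts > 0)
  keep <- ncell >= min_cells
  log_info("filter_genes: %d -> %d genes (min_cells = %d)",
           length(keep), sum(keep), min_cells)
  if (!any(keep)) {
    warning("no genes pass the detection filter")
    return(subset_matrix(mat, genes = character(0)))
  }
  subset_matrix(mat, genes = mat$gene_ids[keep])
}

#' Drop genes expressed in only one sample
#'
#' Optional pre-filter for axis analyses: genes whose nonzero counts are
#' confined to a single sample are removed to suppress individual-specific
#' effects.
#'
#' @param mat an ExpressionMatrix.
#' @param ann annotation covering the matrix cells.
#' @return filtered ExpressionMatrix.
#' @export
filter_sample_unique_genes <- function(mat, ann) {
  ann <- validate_annotation(ann, cell_ids = mat$cell_ids)
  samp <- ann$sample_id
  nsamp <- apply(mat$counts > 0, 1L, function(nz) length(unique(samp[nz])))
  keep <- nsamp != 1L
  log_info("filter_sample_unique_genes: %d -> %d genes", length(keep), sum(keep))
  subset_matrix(mat, genes = mat$gene_ids[keep])
}

#' Log-normalize counts
#'
#' `lognorm[g, c] = ln(1 + counts[g, c] / total_counts[c] * scale_factor)`
#' with natural log and pseudocount 1. The scale factor defaults to 200000.
#' Counts and TPM layers are untouched.
#'
#' @param mat an ExpressionMatrix (no all-zero cells; guaranteed after QC).
#' @param scale_factor scaling of per-cell totals (default 2e5).
#' @return the ExpressionMatrix with a `lognorm` layer.
#' @export
normalize_expression <- function(mat, scale_factor = 2e5) {
  tot <- colSums(mat$counts)
  if (any(tot == 0))
    stop("zero-total cells present: ",
         paste(utils::head(mat$cell_ids[tot == 0], 5), collapse = ", "))
  mat$lognorm <- log1p(sweep(mat$counts, 2L, tot, "/") * scale_factor)
  mat
}

## log2 fold-change on expm1-mean of lognorm with pseudocount 1
log2fc_expm1 <- function(lognorm, case_cells, ctrl_cells) {
  mc <- rowMeans(expm1(lognorm[, case_cells, drop = FALSE]))
  mk <- rowMeans(expm1(lognorm[, ctrl_cells, drop = FALSE]))
  log2((mc + 1) / (mk + 1))
}

#' Consensus differential expression against two control lines
#'
#' For each control line separately, a two-sided Wilcoxon rank-sum test per
#' gene on the lognorm layer with BH adjustment within that comparison. A
#' gene is a consensus DEG iff it passes `q < alpha` and `|log2FC| >
#' min_log2fc` against *both* controls with the same direction. The reported
#' log2FC is against the pooled controls, computed on the expm1-mean of
#' lognorm with pseudocount 1; the reported p/q are the conservative maxima
#' over the two per-control comparisons.
#'
#' @param mat normalized ExpressionMatrix (lognorm layer required).
#' @param ann annotation covering the matrix cells.
#' @param case_samples one or more case sample ids (pooled).
#' @param control_samples exactly two control sample ids.
#' @param alpha BH q-value threshold (default 0.05).
#' @param min_log2fc absolute log2 fold-change threshold (default 0.5).
#' @return data.frame of DegRecords: gene_id, log2fc, p_value, q_value,
#'   direction, for consensus DEGs only.
#' @export
consensus_deg <- function(mat, ann, case_samples, control_samples,
                          alpha = 0.05, min_log2fc = 0.5) {
  if (is.null(mat$lognorm)) stop("lognorm layer missing; run normalize_expression()")
  stopifnot(length(control_samples) == 2L, length(case_samples) >= 1L)
  ann <- validate_annotation(ann, cell_ids = mat$cell_ids)
  case_cells <- which(ann$sample_id %in% case_samples)
  if (!length(case_cells)) stop("no cells in case sample(s)")
  Y <- mat$lognorm
  per_ctrl <- lapply(control_samples, function(cs) {
    cc <- which(ann$sample_id == cs)
    if (length(cc) < 3L) stop("control sample ", cs, " has fewer than 3 cells")
    rs <- rank_sum_rows(Y, case_cells, cc)
    q <- bh_adjust(rs$p_value)
    lfc <- log2fc_expm1(Y, case_cells, cc)
    list(p = rs$p_value, q = q, lfc = lfc)
  })
  pass <- mapply(function(x) x$q < alpha & abs(x$lfc) > min_log2fc,
                 per_ctrl)
  same_dir <- sign(per_ctrl[[1L]]$lfc) == sign(per_ctrl[[2L]]$lfc)
  hit <- pass[, 1L] & pass[, 2L] & same_dir
  pooled <- which(ann$sample_id %in% control_samples)
  lfc_pooled <- log2fc_expm1(Y, case_cells, pooled)
  out <- data.frame(
    gene_id = mat$gene_ids[hit],
    log2fc = lfc_pooled[hit],
    p_value = pmax(per_ctrl[[1L]]$p, per_ctrl[[2L]]$p)[hit],
    q_value = pmax(per_ctrl[[1L]]$q, per_ctrl[[2L]]$q)[hit],
    direction = ifelse(lfc_pooled[hit] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  log_info("consensus_deg: %d/%d genes pass vs both controls",
           nrow(out), length(mat$gene_ids))
  rownames(out) <- NULL
  out
}
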