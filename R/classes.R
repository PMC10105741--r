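#' Expression matrix container
#'
#' Genes x cells container holding the raw counts together with derived
#' layers: `tpm` (per-cell scaling of counts to one million; gene length is
#' not corrected for, see Details) and, after [normalize_expression()], a
#' `lognorm` layer. All layers share dimensions and carry the gene/cell
#' identifiers as dimnames.
#'
#' @details The TPM layer is a count-scaled stand-in: true TPM from
#' isoform-level quantification corrects for transcript length, which
#' requires the annotation-driven quantification step that is out of scope
#' here. When a TPM layer is supplied it is validated (columns sum to 1e6
#' within relative tolerance 1e-6); when absent it is computed from counts.
#'
#' @param counts non-negative numeric matrix (genes x cells).
#' @param gene_ids,cell_ids unique identifier vectors matching `counts`.
#' @param tpm optional non-negative matrix, same shape.
#' @param lognorm optional real matrix, same shape.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, gene_ids = rownames(counts),
                              cell_ids = colnames(counts),
                              tpm = NULL, lognorm = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required")
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stop(sprintf("dimension mismatch: counts is %d x %d but %d gene and %d cell ids given",
                 nrow(counts), ncol(counts), length(gene_ids), length(cell_ids)))
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) stop("duplicate gene ids: ", paste(utils::head(dup_g, 5), collapse = ", "))
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c)) stop("duplicate cell ids: ", paste(utils::head(dup_c, 5), collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (is.null(tpm)) {
    tot <- colSums(counts)
    tpm <- sweep(counts, 2L, ifelse(tot > 0, tot, 1), "/") * 1e6
  } else {
    tpm <- as.matrix(tpm)
    if (!all(dim(tpm) == dim(counts))) stop("tpm layer dimension mismatch")
    if (any(tpm < 0)) stop("tpm must be non-negative")
    cs <- colSums(tpm)
    bad <- which(cs > 0 & abs(cs - 1e6) / 1e6 > 1e-6)
    if (length(bad)) stop("tpm columns do not sum to 1e6: ",
                          paste(utils::head(cell_ids[bad], 5), collapse = ", "))
  }
  dimnames(tpm) <- list(gene_ids, cell_ids)
  if (!is.null(lognorm)) {
    lognorm <- as.matrix(lognorm)
    if (!all(dim(lognorm) == dim(counts))) stop("lognorm layer dimension mismatch")
    dimnames(lognorm) <- list(gene_ids, cell_ids)
  }
  structure(list(counts = counts, tpm = tpm, lognorm = lognorm,
                 gene_ids = gene_ids, cell_ids = cell_ids),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (layers: counts, tpm%s)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (is.null(x$lognorm)) "" else ", lognorm"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

## subset an ExpressionMatrix by gene and/or cell identifiers (or indices);
## gene subsetting changes the per-cell totals, so the TPM layer is
## recomputed from the retained counts in that case
subset_matrix <- function(mat, genes = NULL, cells = NULL) {
  g <- genes %||% mat$gene_ids
  c_ <- cells %||% mat$cell_ids
  gene_ids <- if (is.character(g)) g else mat$gene_ids[g]
  gene_subset <- !identical(gene_ids, mat$gene_ids)
  expression_matrix(mat$counts[g, c_, drop = FALSE],
                    gene_ids = gene_ids,
                    cell_ids = if (is.character(c_)) c_ else mat$cell_ids[c_],
                    tpm = if (gene_subset) NULL else mat$tpm[g, c_, drop = FALSE],
                    lognorm = if (!is.null(mat$lognorm)) mat$lognorm[g, c_, drop = FALSE])
}

annotation_columns <- c("cell_id", "sample_id", "group", "clinical_score",
                        "n_genes_detected", "mito_fraction",
                        "uniquely_mapped_reads", "n_splices")

valid_groups <- c("control", "S", "intermediate", "L", "TCA")

#' Validate a per-cell annotation table
#'
#' Required columns: cell_id, sample_id, group (control/S/intermediate/L/TCA),
#' clinical_score (integer 0-5, controls 0), n_genes_detected, mito_fraction
#' (in \[0,1\]), uniquely_mapped_reads, n_splices. When `cell_ids` is given
#' the annotation must cover every cell in the matrix.
#'
#' @param ann data.frame of per-cell annotations.
#' @param cell_ids optional vector of matrix cell ids that must be covered.
#' @return the annotation, with rows ordered to match `cell_ids` when given.
#' @export
validate_annotation <- function(ann, cell_ids = NULL) {
  miss <- setdiff(annotation_columns, names(ann))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  dup <- unique(ann$cell_id[duplicated(ann$cell_id)])
  if (length(dup)) stop("cells annotated more than once: ",
                        paste(utils::head(dup, 5), collapse = ", "))
  bad_grp <- setdiff(unique(ann$group), valid_groups)
  if (length(bad_grp)) stop("unknown group labels: ", paste(bad_grp, collapse = ", "))
  if (any(ann$clinical_score < 0 | ann$clinical_score > 5))
    stop("clinical_score must lie in 0..5")
  if (any(ann$group == "control" & ann$clinical_score != 0))
    stop("control cells must have clinical_score 0")
  if (any(ann$mito_fraction < 0 | ann$mito_fraction > 1))
    stop("mito_fraction must lie in [0, 1]")
  if (!is.null(cell_ids)) {
    missing_cells <- setdiff(cell_ids, ann$cell_id)
    if (length(missing_cells))
      stop("annotation missing cells: ",
           paste(utils::head(missing_cells, 5), collapse = ", "))
    ann <- ann[match(cell_ids, ann$cell_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

#' PSI matrix container
#'
#' Alternative-splicing events x cells matrix of percent-spliced-in values in
#' \[0,1\]; missing measurements are explicit `NA`s (never encoded as 0).
#' Event metadata carries the seven standard local event types (SE, A5, A3,
#' MX, RI, AF, AL) and the isoform membership defining each event.
#'
#' @param psi numeric matrix, events x cells, values in \[0,1\] or NA.
#' @param events data.frame with columns event_id, gene_id, type,
#'   inclusion_isoforms, total_isoforms (isoform lists comma-separated).
#' @return an object of class `PsiMatrix`.
#' @export
psi_matrix <- function(psi, events) {
  psi <- as.matrix(psi)
  need <- c("event_id", "gene_id", "type", "inclusion_isoforms", "total_isoforms")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(events) != nrow(psi)) stop("event table / PSI matrix row mismatch")
  if (anyDuplicated(events$event_id)) stop("duplicate event ids")
  bad_type <- setdiff(unique(events$type), c("SE", "A5", "A3", "MX", "RI", "AF", "AL"))
  if (length(bad_type)) stop("unknown event types: ", paste(bad_type, collapse = ", "))
  vals <- psi[!is.na(psi)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    stop("PSI values must lie in [0, 1]")
  rownames(psi) <- events$event_id
  structure(list(psi = psi, events = events), class = "PsiMatrix")
}

#' @export
print.PsiMatrix <- function(x, ...) {
  cat(sprintf("PsiMatrix: %d events x %d cells (%.1f%% missing)\n",
              nrow(x$psi), ncol(x$psi), 100 * mean(is.na(x$psi))))
  invisible(x)
}

#' Splice-event definition
#'
#' @param event_id,gene_id identifiers.
#' @param type one of SE, A5, A3, MX, RI, AF, AL.
#' @param inclusion_isoforms,total_isoforms character vectors of isoform ids;
#'   inclusion must be a proper subset of total.
#' @return a `SpliceEvent` list.
#' @export
splice_event <- function(event_id, gene_id, type, inclusion_isoforms, total_isoforms) {
  type <- match.arg(type, c("SE", "A5", "A3", "MX", "RI", "AF", "AL"))
  if (!length(inclusion_isoforms) || !length(total_isoforms))
    stop("isoform sets must be non-empty")
  if (!all(inclusion_isoforms %in% total_isoforms) ||
      length(setdiff(total_isoforms, inclusion_isoforms)) == 0L)
    stop("inclusion isoforms must be a proper subset of total isoforms")
  structure(list(event_id = event_id, gene_id = gene_id, type = type,
                 inclusion_isoforms = inclusion_isoforms,
                 total_isoforms = total_isoforms), class = "SpliceEvent")
}
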