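## core PCA on a genes x cells matrix: rows centered (and optionally scaled),
## decomposition through the smaller Gram matrix, deterministic sign
## convention (each loading vector's largest-magnitude element positive).
pca_core <- function(X, n_pcs, scale_rows = TRUE) {
  mu <- rowMeans(X)
  Xc <- X - mu
  if (scale_rows) {
    s <- sqrt(rowSums(Xc^2) / (ncol(Xc) - 1L))
    keep <- s > 1e-12
    Xc <- Xc[keep, , drop = FALSE] / s[keep]
  } else {
    keep <- rowSums(Xc^2) > 1e-24
    Xc <- Xc[keep, , drop = FALSE]
  }
  n_pcs <- min(n_pcs, nrow(Xc) - 1L, ncol(Xc) - 1L)
  if (n_pcs < 1L) stop("not enough variation for PCA")
  M <- t(Xc)                                   # cells x genes
  if (nrow(M) <= ncol(M)) {
    eg <- eigen(tcrossprod(M), symmetric = TRUE)
    d <- sqrt(pmax(eg$values[seq_len(n_pcs)], 0))
    U <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    V <- crossprod(M, U) / rep(pmax(d, 1e-300), each = ncol(M))
  } else {
    eg <- eigen(crossprod(M), symmetric = TRUE)
    d <- sqrt(pmax(eg$values[seq_len(n_pcs)], 0))
    V <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    U <- M %*% V / rep(pmax(d, 1e-300), each = nrow(M))
  }
  for (j in seq_len(n_pcs)) {                  # sign convention
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U * rep(d, each = nrow(U))
  dimnames(scores) <- list(colnames(X), paste0("PC", seq_len(n_pcs)))
  dimnames(V) <- list(rownames(Xc), paste0("PC", seq_len(n_pcs)))
  list(scores = scores, loadings = V,
       sdev = d / sqrt(max(nrow(M) - 1L, 1L)), used = rownames(Xc))
}

#' Select highly variable genes by binned dispersion
#'
#' Dispersion = variance/mean of `expm1(lognorm)` per gene, z-scored within
#' 20 bins of the gene mean; the top `n_hvg` genes by z-score are returned.
#'
#' @param lognorm genes x cells lognorm matrix.
#' @param n_hvg number of genes to keep (default 4500); when it exceeds the
#'   gene count all genes are used with a warning.
#' @return character vector of gene ids.
#' @export
select_hvg <- function(lognorm, n_hvg = 4500L) {
  if (n_hvg >= nrow(lognorm)) {
    if (n_hvg > nrow(lognorm))
      warning("n_hvg exceeds gene count; using all genes")
    return(rownames(lognorm))
  }
  expr <- expm1(lognorm)
  mu <- rowMeans(expr)
  v <- rowSums((expr - mu)^2) / (ncol(expr) - 1L)
  disp <- ifelse(mu > 0, v / mu, 0)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = 21)))
  bins <- if (length(br) > 2L) cut(mu, breaks = br, include.lowest = TRUE)
          else factor(rep(1L, length(mu)))
  z <- stats::ave(disp, bins, FUN = function(x) {
    s <- stats::sd(x); if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  ord <- order(-z, rownames(lognorm), method = "radix")
  rownames(lognorm)[ord[seq_len(n_hvg)]]
}

#' PCA of normalized expression
#'
#' Highly variable genes are selected by binned dispersion, genes are
#' centered and scaled to unit variance across cells, and the decomposition
#' uses a deterministic sign convention (the largest-magnitude loading of
#' each PC is positive).
#'
#' @param mat normalized ExpressionMatrix.
#' @param n_pcs number of components (default 15).
#' @param n_hvg highly variable genes to use (default 4500; all genes with a
#'   warning when fewer are available).
#' @return list with `scores` (cells x PCs), `loadings` (genes x PCs, unit
#'   norm), `sdev`, and `hvg`.
#' @export
fit_pca <- function(mat, n_pcs = 15L, n_hvg = 4500L) {
  if (is.null(mat$lognorm)) stop("lognorm layer missing; run normalize_expression()")
  hvg <- select_hvg(mat$lognorm, n_hvg)
  p <- pca_core(mat$lognorm[hvg, , drop = FALSE], n_pcs, scale_rows = TRUE)
  list(scores = p$scores, loadings = p$loadings, sdev = p$sdev, hvg = p$used)
}

#' Build the pseudo-disease-severity axis from PC scores
#'
#' For every candidate PC the Spearman correlation between per-cell PC score
#' and per-cell clinical score is computed; the PC maximizing the absolute
#' correlation is chosen (ties broken toward the lower index), oriented so
#' the correlation is positive (controls low), and min-max rescaled to
#' \[0,1\] as the per-cell pseudo-severity.
#'
#' @param pca output of [fit_pca()] (or any list with a `scores` matrix).
#' @param ann annotation covering the score rows.
#' @param candidate_pcs how many leading PCs to consider (default all).
#' @return a `SeverityAxis` list: pc_index, loadings, cell_score,
#'   pseudo_severity, orientation, selection_correlation, pc_correlations.
#' @export
select_severity_pc <- function(pca, ann, candidate_pcs = ncol(pca$scores)) {
  scores <- pca$scores
  ann <- validate_annotation(ann, cell_ids = rownames(scores))
  clin <- ann$clinical_score
  if (length(unique(clin)) < 2L)
    stop("axis undefined without severity contrast: all clinical scores equal")
  k <- min(candidate_pcs, ncol(scores))
  rho <- vapply(seq_len(k), function(j)
    suppressWarnings(stats::cor(scores[, j], clin, method = "spearman")),
    numeric(1L))
  rho[is.na(rho)] <- 0
  pc <- which.max(abs(rho))           # ties: lower index wins
  orientation <- if (rho[pc] >= 0) 1 else -1
  oriented <- orientation * scores[, pc]
  ps <- minmax01(oriented)
  axis <- list(pc_index = pc,
               loadings = if (!is.null(pca$loadings))
                 orientation * pca$loadings[, pc] else NULL,
               cell_score = stats::setNames(scores[, pc], rownames(scores)),
               pseudo_severity = stats::setNames(ps, rownames(scores)),
               orientation = orientation,
               selection_correlation = abs(rho[pc]),
               pc_correlations = rho)
  class(axis) <- "SeverityAxis"
  log_info("severity axis: PC%d selected (|Spearman| = %.3f vs clinical score)",
           pc, abs(rho[pc]))
  axis
}

#' @export
print.SeverityAxis <- function(x, ...) {
  cat(sprintf("SeverityAxis: PC%d, |rho| = %.3f vs clinical score, %d cells\n",
              x$pc_index, x$selection_correlation, length(x$pseudo_severity)))
  invisible(x)
}

#' Convenience wrapper: QC'd matrix to severity axis
#'
#' Cells of TCA samples are excluded from axis construction by default (the
#' total-colonic form follows distinct pathogenic pathways and would distort
#' the S-to-L axis).
#'
#' @param mat normalized ExpressionMatrix.
#' @param ann annotation.
#' @param n_pcs,n_hvg passed to [fit_pca()].
#' @param exclude_tca drop TCA-group cells first (default TRUE).
#' @return a `SeverityAxis` (covering the retained cells only).
#' @export
build_severity_axis <- function(mat, ann, n_pcs = 15L, n_hvg = 4500L,
                                exclude_tca = TRUE) {
  ann <- validate_annotation(ann, cell_ids = mat$cell_ids)
  if (exclude_tca && any(ann$group == "TCA")) {
    keep <- ann$cell_id[ann$group != "TCA"]
    log_info("axis: excluding %d TCA cells", sum(ann$group == "TCA"))
    mat <- subset_matrix(mat, cells = keep)
    ann <- ann[ann$group != "TCA", , drop = FALSE]
  }
  pca <- fit_pca(mat, n_pcs = n_pcs, n_hvg = n_hvg)
  select_severity_pc(pca, ann)
}

#' Rank-sum test of pseudo-severity between two groups
#'
#' @param axis a `SeverityAxis`.
#' @param ann annotation covering the axis cells.
#' @param group_a,group_b group labels to compare.
#' @return list with `statistic` and `p_value` (two-sided rank-sum).
#' @export
group_axis_test <- function(axis, ann, group_a, group_b) {
  cells <- names(axis$pseudo_severity)
  ann <- validate_annotation(ann, cell_ids = cells)
  a <- axis$pseudo_severity[ann$group == group_a]
  b <- axis$pseudo_severity[ann$group == group_b]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 cells on the axis")
  rank_sum_test(a, b)
}
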