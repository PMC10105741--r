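#' Co-expression of every gene with a hub regulator within one condition
#'
#' Spearman correlation between the hub gene and each other gene over the
#' cells of the requested condition, p-values from the t approximation and
#' BH q-values across genes. Genes with no rank variance get r = NA, p = 1.
#'
#' @param mat normalized ExpressionMatrix.
#' @param hub hub gene id (must be present and non-constant in condition).
#' @param ann annotation covering the matrix cells.
#' @param groups group labels defining the condition (NULL = all cells).
#' @return data.frame: gene_id, r, p_value, q_value (hub row excluded).
#' @export
condition_correlation <- function(mat, hub, ann, groups = NULL) {
  if (is.null(mat$lognorm)) stop("lognorm layer missing; run normalize_expression()")
  if (!hub %in% mat$gene_ids) stop("hub gene ", hub, " not in matrix")
  ann <- validate_annotation(ann, cell_ids = mat$cell_ids)
  cells <- if (is.null(groups)) mat$cell_ids
           else ann$cell_id[ann$group %in% groups]
  if (length(cells) < 10L) stop("condition has fewer than 10 cells")
  Y <- mat$lognorm[, cells, drop = FALSE]
  hv <- Y[hub, ]
  if (stats::sd(hv) == 0) stop("hub gene is constant within the condition")
  others <- setdiff(rownames(Y), hub)
  sp <- spearman_rows_vs(Y[others, , drop = FALSE], hv)
  data.frame(gene_id = others, r = sp$r, p_value = sp$p_value,
             q_value = bh_adjust(sp$p_value), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Three-step hub-regulator target classification
#'
#' Step 1 keeps genes significantly co-expressed with the hub in the case
#' condition (`corr_q < corr_q_threshold`); step 2 keeps genes whose
#' expression is significantly disrupted (consensus DEGs); step 3 keeps genes
#' with binding evidence. Survivors are labeled `activated` when positively
#' correlated and upregulated, `repressed` when negatively correlated and
#' downregulated; correlation/DEG sign mismatches stay `none`. Each gene's
#' first failing step is recorded.
#'
#' @param correlations output of [condition_correlation()].
#' @param deg_table consensus DEG table ([consensus_deg()] output).
#' @param binding_genes character vector of genes with (ChIP-derived) binding
#'   evidence; empty set warns and yields all-`none` calls.
#' @param corr_q_threshold step-1 threshold (default 0.05).
#' @param motif_hits optional named integer vector of promoter motif-site
#'   counts, recorded per gene (not a filter).
#' @return data.frame of HubTargetCalls: gene_id, r_case, corr_q, is_deg,
#'   deg_direction, has_binding_evidence, n_motif_hits, call, failed_step.
#' @export
classify_hub_targets <- function(correlations, deg_table, binding_genes,
                                 corr_q_threshold = 0.05, motif_hits = NULL) {
  if (!length(binding_genes))
    warning("empty binding-evidence set: step 3 fails vacuously, all calls are 'none'")
  g <- correlations$gene_id
  dir <- stats::setNames(deg_table$direction, deg_table$gene_id)[g]
  dir[is.na(dir)] <- "none"
  is_deg <- g %in% deg_table$gene_id
  bind <- g %in% binding_genes
  hits <- if (is.null(motif_hits)) rep(NA_integer_, length(g))
          else as.integer(motif_hits[g])
  corr_ok <- !is.na(correlations$q_value) &
    correlations$q_value < corr_q_threshold
  call <- rep("none", length(g))
  failed <- rep("", length(g))
  failed[!corr_ok] <- "correlation"
  failed[corr_ok & !is_deg] <- "deg"
  failed[corr_ok & is_deg & !bind] <- "binding"
  ok <- corr_ok & is_deg & bind
  up <- ok & correlations$r > 0 & dir == "up"
  down <- ok & correlations$r < 0 & dir == "down"
  call[up] <- "activated"; call[down] <- "repressed"
  failed[ok & !(up | down)] <- "sign"
  data.frame(gene_id = g, r_case = correlations$r,
             corr_q = correlations$q_value, is_deg = is_deg,
             deg_direction = dir, has_binding_evidence = bind,
             n_motif_hits = hits, call = call, failed_step = failed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' DEG vs non-DEG motif enrichment (2x2 contingency test)
#'
#' Odds ratio of motif presence in DEGs against the non-DEG background:
#' OR = (a d)/(b c) over the table (DEG x motif-present), with the
#' Haldane-Anscombe 0.5 correction applied iff any cell is zero, and a
#' chi-square test with 1 df (no continuity correction by default).
#'
#' @param deg_flags logical vector: gene is a DEG.
#' @param motif_flags logical vector over the same gene universe: gene
#'   carries the motif (e.g. at least `min_motif_sites` promoter hits).
#' @param correct apply Yates continuity correction to the chi-square
#'   statistic (default FALSE).
#' @return list with `odds_ratio`, `chi2`, `p_value` and `table`.
#' @export
motif_enrichment_test <- function(deg_flags, motif_flags, correct = FALSE) {
  stopifnot(length(deg_flags) == length(motif_flags),
            is.logical(deg_flags), is.logical(motif_flags))
  if (length(unique(deg_flags)) < 2L || length(unique(motif_flags)) < 2L)
    stop("degenerate margin: both flags need both TRUE and FALSE genes")
  a <- sum(deg_flags & motif_flags);  b <- sum(deg_flags & !motif_flags)
  c_ <- sum(!deg_flags & motif_flags); d <- sum(!deg_flags & !motif_flags)
  tab <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE,
                dimnames = list(c("DEG", "nonDEG"), c("motif", "no_motif")))
  if (min(a, b, c_, d) == 0) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else or <- (a * d) / (b * c_)
  n <- a + b + c_ + d
  expct <- outer(rowSums(tab), colSums(tab)) / n
  dev <- abs(tab - expct)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expct)
  list(odds_ratio = or, chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       table = tab)
}
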