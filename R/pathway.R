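#' Additive pathway score per cell
#'
#' The additive model deliberately ignores gene-gene interactions: the score
#' is the arithmetic mean of the lognorm values of the resolved set members
#' in each cell. The mean (rather than the sum) keeps scores comparable
#' across sets of different sizes; group comparisons are unaffected by the
#' choice. Unresolved members are dropped with a log line.
#'
#' @param mat normalized ExpressionMatrix.
#' @param genes character vector of set member gene ids.
#' @param set_name name used in output and messages.
#' @param layer "lognorm" (default) or "tpm".
#' @return data.frame: cell_id, set_name, score.
#' @export
pathway_score <- function(mat, genes, set_name = "set", layer = c("lognorm", "tpm")) {
  layer <- match.arg(layer)
  M <- if (layer == "lognorm") mat$lognorm else mat$tpm
  if (is.null(M)) stop(layer, " layer missing")
  members <- resolve_gene_set(genes, mat$gene_ids, set_name)
  data.frame(cell_id = mat$cell_ids, set_name = set_name,
             score = unname(colMeans(M[members, , drop = FALSE])),
             stringsAsFactors = FALSE)
}

#' Geometric-average complex activity per cell
#'
#' Activity is the n-th root of the product of the subunits' lognorm values;
#' it is exactly zero whenever any subunit is unexpressed (lognorm = 0) in a
#' cell, encoding the requirement that a complex needs all of its subunits.
#' Complex definitions are closed lists: a missing subunit gene is fatal.
#'
#' @param mat normalized ExpressionMatrix.
#' @param subunits character vector of subunit gene ids (all must resolve).
#' @param complex_name name used in output (e.g. Sin3, NuRD, CoREST).
#' @return data.frame: cell_id, complex_name, activity.
#' @export
complex_activity <- function(mat, subunits, complex_name = "complex") {
  if (is.null(mat$lognorm)) stop("lognorm layer missing; run normalize_expression()")
  missing <- setdiff(subunits, mat$gene_ids)
  if (length(missing))
    stop("complex ", complex_name, " subunit(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  A <- mat$lognorm[subunits, , drop = FALSE]
  zero <- colSums(A <= 0) > 0
  act <- numeric(ncol(A))
  if (any(!zero))
    act[!zero] <- exp(colMeans(log(A[, !zero, drop = FALSE])))
  data.frame(cell_id = mat$cell_ids, complex_name = complex_name,
             activity = act, stringsAsFactors = FALSE)
}

#' Rank-sum comparison of pathway scores between case groups and pooled
#' controls
#'
#' Each non-control group in the score table is tested against the pooled
#' controls (the two control lines are merged for pathway-level p-values)
#' with a two-sided Wilcoxon rank-sum test; BH adjustment is applied across
#' all (set, group) comparisons made in one call.
#'
#' @param scores data.frame from [pathway_score()] or [complex_activity()]
#'   (score column may be named `score` or `activity`).
#' @param ann annotation covering the scored cells.
#' @param control_group group label of the pooled reference (default
#'   "control").
#' @return data.frame: set_name, group, statistic, p_value, q_value.
#' @export
compare_pathway_groups <- function(scores, ann, control_group = "control") {
  val_col <- if ("score" %in% names(scores)) "score" else "activity"
  set_col <- if ("set_name" %in% names(scores)) "set_name" else "complex_name"
  ann <- validate_annotation(ann)
  grp <- stats::setNames(ann$group, ann$cell_id)[scores$cell_id]
  if (anyNA(grp)) stop("scores contain cells absent from the annotation")
  rows <- list()
  for (sn in unique(scores[[set_col]])) {
    sub <- scores[scores[[set_col]] == sn, , drop = FALSE]
    g <- grp[sub$cell_id]
    ctrl <- sub[[val_col]][g == control_group]
    if (length(ctrl) < 2L) stop("pooled control group has fewer than 2 cells")
    for (other in setdiff(unique(g), control_group)) {
      v <- sub[[val_col]][g == other]
      if (length(v) < 2L) stop("group ", other, " has fewer than 2 cells")
      rs <- rank_sum_test(v, ctrl)
      rows[[length(rows) + 1L]] <-
        data.frame(set_name = sn, group = other, statistic = rs$statistic,
                   p_value = rs$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$set_name, out$group), , drop = FALSE]
}
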