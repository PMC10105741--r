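#' Per-cell alternative-splicing frequency
#'
#' Number of splices divided by uniquely mapped reads for each cell; a
#' normalized measure of the relative splicing level of a cell. Cells with
#' zero mapped reads get a missing value with a warning.
#'
#' @param ann per-cell annotation (needs n_splices, uniquely_mapped_reads).
#' @return data.frame: cell_id, as_frequency.
#' @export
as_frequency <- function(ann) {
  ann <- validate_annotation(ann)
  bad <- ann$uniquely_mapped_reads == 0
  if (any(bad))
    warning(sum(bad), " cell(s) with zero uniquely mapped reads: AS frequency set NA")
  freq <- ifelse(bad, NA_real_, ann$n_splices / ann$uniquely_mapped_reads)
  data.frame(cell_id = ann$cell_id, as_frequency = freq,
             stringsAsFactors = FALSE)
}

#' Percent spliced in for one event from isoform abundances
#'
#' PSI = sum of inclusion-isoform TPM over sum of all event-isoform TPM;
#' missing (NA) when the total falls below `min_total_tpm`, so low-coverage
#' cells are never conflated with true exclusion.
#'
#' @param isoform_tpm named numeric vector of isoform abundances.
#' @param event a `SpliceEvent` (see [splice_event()]).
#' @param min_total_tpm minimum total event abundance (default 1.0 TPM).
#' @return PSI in \[0,1\], or NA when below the abundance threshold.
#' @export
compute_psi <- function(isoform_tpm, event, min_total_tpm = 1.0) {
  absent <- setdiff(event$total_isoforms, names(isoform_tpm))
  if (length(absent))
    stop("isoform(s) absent from abundance map: ", paste(absent, collapse = ", "))
  total <- sum(isoform_tpm[event$total_isoforms])
  if (total < min_total_tpm) return(NA_real_)
  unname(sum(isoform_tpm[event$inclusion_isoforms]) / total)
}

#' PSI matrix from an isoform-abundance matrix and an event catalog
#'
#' @param isoform_tpm isoforms x cells abundance matrix (rownames = isoform
#'   ids).
#' @param events list of `SpliceEvent`s or a data.frame with the event-table
#'   columns (isoform lists comma-separated).
#' @param min_total_tpm per-(event, cell) abundance threshold.
#' @return a `PsiMatrix`.
#' @export
compute_psi_matrix <- function(isoform_tpm, events, min_total_tpm = 1.0) {
  if (is.data.frame(events)) {
    ev_df <- events
    events <- lapply(seq_len(nrow(ev_df)), function(i)
      splice_event(ev_df$event_id[i], ev_df$gene_id[i], ev_df$type[i],
                   strsplit(ev_df$inclusion_isoforms[i], ",", fixed = TRUE)[[1L]],
                   strsplit(ev_df$total_isoforms[i], ",", fixed = TRUE)[[1L]]))
  } else {
    ev_df <- data.frame(
      event_id = vapply(events, `[[`, "", "event_id"),
      gene_id = vapply(events, `[[`, "", "gene_id"),
      type = vapply(events, `[[`, "", "type"),
      inclusion_isoforms = vapply(events, function(e)
        paste(e$inclusion_isoforms, collapse = ","), ""),
      total_isoforms = vapply(events, function(e)
        paste(e$total_isoforms, collapse = ","), ""),
      stringsAsFactors = FALSE)
  }
  psi <- matrix(NA_real_, nrow = length(events), ncol = ncol(isoform_tpm),
                dimnames = list(ev_df$event_id, colnames(isoform_tpm)))
  for (i in seq_along(events)) {
    e <- events[[i]]
    absent <- setdiff(e$total_isoforms, rownames(isoform_tpm))
    if (length(absent))
      stop("isoform(s) absent from abundance map: ", paste(absent, collapse = ", "))
    tot <- colSums(isoform_tpm[e$total_isoforms, , drop = FALSE])
    inc <- colSums(isoform_tpm[e$inclusion_isoforms, , drop = FALSE])
    v <- ifelse(tot < min_total_tpm, NA_real_, inc / pmax(tot, .Machine$double.xmin))
    psi[i, ] <- v
  }
  psi_matrix(psi, ev_df)
}

## per-sample mean PSI over non-missing cells; events x samples
psi_per_sample <- function(psi, ann) {
  ann <- validate_annotation(ann, cell_ids = colnames(psi$psi))
  samples <- unique(ann$sample_id)
  out <- vapply(samples, function(s)
    rowMeans(psi$psi[, ann$sample_id == s, drop = FALSE], na.rm = TRUE),
    numeric(nrow(psi$psi)))
  out[is.nan(out)] <- NA_real_
  colnames(out) <- samples
  out
}

#' Differential PSI between two sample groups
#'
#' Per-sample mode (`per_sample_t`): a single PSI per sample (mean over
#' non-missing cells), two-sided t-test between the groups. Per-cell mode
#' (`per_cell_ranksum`): two-sided Wilcoxon rank-sum over cells. In both
#' modes Delta-PSI is mean(group_b) - mean(group_a) of the per-sample PSI
#' values, BH adjustment runs across events, and events missing in more than
#' half the cells of either group are skipped (logged).
#'
#' @param psi a `PsiMatrix`.
#' @param ann annotation covering the PSI cells.
#' @param group_a_samples,group_b_samples sample ids of the two groups.
#' @param mode "per_sample_t" (needs >= 2 samples per group) or
#'   "per_cell_ranksum" (needs >= 5 non-missing cells per group per event).
#' @return data.frame: event_id, delta_psi, p_value, q_value, n_a, n_b.
#' @export
differential_psi <- function(psi, ann, group_a_samples, group_b_samples,
                             mode = c("per_sample_t", "per_cell_ranksum")) {
  mode <- match.arg(mode)
  ann <- validate_annotation(ann, cell_ids = colnames(psi$psi))
  ia <- which(ann$sample_id %in% group_a_samples)
  ib <- which(ann$sample_id %in% group_b_samples)
  if (!length(ia) || !length(ib)) stop("empty group")
  if (mode == "per_sample_t" &&
      (length(unique(ann$sample_id[ia])) < 2L ||
       length(unique(ann$sample_id[ib])) < 2L))
    stop("per_sample_t needs >= 2 samples per group")
  P <- psi$psi
  miss_a <- rowMeans(is.na(P[, ia, drop = FALSE]))
  miss_b <- rowMeans(is.na(P[, ib, drop = FALSE]))
  usable <- miss_a <= 0.5 & miss_b <= 0.5
  if (any(!usable))
    log_info("differential_psi: skipping %d event(s) missing in > 50%% of cells",
             sum(!usable))
  ps <- psi_per_sample(psi, ann)
  sa <- unique(ann$sample_id[ia]); sb <- unique(ann$sample_id[ib])
  rows <- lapply(which(usable), function(i) {
    va <- ps[i, sa]; vb <- ps[i, sb]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (!length(va) || !length(vb)) {
      log_info("differential_psi: event %s all-missing in one group, skipped",
               rownames(P)[i])
      return(NULL)
    }
    dpsi <- mean(vb) - mean(va)
    if (mode == "per_sample_t") {
      p <- if (length(va) < 2L || length(vb) < 2L) NA_real_
           else tryCatch(stats::t.test(vb, va)$p.value, error = function(e) NA_real_)
      n_a <- length(va); n_b <- length(vb)
    } else {
      ca <- P[i, ia]; cb <- P[i, ib]
      ca <- ca[!is.na(ca)]; cb <- cb[!is.na(cb)]
      if (length(ca) < 5L || length(cb) < 5L) return(NULL)
      p <- rank_sum_test(cb, ca)$p_value
      n_a <- length(ca); n_b <- length(cb)
    }
    data.frame(event_id = rownames(P)[i], delta_psi = dpsi, p_value = p,
               n_a = n_a, n_b = n_b, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable events")
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out[, c("event_id", "delta_psi", "p_value", "q_value", "n_a", "n_b")]
}

#' PCA of cells in PSI space with per-event weights
#'
#' Events missing in >= `max_missing` of cells are dropped; remaining missing
#' entries are mean-imputed per event (deterministic), events are centered
#' (not scaled; PSI already shares the \[0,1\] scale) and decomposed with the
#' same routine and sign convention as [fit_pca()]. The severity PC is the
#' one maximizing |Spearman| against clinical scores; events are ranked by
#' the magnitude and sign of their weight on it.
#'
#' @param psi a `PsiMatrix`.
#' @param ann annotation covering the PSI cells.
#' @param n_pcs number of PCs (default 15).
#' @param max_missing per-event missingness bound (default 0.30).
#' @return list: scores, weights (events x PCs, unit norm), pc_index,
#'   orientation, selection_correlation, pseudo_severity, event_rank
#'   (data.frame event_id, weight, abs_weight).
#' @export
psi_pca <- function(psi, ann, n_pcs = 15L, max_missing = 0.30) {
  ann <- validate_annotation(ann, cell_ids = colnames(psi$psi))
  P <- psi$psi
  keep <- rowMeans(is.na(P)) < max_missing
  if (sum(keep) < 20L)
    stop("fewer than 20 events with < ", round(100 * max_missing),
         "% missingness")
  P <- P[keep, , drop = FALSE]
  for (i in seq_len(nrow(P))) {
    na <- is.na(P[i, ])
    if (any(na)) P[i, na] <- mean(P[i, !na])
  }
  pc <- pca_core(P, n_pcs, scale_rows = FALSE)
  ax <- select_severity_pc(list(scores = pc$scores, loadings = pc$loadings), ann)
  w <- pc$loadings[, ax$pc_index] * ax$orientation
  rank_df <- data.frame(event_id = rownames(pc$loadings), weight = w,
                        abs_weight = abs(w), stringsAsFactors = FALSE)
  rank_df <- rank_df[order(-rank_df$abs_weight, rank_df$event_id), ]
  rownames(rank_df) <- NULL
  list(scores = pc$scores, weights = pc$loadings, pc_index = ax$pc_index,
       orientation = ax$orientation,
       selection_correlation = ax$selection_correlation,
       pseudo_severity = ax$pseudo_severity, event_rank = rank_df)
}

#' Driver-event target prediction (three-step, splicing layer)
#'
#' Spearman correlation of every event's PSI with the driver event's PSI
#' over cells where both are present (step 1, BH q < threshold), intersected
#' with motif-flagged target events (step 2) and with disease-associated
#' events (step 3). Positively correlated survivors are `enhanced`,
#' negatively correlated ones `repressed`.
#'
#' @param psi a `PsiMatrix`.
#' @param driver_event driver event id (< 30% missing cells, non-constant).
#' @param motif_target_events events whose exons carry the driver's binding
#'   motif.
#' @param disease_events events significantly associated with disease (e.g.
#'   significant [differential_psi()] calls).
#' @param corr_q_threshold step-1 threshold (default 0.05).
#' @return list with `enhanced`, `repressed` (character vectors) and the
#'   full `table` (event_id, r, p_value, q_value, in_motif, in_disease,
#'   call).
#' @export
driver_target_prediction <- function(psi, driver_event, motif_target_events,
                                     disease_events, corr_q_threshold = 0.05) {
  P <- psi$psi
  if (!driver_event %in% rownames(P)) stop("driver event not in PSI matrix")
  dv <- P[driver_event, ]
  if (mean(is.na(dv)) >= 0.30) stop("driver event missing in >= 30% of cells")
  if (stats::sd(dv, na.rm = TRUE) == 0) stop("driver event PSI is constant")
  others <- setdiff(rownames(P), driver_event)
  cors <- lapply(others, function(e) spearman_cor(P[e, ], dv))
  r <- vapply(cors, `[[`, numeric(1L), "r")
  p <- vapply(cors, `[[`, numeric(1L), "p_value")
  p[is.na(p)] <- 1
  q <- bh_adjust(p)
  in_motif <- others %in% motif_target_events
  in_disease <- others %in% disease_events
  pass <- !is.na(r) & q < corr_q_threshold & in_motif & in_disease
  call <- rep("none", length(others))
  call[pass & r > 0] <- "enhanced"
  call[pass & r < 0] <- "repressed"
  tab <- data.frame(event_id = others, r = r, p_value = p, q_value = q,
                    in_motif = in_motif, in_disease = in_disease, call = call,
                    stringsAsFactors = FALSE)
  list(enhanced = tab$event_id[tab$call == "enhanced"],
       repressed = tab$event_id[tab$call == "repressed"], table = tab)
}

#' Overlap of predicted targets with a known-target list
#' @param predicted,known character vectors of event ids.
#' @return list: n_overlap, n_predicted_only, n_known_only.
#' @export
overlap_with_known <- function(predicted, known) {
  list(n_overlap = length(intersect(predicted, known)),
       n_predicted_only = length(setdiff(predicted, known)),
       n_known_only = length(setdiff(known, predicted)))
}

#' Combined expression/splicing severity coordinates per sample
#'
#' Transcriptional and post-transcriptional severity are two complementary
#' coordinates: per sample, the median expression pseudo-severity and the
#' median splicing (PSI-space) pseudo-severity over the cells both axes
#' cover, both oriented controls-low.
#'
#' @param expr_axis a `SeverityAxis` from expression.
#' @param psi_axis output of [psi_pca()].
#' @param ann annotation.
#' @return data.frame: sample_id, group, expression_severity,
#'   splicing_severity.
#' @export
combined_severity_coordinates <- function(expr_axis, psi_axis, ann) {
  cells <- intersect(names(expr_axis$pseudo_severity),
                     names(psi_axis$pseudo_severity))
  if (!length(cells)) stop("no overlapping cells between the two axes")
  ann <- validate_annotation(ann)
  ann <- ann[match(cells, ann$cell_id), , drop = FALSE]
  if (anyNA(ann$cell_id)) stop("axis cells absent from annotation")
  agg <- function(v) tapply(v, ann$sample_id, stats::median)
  e <- agg(expr_axis$pseudo_severity[cells])
  s <- agg(psi_axis$pseudo_severity[cells])
  grp <- tapply(ann$group, ann$sample_id, function(x) x[1L])
  data.frame(sample_id = names(e), group = as.character(grp),
             expression_severity = as.numeric(e),
             splicing_severity = as.numeric(s),
             row.names = NULL, stringsAsFactors = FALSE)
}
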