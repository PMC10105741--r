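#' Default pipeline configuration
#'
#' Every threshold defaults to the value used throughout the package's
#' analysis contract: QC bounds 3000/9000 detected genes and 20%
#' mitochondrial content, gene detection in >= 5 cells, scale factor 200000,
#' DEG thresholds q < 0.05 and |log2FC| > 0.5, 15 PCs over 4500 highly
#' variable genes, axis-DEG q < 0.01, 4 modules with LOESS span 0.5, 50
#' switch-timing bins at per-bin alpha 0.05, correlation q < 0.05 for target
#' prediction with >= 2 motif sites, and PSI thresholds min_total_tpm 1.0 /
#' 30% missingness. Overrides are supplied as nested lists; the config
#' round-trips through YAML unchanged.
#'
#' @param ... named overrides of the top-level entries (lists are replaced
#'   entry-wise).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "encc_out",
    input = list(simulate = TRUE, sim = list(),
                 counts = NULL, annotation = NULL, format = "mtx",
                 psi = NULL),
    stages = list(qc = TRUE, axis = TRUE, dynamics = TRUE, pathway = TRUE,
                  targets = TRUE, splicing = TRUE),
    qc = list(min_genes = 3000L, max_genes = 9000L, max_mito = 0.2,
              min_cells = 5L, drop_sample_unique = TRUE),
    norm = list(scale_factor = 2e5),
    deg = list(alpha = 0.05, min_log2fc = 0.5),
    axis = list(n_pcs = 15L, n_hvg = 4500L, exclude_tca = TRUE),
    dynamics = list(q_threshold = 0.01, k = 4L, loess_span = 0.5,
                    n_bins = 50L, bin_alpha = 0.05, min_cells_per_bin = 10L,
                    core_fdr = 0.05),
    pathway = list(gmt = NULL, complexes = NULL),
    targets = list(hub = NULL, binding = NULL, motifs = NULL,
                   corr_q = 0.05, min_motif_sites = 2L),
    splicing = list(driver = NULL, motif_events = NULL, known_targets = NULL,
                    min_total_tpm = 1.0, max_missing = 0.3,
                    diff_mode = "per_sample_t", corr_q = 0.05))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a `PipelineConfig`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_guard <- function(out_dir, stage, logfile, expr) {
  tryCatch({ force(expr); TRUE }, error = function(e) {
    log_info("stage %s FAILED: %s", stage, conditionMessage(e), logfile = logfile)
    writeLines(conditionMessage(e),
               file.path(out_dir, paste0("FAILED_", stage)))
    FALSE
  })
}

#' Run the full severity pipeline
#'
#' Stages run in order qc -> axis -> dynamics -> pathway -> targets ->
#' splicing, each writing its result tables under `config$out_dir` and a log
#' line with input/output dimensions and the seed in effect. With
#' `input$simulate = TRUE` the synthetic generator provides the dataset
#' (ground-truth hub / binding / motif / driver inputs stand in for the
#' user-supplied evidence files); otherwise counts, annotation and
#' optionally a PSI fixture are read from the configured paths. A stage
#' failure leaves partial outputs in place, writes a `FAILED_<stage>`
#' marker, and yields a nonzero exit status.
#'
#' @param config a `PipelineConfig`.
#' @return integer exit status, 0 on success (invisibly).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "pipeline.log")
  unlink(c(logfile, list.files(out, pattern = "^FAILED_", full.names = TRUE)))
  set.seed(cfg$seed)
  log_info("pipeline start: seed = %d", cfg$seed, logfile = logfile)

  truth <- NULL; psi <- NULL
  if (isTRUE(cfg$input$simulate)) {
    sim_args <- cfg$input$sim
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    ds <- simulate_dataset(do.call(sim_config, sim_args))
    mat <- ds$matrix; ann <- ds$annotation; psi <- ds$psi; truth <- ds$truth
  } else {
    ex <- read_expression(cfg$input$counts, cfg$input$annotation,
                          format = cfg$input$format)
    mat <- ex$matrix; ann <- ex$annotation
    if (!is.null(cfg$input$psi)) {
      fx <- dirname(cfg$input$psi)
      psi_df <- utils::read.delim(cfg$input$psi, check.names = FALSE,
                                  na.strings = "NA")
      meta <- c("event_id", "gene_id", "type", "inclusion_isoforms",
                "total_isoforms")
      psi <- psi_matrix(as.matrix(psi_df[, setdiff(names(psi_df), meta)]),
                        psi_df[, meta])
    }
  }
  log_info("input: %d genes x %d cells", nrow(mat$counts), ncol(mat$counts),
           logfile = logfile)
  status <- 0L
  control_samples <- utils::head(unique(ann$sample_id[ann$group == "control"]), 2L)
  case_samples <- unique(ann$sample_id[ann$group != "control"])
  axis <- NULL; ax_test <- NULL; deg_pooled <- NULL

  ## ---- qc ------------------------------------------------------------------
  if (isTRUE(cfg$stages$qc)) {
    ok <- stage_guard(out, "qc", logfile, {
      fc <- filter_cells(mat, ann, cfg$qc$min_genes, cfg$qc$max_genes,
                         cfg$qc$max_mito)
      mat <- fc$matrix; ann <- fc$annotation
      mat <- filter_genes(mat, cfg$qc$min_cells)
      if (isTRUE(cfg$qc$drop_sample_unique))
        mat <- filter_sample_unique_genes(mat, ann)
      mat <- normalize_expression(mat, cfg$norm$scale_factor)
      if (!is.null(psi))
        psi <- psi_matrix(psi$psi[, mat$cell_ids, drop = FALSE], psi$events)
      write_table(data.frame(cell_id = mat$cell_ids), file.path(out, "cells_kept.tsv"))
      write_table(data.frame(gene_id = mat$gene_ids), file.path(out, "genes_kept.tsv"))
      if (length(control_samples) == 2L) {
        for (cs in case_samples) {
          deg <- consensus_deg(mat, ann, cs, control_samples,
                               alpha = cfg$deg$alpha,
                               min_log2fc = cfg$deg$min_log2fc)
          write_table(deg, file.path(out, paste0("deg_", cs, ".tsv")))
        }
        deg_pooled <- consensus_deg(mat, ann, case_samples, control_samples,
                                     alpha = cfg$deg$alpha,
                                     min_log2fc = cfg$deg$min_log2fc)
      }
      log_info("qc done: %d genes x %d cells retained (seed %d)",
               nrow(mat$counts), ncol(mat$counts), cfg$seed, logfile = logfile)
    })
    if (!ok) return(invisible(1L))
  } else if (is.null(mat$lognorm)) {
    mat <- normalize_expression(mat, cfg$norm$scale_factor)
  }

  ## ---- axis ----------------------------------------------------------------
  if (isTRUE(cfg$stages$axis)) {
    ok <- stage_guard(out, "axis", logfile, {
      axis <- build_severity_axis(mat, ann, n_pcs = cfg$axis$n_pcs,
                                   n_hvg = cfg$axis$n_hvg,
                                   exclude_tca = cfg$axis$exclude_tca)
      write_table(data.frame(cell_id = names(axis$pseudo_severity),
                             pc_score = unname(axis$cell_score),
                             pseudo_severity = unname(axis$pseudo_severity)),
                  file.path(out, "axis_cells.tsv"))
      write_table(data.frame(key = c("pc_index", "orientation",
                                     "selection_correlation"),
                             value = c(axis$pc_index, axis$orientation,
                                       axis$selection_correlation)),
                  file.path(out, "axis_meta.tsv"))
      log_info("axis done: PC%d over %d cells (seed %d)", axis$pc_index,
               length(axis$pseudo_severity), cfg$seed, logfile = logfile)
    })
    if (!ok) status <- 1L
  }

  ## ---- dynamics ------------------------------------------------------------
  if (isTRUE(cfg$stages$dynamics) && !is.null(axis)) {
    ok <- stage_guard(out, "dynamics", logfile, {
      ax_test <- axis_differential_test(mat, axis, cfg$dynamics$q_threshold)
      write_table(ax_test, file.path(out, "axis_deg.tsv"))
      sig <- ax_test$gene_id[ax_test$significant]
      if (length(sig) >= cfg$dynamics$k) {
        sm <- smooth_and_cluster(mat, axis, sig, k = cfg$dynamics$k,
                                 loess_span = cfg$dynamics$loess_span)
        write_table(sm$modules, file.path(out, "modules.tsv"))
      } else {
        write_table(data.frame(gene_id = character(0), module = integer(0)),
                    file.path(out, "modules.tsv"))
      }
      core <- if (length(control_samples) == 2L &&
                  all(c("S", "L") %in% ann$group))
        core_gene_set(mat, ann, axis, control_samples,
                      fdr = cfg$dynamics$core_fdr, alpha = cfg$deg$alpha,
                      min_log2fc = cfg$deg$min_log2fc)
      else character(0)
      al <- axis_lognorm(mat, axis)
      rows <- lapply(core, function(g) {
        sw <- switch_timing(al$Y[g, ], al$t, n_bins = cfg$dynamics$n_bins,
                            alpha = cfg$dynamics$bin_alpha,
                            min_cells_per_bin = cfg$dynamics$min_cells_per_bin)
        data.frame(gene_id = g, start = sw$interval[1L], end = sw$interval[2L],
                   direction = sw$direction %||% NA_character_,
                   n_significant_bins = length(sw$significant_bins),
                   stringsAsFactors = FALSE)
      })
      sw_tab <- if (length(rows)) do.call(rbind, rows)
        else data.frame(gene_id = character(0), start = numeric(0),
                        end = numeric(0), direction = character(0),
                        n_significant_bins = integer(0))
      write_table(sw_tab, file.path(out, "switch_periods.tsv"))
      log_info("dynamics done: %d axis DEGs, %d core genes (seed %d)",
               sum(ax_test$significant), length(core), cfg$seed,
               logfile = logfile)
    })
    if (!ok) status <- 1L
  }

  ## ---- pathway -------------------------------------------------------------
  if (isTRUE(cfg$stages$pathway)) {
    ok <- stage_guard(out, "pathway", logfile, {
      sets <- if (!is.null(cfg$pathway$gmt)) read_gmt(cfg$pathway$gmt)
        else if (!is.null(truth)) {
          s <- lapply(as.character(1:4), function(m)
            names(truth$module_label)[truth$module_label == m])
          names(s) <- paste0("planted_module", 1:4); s
        } else stop("no GMT supplied and no simulated truth available")
      scores <- do.call(rbind, lapply(names(sets), function(nm)
        pathway_score(mat, sets[[nm]], set_name = nm)))
      write_table(scores, file.path(out, "pathway_scores.tsv"))
      cxs <- if (!is.null(cfg$pathway$complexes)) read_gmt(cfg$pathway$complexes)
        else if (!is.null(truth)) {
          act <- names(truth$hub_target_class)[truth$hub_target_class == "activated"]
          list(synthetic_hub_complex = intersect(c(truth$hub_gene,
                                                   utils::head(act, 2L)),
                                                 mat$gene_ids))
        } else list()
      cx_tab <- do.call(rbind, lapply(names(cxs), function(nm)
        complex_activity(mat, cxs[[nm]], complex_name = nm)))
      if (!is.null(cx_tab))
        write_table(cx_tab, file.path(out, "complex_activity.tsv"))
      tests <- compare_pathway_groups(scores, ann)
      write_table(tests, file.path(out, "pathway_tests.tsv"))
      log_info("pathway done: %d sets scored (seed %d)", length(sets),
               cfg$seed, logfile = logfile)
    })
    if (!ok) status <- 1L
  }

  ## ---- targets -------------------------------------------------------------
  if (isTRUE(cfg$stages$targets)) {
    ok <- stage_guard(out, "targets", logfile, {
      hub <- cfg$targets$hub %||% truth$hub_gene
      if (is.null(hub)) stop("no hub gene configured")
      binding <- if (!is.null(cfg$targets$binding)) readLines(cfg$targets$binding)
        else truth$binding_genes %||% character(0)
      hits <- if (!is.null(cfg$targets$motifs)) {
        mt <- utils::read.delim(cfg$targets$motifs)
        stats::setNames(mt[[2L]], mt[[1L]])
      } else truth$motif_gene_hits
      case_groups <- setdiff(unique(ann$group), "control")
      cors <- condition_correlation(mat, hub, ann, groups = case_groups)
      deg <- deg_pooled %||% stop("targets stage needs the qc stage's DEG table")
      calls <- classify_hub_targets(cors, deg, binding,
                                    corr_q_threshold = cfg$targets$corr_q,
                                    motif_hits = hits)
      write_table(calls, file.path(out, "hub_target_calls.tsv"))
      if (!is.null(hits)) {
        universe <- mat$gene_ids
        deg_flags <- universe %in% deg$gene_id
        motif_flags <- !is.na(hits[universe]) &
          hits[universe] >= cfg$targets$min_motif_sites
        me <- motif_enrichment_test(deg_flags, unname(motif_flags))
        write_table(data.frame(key = c("odds_ratio", "chi2", "p_value"),
                               value = c(me$odds_ratio, me$chi2, me$p_value)),
                    file.path(out, "motif_enrichment.tsv"))
      }
      log_info("targets done: %d activated, %d repressed (seed %d)",
               sum(calls$call == "activated"), sum(calls$call == "repressed"),
               cfg$seed, logfile = logfile)
    })
    if (!ok) status <- 1L
  }

  ## ---- splicing ------------------------------------------------------------
  if (isTRUE(cfg$stages$splicing) && !is.null(psi)) {
    ok <- stage_guard(out, "splicing", logfile, {
      write_table(as_frequency(ann), file.path(out, "as_frequency.tsv"))
      dpsi <- differential_psi(psi, ann, control_samples, case_samples,
                               mode = cfg$splicing$diff_mode)
      write_table(dpsi, file.path(out, "differential_psi.tsv"))
      keep_cells <- if (isTRUE(cfg$axis$exclude_tca))
        ann$cell_id[ann$group != "TCA"] else ann$cell_id
      psub <- psi_matrix(psi$psi[, keep_cells, drop = FALSE], psi$events)
      pax <- psi_pca(psub, ann[match(keep_cells, ann$cell_id), ],
                     n_pcs = cfg$axis$n_pcs,
                     max_missing = cfg$splicing$max_missing)
      write_table(pax$event_rank, file.path(out, "psi_pca_weights.tsv"))
      driver <- cfg$splicing$driver %||% truth$driver_event
      if (is.null(driver)) stop("no driver event configured")
      motif_events <- if (!is.null(cfg$splicing$motif_events))
        readLines(cfg$splicing$motif_events)
      else truth$motif_target_events %||% character(0)
      ## disease association for target prediction follows the per-cell
      ## rank-sum analysis (the per-sample table above mirrors the
      ## sample-level comparison, which is underpowered with two controls)
      dpsi_cell <- differential_psi(psi, ann, control_samples, case_samples,
                                    mode = "per_cell_ranksum")
      disease <- dpsi_cell$event_id[!is.na(dpsi_cell$q_value) &
                                      dpsi_cell$q_value < 0.05]
      dt <- driver_target_prediction(psi, driver, motif_events, disease,
                                     corr_q_threshold = cfg$splicing$corr_q)
      write_table(dt$table, file.path(out, "driver_targets.tsv"))
      if (!is.null(axis)) {
        coords <- combined_severity_coordinates(axis, pax, ann)
        write_table(coords, file.path(out, "severity_2d.tsv"))
      }
      log_info("splicing done: %d events tested, %d enhanced, %d repressed (seed %d)",
               nrow(dpsi), length(dt$enhanced), length(dt$repressed),
               cfg$seed, logfile = logfile)
    })
    if (!ok) status <- 1L
  }
  log_info("pipeline finished with status %d", status, logfile = logfile)
  invisible(status)
}
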