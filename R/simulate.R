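#' Simulation configuration
#'
#' Defaults describe the stated world the downstream stages assume: two
#' control lines and six patient lines spanning clinical scores 1-5 (S,
#' intermediate and L groups), 200 cells per line, negative-binomial counts
#' with dropout, four dynamic gene modules along severity, switch-like genes
#' with known switch centers, one hub regulator with activated/repressed
#' target genes, a nuisance factor larger than the severity signal (so the
#' severity axis is *not* the first principal component), and a PSI layer
#' with a severity-linked driver event, motif-flagged target events and a
#' mutually exclusive exon pair deterministically coupled to the driver.
#'
#' @param n_control_samples,n_case_samples sample counts (>= 1 control, >= 2
#'   cases; a single-sample design is degenerate and rejected).
#' @param cells_per_sample cells per line.
#' @param n_genes total genes, including planted structure.
#' @param n_module_genes genes per dynamic module (4 modules).
#' @param n_switch_genes switch-like genes with logistic steps.
#' @param n_hub_targets activated targets of the hub regulator; the same
#'   number of repressed targets is planted.
#' @param n_events splice events; `n_driver_targets` enhanced plus the same
#'   number repressed are coupled to the driver event.
#' @param n_driver_targets driver-coupled events per class.
#' @param effect_size log-fold amplitude (natural log) of severity effects on
#'   the gene log-mean; 0 gives a null simulation.
#' @param nb_dispersion negative-binomial dispersion phi (variance =
#'   mu + phi mu^2).
#' @param dropout_rate probability an observed count is zeroed.
#' @param library_size_mean mean per-cell total count.
#' @param mito_gene_fraction fraction of genes that are mitochondrial, and
#'   the expected mitochondrial count share per cell.
#' @param n_nuisance_genes,nuisance_amplitude genes loading on the
#'   severity-orthogonal nuisance factor and its log-mean amplitude; the
#'   defaults make the nuisance the leading variance component, ahead of
#'   the severity signal.
#' @param severity_jitter_sd within-sample jitter of per-cell pseudo-severity
#'   (truncated to \[0,1\]); 0.03 keeps a sample's cells contiguous on the axis.
#' @param psi_effect_size severity amplitude of the PSI driver link; NULL
#'   (default) follows `effect_size`, 0 ablates the splicing layer's severity
#'   signal while leaving expression effects in place.
#' @param psi_concentration Beta concentration of PSI noise around its mean.
#' @param psi_missing_rate fraction of (event, cell) PSI entries set missing.
#' @param qc_fail_fraction fraction of cells given planted annotation-level
#'   QC failures (too few/many detected genes or high mitochondrial content).
#' @param seed master seed; all draws derive sub-streams from it.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_control_samples = 2L, n_case_samples = 6L,
                       cells_per_sample = 200L, n_genes = 1500L,
                       n_module_genes = 75L, n_switch_genes = 20L,
                       n_hub_targets = 30L, n_events = 100L,
                       n_driver_targets = 15L, effect_size = 1.5,
                       nb_dispersion = 0.15, dropout_rate = 0.1,
                       library_size_mean = 40000L,
                       mito_gene_fraction = 0.05,
                       n_nuisance_genes = 300L,
                       nuisance_amplitude = 2 * max(effect_size, 1),
                       severity_jitter_sd = 0.03,
                       psi_effect_size = NULL,
                       psi_concentration = 50,
                       psi_missing_rate = 0.02,
                       qc_fail_fraction = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  ints <- c("n_control_samples", "n_case_samples", "cells_per_sample",
            "n_genes", "n_module_genes", "n_switch_genes", "n_hub_targets",
            "n_events", "n_driver_targets", "library_size_mean", "seed")
  for (nm in ints) cfg[[nm]] <- as.integer(cfg[[nm]])
  if (any(vapply(cfg[ints], function(x) x < 0L, logical(1L))))
    stop("all count parameters must be non-negative")
  if (cfg$n_control_samples < 1L || cfg$n_case_samples < 2L ||
      cfg$n_control_samples + cfg$n_case_samples < 3L)
    stop("degenerate design: need >= 1 control and >= 2 case samples")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  planted <- 4L * cfg$n_module_genes + cfg$n_switch_genes + 1L +
    2L * cfg$n_hub_targets + cfg$n_nuisance_genes +
    round(cfg$mito_gene_fraction * cfg$n_genes)
  if (planted > cfg$n_genes)
    stop("n_genes too small for the requested planted structure")
  if (cfg$n_events < 2L * cfg$n_driver_targets + 4L)
    stop("n_events too small: need driver + targets + MX pair + null events")
  class(cfg) <- "SimConfig"
  cfg
}

## clinical scores for case samples; the default six-case design mirrors a
## 3 S / 1 intermediate / 2 L patient panel (scores 1..5, controls 0)
case_scores <- function(n) {
  if (n == 6L) return(c(1L, 2L, 2L, 3L, 4L, 5L))
  pmin(5L, pmax(1L, as.integer(round(seq(1, 5, length.out = n)))))
}

group_of_score <- function(score) {
  ifelse(score == 0L, "control",
         ifelse(score <= 2L, "S", ifelse(score == 3L, "intermediate", "L")))
}

## module archetype mean curves on the log scale, evaluated at pseudo-severity
module_archetype <- function(m, t) {
  switch(m,
         `1` = exp(-((t - 0.2) / 0.12)^2),        # up early, then decay
         `2` = -stats::plogis((t - 0.25) / 0.10), # rapid early downregulation
         `3` = stats::plogis((t - 0.7) / 0.06),   # up late
         `4` = -stats::plogis((t - 0.7) / 0.06))  # down late
}

#' Simulate a synthetic ENCC severity dataset with ground truth
#'
#' See [sim_config()] for the planted structure. Counts are drawn
#' negative-binomial around a compositional mean (per-cell library size times
#' relative gene abundance, with severity/nuisance effects acting
#' multiplicatively on the log-mean), then thinned by dropout. PSI values are
#' Beta-distributed around logistic means; the driver event rises with
#' severity, target events are coupled to the driver's realized PSI on the
#' logit scale, and the mutually exclusive pair is (driver PSI, 1 - driver
#' PSI) exactly.
#'
#' @param config a `SimConfig` from [sim_config()].
#' @return list with `matrix` (ExpressionMatrix), `annotation` (data.frame),
#'   `psi` (PsiMatrix), `truth` (SimulationTruth list) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config

  ## ---- samples and cells -------------------------------------------------
  ctrl_ids <- paste0("CTRL", seq_len(cfg$n_control_samples))
  case_ids <- paste0("HSCR", seq_len(cfg$n_case_samples))
  scores <- c(rep(0L, cfg$n_control_samples), case_scores(cfg$n_case_samples))
  samples <- data.frame(sample_id = c(ctrl_ids, case_ids),
                        clinical_score = scores,
                        group = group_of_score(scores),
                        severity = scores / 5,
                        stringsAsFactors = FALSE)
  n_cells <- nrow(samples) * cfg$cells_per_sample
  cell_sample <- rep(samples$sample_id, each = cfg$cells_per_sample)
  cell_ids <- paste0(cell_sample, "_c",
                     rep(seq_len(cfg$cells_per_sample), times = nrow(samples)))

  set.seed(derive_seed(cfg$seed, "severity"))
  t_cell <- rep(samples$severity, each = cfg$cells_per_sample) +
    stats::rnorm(n_cells, 0, cfg$severity_jitter_sd)
  t_cell <- pmin(1, pmax(0, t_cell))

  ## ---- gene roles ---------------------------------------------------------
  n_mito <- round(cfg$mito_gene_fraction * cfg$n_genes)
  roles <- rep("none", cfg$n_genes)
  idx <- 1L
  take <- function(k) { out <- idx:(idx + k - 1L); idx <<- idx + k; out }
  mod_idx <- lapply(1:4, function(m) take(cfg$n_module_genes))
  switch_idx <- if (cfg$n_switch_genes) take(cfg$n_switch_genes) else integer(0)
  hub_idx <- take(1L)
  act_idx <- if (cfg$n_hub_targets) take(cfg$n_hub_targets) else integer(0)
  rep_idx <- if (cfg$n_hub_targets) take(cfg$n_hub_targets) else integer(0)
  nui_idx <- if (cfg$n_nuisance_genes) take(cfg$n_nuisance_genes) else integer(0)
  mito_idx <- if (n_mito) take(n_mito) else integer(0)
  gene_ids <- paste0("G", formatC(seq_len(cfg$n_genes), width = 4, flag = "0"))
  gene_ids[mito_idx] <- paste0("MT-", gene_ids[mito_idx])
  for (m in 1:4) roles[mod_idx[[m]]] <- paste0("module", m)
  roles[switch_idx] <- "switch"; roles[hub_idx] <- "hub"
  roles[act_idx] <- "hub_activated"; roles[rep_idx] <- "hub_repressed"
  roles[nui_idx] <- "nuisance"; roles[mito_idx] <- "mito"

  ## ---- expression ---------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "expression"))
  abund <- exp(stats::rnorm(cfg$n_genes, 0, 1.2))
  ## planted dynamic genes emulate detectably expressed DEGs: their baseline
  ## abundance is drawn from the upper range so dropout does not censor the
  ## planted dynamics (see vignette)
  effect_idx <- c(unlist(mod_idx), switch_idx, hub_idx, act_idx, rep_idx)
  abund[effect_idx] <- exp(stats::rnorm(length(effect_idx), 0.8, 0.6))
  if (n_mito) { # fix the expected mitochondrial share
    f <- cfg$mito_gene_fraction
    abund[mito_idx] <- abund[mito_idx] *
      (f / (1 - f)) * sum(abund[-mito_idx]) / sum(abund[mito_idx])
  }
  eta <- matrix(0, nrow = cfg$n_genes, ncol = n_cells)
  es <- cfg$effect_size
  for (m in 1:4)
    eta[mod_idx[[m]], ] <- matrix(rep(es * module_archetype(m, t_cell),
                                      each = cfg$n_module_genes),
                                  nrow = cfg$n_module_genes)
  switch_center <- switch_dir <- NULL
  if (length(switch_idx)) {
    ## switch positions are only estimable where cells populate the axis, so
    ## centers are planted inside the jitter range of interior case samples
    interior <- samples$severity[samples$severity > 0.1 & samples$severity < 0.9]
    if (!length(interior)) interior <- 0.5
    switch_center <- sample(interior, length(switch_idx), replace = TRUE) +
      stats::runif(length(switch_idx), -0.02, 0.02)
    switch_dir <- rep(c("up", "down"), length.out = length(switch_idx))
    for (i in seq_along(switch_idx)) {
      s <- if (switch_dir[i] == "up") 1 else -1
      ## switch-like genes carry the sharpest, strongest changes: a near-step
      ## logistic at twice the module amplitude
      eta[switch_idx[i], ] <- s * 2 * es * stats::plogis((t_cell - switch_center[i]) / 0.008)
    }
  }
  hub_latent <- t_cell + stats::rnorm(n_cells, 0, 0.08)
  eta[hub_idx, ] <- es * hub_latent
  if (length(act_idx))
    eta[act_idx, ] <- matrix(rep(es * hub_latent, each = length(act_idx)),
                             nrow = length(act_idx))
  if (length(rep_idx))
    eta[rep_idx, ] <- matrix(rep(-es * hub_latent, each = length(rep_idx)),
                             nrow = length(rep_idx))
  if (length(nui_idx)) {
    u <- stats::rnorm(n_cells)
    ## balanced signs, and the block's total mass is held constant per cell
    ## below, so the nuisance contrasts genes against each other without
    ## leaking into every other gene through the compositional step
    sgn <- rep(c(1, -1), length.out = length(nui_idx))
    eta[nui_idx, ] <- sgn %o% (cfg$nuisance_amplitude * u)
  }
  W <- abund * exp(eta)
  if (length(nui_idx)) {
    block <- W[nui_idx, , drop = FALSE]
    W[nui_idx, ] <- sweep(block, 2L, colSums(block), "/") * sum(abund[nui_idx])
  }
  prop <- sweep(W, 2L, colSums(W), "/")
  libsize <- stats::rlnorm(n_cells, log(cfg$library_size_mean), 0.3)
  mu <- sweep(prop, 2L, libsize, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / cfg$nb_dispersion),
                   nrow = cfg$n_genes)
  if (cfg$dropout_rate > 0) {
    ## abundance-dependent dropout: low-expression measurements vanish with
    ## probability dropout_rate, well-expressed ones are essentially safe
    p_drop <- cfg$dropout_rate * exp(-as.vector(mu) / 5)
    keep <- stats::runif(length(counts)) >= p_drop
    counts <- counts * keep
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gene_ids, cell_ids)
  mat <- expression_matrix(counts)

  ## ---- annotation (paper-scale QC covariates; see vignette) --------------
  set.seed(derive_seed(cfg$seed, "annotation"))
  n_detect <- as.integer(round(pmin(8800, pmax(3200, stats::rnorm(n_cells, 6000, 700)))))
  mito_frac <- if (n_mito)
    colSums(counts[mito_idx, , drop = FALSE]) / pmax(colSums(counts), 1)
  else rep(0.01, n_cells)
  umr <- as.integer(round(stats::rlnorm(n_cells, log(5e4), 0.2)))
  splice_rate <- pmax(0.05, 0.12 + 0.08 * t_cell + stats::rnorm(n_cells, 0, 0.01))
  n_splices <- as.integer(round(umr * splice_rate))
  n_fail <- round(cfg$qc_fail_fraction * n_cells)
  qc_fail <- data.frame(cell_id = character(0), mode = character(0),
                        stringsAsFactors = FALSE)
  if (n_fail > 0) {
    fail_cells <- sort(sample.int(n_cells, n_fail))
    modes <- rep(c("low_genes", "high_genes", "high_mito"),
                 length.out = n_fail)
    for (i in seq_len(n_fail)) {
      j <- fail_cells[i]
      if (modes[i] == "low_genes")
        n_detect[j] <- as.integer(round(stats::runif(1, 500, 2900)))
      else if (modes[i] == "high_genes")
        n_detect[j] <- as.integer(round(stats::runif(1, 9100, 12000)))
      else mito_frac[j] <- stats::runif(1, 0.25, 0.6)
    }
    qc_fail <- data.frame(cell_id = cell_ids[fail_cells], mode = modes,
                          stringsAsFactors = FALSE)
  }
  ann <- data.frame(cell_id = cell_ids, sample_id = cell_sample,
                    group = rep(samples$group, each = cfg$cells_per_sample),
                    clinical_score = rep(samples$clinical_score,
                                         each = cfg$cells_per_sample),
                    n_genes_detected = n_detect,
                    mito_fraction = as.numeric(mito_frac),
                    uniquely_mapped_reads = umr, n_splices = n_splices,
                    stringsAsFactors = FALSE)
  ann <- validate_annotation(ann, cell_ids = cell_ids)

  ## ---- splicing layer -----------------------------------------------------
  set.seed(derive_seed(cfg$seed, "psi"))
  ne <- cfg$n_events
  event_ids <- paste0("E", formatC(seq_len(ne), width = 3, flag = "0"))
  driver <- event_ids[1L]
  enh_idx <- 1L + seq_len(cfg$n_driver_targets)
  repr_idx <- max(enh_idx) + seq_len(cfg$n_driver_targets)
  mxe_idx <- max(repr_idx) + 1:2
  null_idx <- setdiff(seq_len(ne), c(1L, enh_idx, repr_idx, mxe_idx))
  types <- rep("SE", ne)
  types[mxe_idx] <- "MX"
  types[null_idx] <- rep(c("SE", "A5", "A3", "MX", "RI", "AF", "AL"),
                         length.out = length(null_idx))
  ev_gene <- gene_ids[1L + (seq_len(ne) - 1L) %% cfg$n_genes]
  ev_gene[1L] <- gene_ids[mod_idx[[3]][1L]]  # driver sits in an up-late splicing gene
  events <- data.frame(event_id = event_ids, gene_id = ev_gene, type = types,
                       inclusion_isoforms = paste0(event_ids, ".i1"),
                       total_isoforms = paste0(event_ids, ".i1,", event_ids, ".i2"),
                       stringsAsFactors = FALSE)
  conc <- cfg$psi_concentration
  rbeta_mean <- function(m) {
    m <- pmin(1 - 1e-6, pmax(1e-6, m))
    stats::rbeta(length(m), m * conc, (1 - m) * conc)
  }
  esp <- cfg$psi_effect_size %||% es
  driver_mean <- 0.3 + 0.4 * stats::plogis(esp * (t_cell - 0.5) / 0.12)
  if (esp == 0) driver_mean <- rep(0.5, n_cells)
  psi <- matrix(NA_real_, nrow = ne, ncol = n_cells,
                dimnames = list(event_ids, cell_ids))
  psi[1L, ] <- rbeta_mean(driver_mean)
  dlogit <- stats::qlogis(pmin(1 - 1e-4, pmax(1e-4, psi[1L, ])))
  for (i in enh_idx)
    psi[i, ] <- rbeta_mean(stats::plogis(stats::rnorm(1, 0, 0.5) + dlogit))
  for (i in repr_idx)
    psi[i, ] <- rbeta_mean(stats::plogis(stats::rnorm(1, 0, 0.5) - dlogit))
  psi[mxe_idx[1L], ] <- psi[1L, ]        # MX pair coupled exactly to the driver
  psi[mxe_idx[2L], ] <- 1 - psi[1L, ]
  for (i in null_idx)
    psi[i, ] <- rbeta_mean(rep(stats::runif(1, 0.2, 0.8), n_cells))
  if (cfg$psi_missing_rate > 0) {
    miss <- matrix(stats::runif(length(psi)) < cfg$psi_missing_rate,
                   nrow = ne)
    miss[mxe_idx[2L], ] <- miss[mxe_idx[1L], ]  # pair shares its mask
    psi[miss] <- NA_real_
  }
  psim <- psi_matrix(psi, events)

  dtc <- rep("none", ne); names(dtc) <- event_ids
  dtc[enh_idx] <- "enhanced"; dtc[repr_idx] <- "repressed"
  dtc[mxe_idx[1L]] <- "enhanced"; dtc[mxe_idx[2L]] <- "repressed"
  dtc[1L] <- "none"  # the driver is not its own target
  motif_events <- c(event_ids[c(enh_idx, repr_idx, mxe_idx)],
                    event_ids[utils::head(null_idx, 10L)])

  ## ---- truth --------------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "evidence"))
  module_label <- rep("none", cfg$n_genes); names(module_label) <- gene_ids
  for (m in 1:4) module_label[mod_idx[[m]]] <- as.character(m)
  hub_target_class <- rep("none", cfg$n_genes); names(hub_target_class) <- gene_ids
  hub_target_class[act_idx] <- "activated"; hub_target_class[rep_idx] <- "repressed"
  target_genes <- gene_ids[c(act_idx, rep_idx)]
  decoys <- sample(gene_ids[roles == "none"],
                   min(20L, sum(roles == "none")))
  binding_genes <- sort(c(target_genes, decoys))
  motif_hits <- stats::setNames(stats::rpois(cfg$n_genes, 0.3), gene_ids)
  motif_hits[target_genes] <- 2L + stats::rpois(length(target_genes), 2)

  sc <- stats::setNames(rep(NA_real_, cfg$n_genes), gene_ids)
  sd_ <- stats::setNames(rep(NA_character_, cfg$n_genes), gene_ids)
  if (length(switch_idx)) {
    sc[switch_idx] <- switch_center; sd_[switch_idx] <- switch_dir
  }
  truth <- list(
    sample_severity = stats::setNames(samples$severity, samples$sample_id),
    cell_severity = stats::setNames(t_cell, cell_ids),
    module_label = module_label,
    switch_center = sc[switch_idx], switch_direction = sd_[switch_idx],
    hub_gene = gene_ids[hub_idx], hub_target_class = hub_target_class,
    driver_event = driver, driver_target_class = dtc,
    mxe_pair = event_ids[mxe_idx],
    binding_genes = binding_genes, motif_gene_hits = motif_hits,
    motif_target_events = sort(motif_events),
    gene_role = stats::setNames(roles, gene_ids),
    qc_fail = qc_fail)

  list(matrix = mat, annotation = ann, psi = psim, truth = truth, config = cfg)
}

fmt_full <- function(x) {
  if (is.double(x)) vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1L))
  else as.character(x)
}

write_tsv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- fmt_full(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
}

#' Write a simulated dataset as a plain-text fixture directory
#'
#' Six files: `counts.mtx`, `genes.tsv`, `cells.tsv`, `annotation.tsv`,
#' `psi.tsv` (event metadata followed by per-cell PSI, full precision) and
#' `truth.tsv` (long-format ground truth). [read_fixture()] reverses this
#' exactly; generation with a fixed seed is byte-stable.
#'
#' @param dataset output of [simulate_dataset()].
#' @param out_dir directory to create.
#' @export
write_fixture <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mtx(dataset$matrix$counts, out_dir)
  write_tsv_full(dataset$annotation, file.path(out_dir, "annotation.tsv"))
  psi_df <- cbind(dataset$psi$events,
                  as.data.frame(dataset$psi$psi, check.names = FALSE))
  write_tsv_full(psi_df, file.path(out_dir, "psi.tsv"))
  tr <- dataset$truth
  kv <- function(section, key, value)
    data.frame(section = section, key = key, value = fmt_full(value),
               stringsAsFactors = FALSE)
  truth_df <- rbind(
    kv("sample_severity", names(tr$sample_severity), tr$sample_severity),
    kv("cell_severity", names(tr$cell_severity), tr$cell_severity),
    kv("module_label", names(tr$module_label), tr$module_label),
    if (length(tr$switch_center))
      kv("switch_center", names(tr$switch_center), tr$switch_center),
    if (length(tr$switch_direction))
      kv("switch_direction", names(tr$switch_direction), tr$switch_direction),
    kv("hub_gene", "hub", tr$hub_gene),
    kv("hub_target_class", names(tr$hub_target_class), tr$hub_target_class),
    kv("driver_event", "driver", tr$driver_event),
    kv("driver_target_class", names(tr$driver_target_class), tr$driver_target_class),
    kv("mxe_pair", c("first", "second"), tr$mxe_pair),
    kv("binding_genes", tr$binding_genes, tr$binding_genes),
    kv("motif_gene_hits", names(tr$motif_gene_hits), tr$motif_gene_hits),
    kv("motif_target_events", tr$motif_target_events, tr$motif_target_events),
    kv("gene_role", names(tr$gene_role), tr$gene_role),
    if (nrow(tr$qc_fail)) kv("qc_fail", tr$qc_fail$cell_id, tr$qc_fail$mode))
  write_tsv_full(truth_df, file.path(out_dir, "truth.tsv"))
  invisible(out_dir)
}

#' Read back a fixture directory written by [write_fixture()]
#' @param dir fixture directory.
#' @return list with the same shape as [simulate_dataset()] output (without
#'   `config`).
#' @export
read_fixture <- function(dir) {
  ex <- read_expression(file.path(dir, "counts.mtx"),
                        file.path(dir, "annotation.tsv"), format = "mtx")
  psi_df <- utils::read.delim(file.path(dir, "psi.tsv"), check.names = FALSE,
                              na.strings = "NA")
  meta_cols <- c("event_id", "gene_id", "type", "inclusion_isoforms",
                 "total_isoforms")
  events <- psi_df[, meta_cols, drop = FALSE]
  psi <- as.matrix(psi_df[, setdiff(names(psi_df), meta_cols), drop = FALSE])
  rownames(psi) <- events$event_id
  tru <- utils::read.delim(file.path(dir, "truth.tsv"), check.names = FALSE,
                           colClasses = "character")
  pick <- function(section) {
    sub <- tru[tru$section == section, , drop = FALSE]
    stats::setNames(sub$value, sub$key)
  }
  num <- function(x) stats::setNames(as.numeric(x), names(x))
  qf <- tru[tru$section == "qc_fail", , drop = FALSE]
  truth <- list(
    sample_severity = num(pick("sample_severity")),
    cell_severity = num(pick("cell_severity")),
    module_label = pick("module_label"),
    switch_center = num(pick("switch_center")),
    switch_direction = pick("switch_direction"),
    hub_gene = unname(pick("hub_gene")),
    hub_target_class = pick("hub_target_class"),
    driver_event = unname(pick("driver_event")),
    driver_target_class = pick("driver_target_class"),
    mxe_pair = unname(pick("mxe_pair")),
    binding_genes = unname(pick("binding_genes")),
    motif_gene_hits = num(pick("motif_gene_hits")),
    motif_target_events = unname(pick("motif_target_events")),
    gene_role = pick("gene_role"),
    qc_fail = data.frame(cell_id = qf$key, mode = qf$value,
                         stringsAsFactors = FALSE))
  list(matrix = ex$matrix, annotation = ex$annotation,
       psi = psi_matrix(psi, events), truth = truth)
}

#' Configuration for the small committed fixture (20 genes x 60 cells,
#' 6 events, 5 planted QC failures)
#' @param seed master seed (default 20).
#' @return a `SimConfig`.
#' @export
small_fixture_config <- function(seed = 20L) {
  sim_config(n_control_samples = 1L, n_case_samples = 2L,
             cells_per_sample = 20L, n_genes = 20L, n_module_genes = 2L,
             n_switch_genes = 2L, n_hub_targets = 2L, n_events = 6L,
             n_driver_targets = 1L, n_nuisance_genes = 2L,
             mito_gene_fraction = 0.05, library_size_mean = 5000L,
             qc_fail_fraction = 5 / 60, seed = seed)
}
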