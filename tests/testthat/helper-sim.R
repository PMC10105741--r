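## Shared fixtures for the whole suite. Default-config simulations are
## expensive (1500 genes x 1600 cells), so the ten seeds used by the
## acceptance criteria are built once and cached; every test file reuses
## them through cached_sim().

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    ds <- quietly(simulate_dataset(sim_config(seed = seed)))
    fc <- quietly(filter_cells(ds$matrix, ds$annotation))
    mat <- quietly(filter_genes(fc$matrix))
    mat <- normalize_expression(mat)
    ann <- fc$annotation
    psi <- psi_matrix(ds$psi$psi[, ann$cell_id, drop = FALSE], ds$psi$events)
    axis <- quietly(build_severity_axis(mat, ann))
    .sim_cache[[key]] <- list(mat = mat, ann = ann, psi = psi,
                              truth = ds$truth, axis = axis)
  }
  .sim_cache[[key]]
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))

fixture_dir <- function() {
  d <- system.file("extdata", "fixture_small", package = "enccSeverity")
  if (!nzchar(d)) d <- file.path("..", "..", "inst", "extdata", "fixture_small")
  d
}

## a small deterministic expression matrix with grouped annotation, used by
## the contract tests that do not need the full generator
toy_dataset <- function(seed = 42L, n_per_sample = 30L, n_genes = 40L,
                        samples = c(CTRLA = "control", CTRLB = "control",
                                    CASE1 = "S")) {
  set.seed(seed)
  n_cells <- n_per_sample * length(samples)
  sample_id <- rep(names(samples), each = n_per_sample)
  counts <- matrix(rpois(n_genes * n_cells, lambda = 20), nrow = n_genes,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   paste0(sample_id, "_", seq_len(n_cells))))
  ann <- data.frame(cell_id = colnames(counts), sample_id = sample_id,
                    group = rep(unname(samples), each = n_per_sample),
                    clinical_score = rep(ifelse(samples == "control", 0L, 2L),
                                         each = n_per_sample),
                    n_genes_detected = 5000L, mito_fraction = 0.05,
                    uniquely_mapped_reads = 50000L, n_splices = 6000L,
                    stringsAsFactors = FALSE)
  list(mat = normalize_expression(expression_matrix(counts)), ann = ann)
}
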