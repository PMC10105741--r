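## construct a two-factor matrix: a severity-orthogonal nuisance factor on a
## LARGER gene block (genes are scaled to unit variance before PCA, so the
## block size, not the amplitude, decides the variance ranking) and a
## clinical-score-linked factor on a smaller block
two_factor_matrix <- function(seed = 1L, n_cells = 120L, noise = 0.3) {
  set.seed(seed)
  clin <- rep(c(0L, 0L, 1L, 3L, 5L), length.out = n_cells)
  u <- rnorm(n_cells)
  sev <- scale(clin)[, 1L]
  X <- rbind(matrix(rep(u, each = 55), nrow = 55),
             matrix(rep(sev, each = 25), nrow = 25)) +
    matrix(rnorm(80 * n_cells, 0, noise), nrow = 80)
  dimnames(X) <- list(sprintf("g%02d", 1:80), paste0("c", seq_len(n_cells)))
  ann <- data.frame(cell_id = colnames(X), sample_id = paste0("s", clin),
                    group = ifelse(clin == 0, "control", "S"),
                    clinical_score = clin, n_genes_detected = 5000L,
                    mito_fraction = 0.05, uniquely_mapped_reads = 1000L,
                    n_splices = 100L, stringsAsFactors = FALSE)
  ## wrap as an ExpressionMatrix with the lognorm layer set directly
  mat <- expression_matrix(matrix(1, 80, n_cells,
                                  dimnames = dimnames(X)))
  mat$lognorm <- X
  list(mat = mat, ann = ann, u = u, sev = sev)
}

test_that("fit_pca recovers a planted dominant factor and is orthonormal", {
  tf <- two_factor_matrix()
  p <- quietly(fit_pca(tf$mat, n_pcs = 5L, n_hvg = 80L))
  expect_gt(abs(cor(p$scores[, 1L], tf$u, method = "spearman")), 0.95)
  expect_equal(crossprod(p$loadings), diag(5L), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## sign convention: largest-magnitude loading positive
  for (j in 1:5) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("duplicated cells receive identical scores", {
  tf <- two_factor_matrix(n_cells = 60L)
  mat <- tf$mat
  dup <- mat$lognorm[, c(seq_len(60L), 1L)]
  colnames(dup) <- c(colnames(mat$lognorm), "c1dup")
  m2 <- expression_matrix(matrix(1, 80, 61, dimnames = dimnames(dup)))
  m2$lognorm <- dup
  p <- quietly(fit_pca(m2, n_pcs = 3L, n_hvg = 80L))
  expect_equal(p$scores["c1", ], p$scores["c1dup", ], tolerance = 1e-8)
})

test_that("select_severity_pc picks the severity PC despite a larger nuisance", {
  tf <- two_factor_matrix()
  p <- quietly(fit_pca(tf$mat, n_pcs = 5L, n_hvg = 80L))
  ax <- quietly(select_severity_pc(p, tf$ann))
  expect_equal(ax$pc_index, 2L)
  expect_gt(ax$selection_correlation, 0.9)
  ## controls sit low
  med <- tapply(ax$pseudo_severity, tf$ann$group, median)
  expect_lt(med[["control"]], med[["S"]])
})

test_that("pseudo-severity is invariant to orientation flips and affine maps", {
  tf <- two_factor_matrix()
  p <- quietly(fit_pca(tf$mat, n_pcs = 3L, n_hvg = 80L))
  ax <- quietly(select_severity_pc(p, tf$ann))
  p_flip <- p; p_flip$scores <- -p$scores; p_flip$loadings <- -p$loadings
  ax_flip <- quietly(select_severity_pc(p_flip, tf$ann))
  expect_equal(ax_flip$pseudo_severity, ax$pseudo_severity, tolerance = 1e-12)
  p_aff <- p; p_aff$scores <- 3.7 * p$scores + 2
  ax_aff <- quietly(select_severity_pc(p_aff, tf$ann))
  expect_equal(ax_aff$pseudo_severity, ax$pseudo_severity, tolerance = 1e-12)
})

test_that("a perfectly monotone toy axis yields selection correlation 1", {
  ## tie-free clinical scores: one cell per score level
  n <- 6L
  clin <- 0:5
  scores <- matrix(seq_len(n), ncol = 1L,
                   dimnames = list(paste0("c", 1:n), "PC1"))
  ann <- data.frame(cell_id = rownames(scores), sample_id = paste0("s", clin),
                    group = ifelse(clin == 0, "control", "S"),
                    clinical_score = clin, n_genes_detected = 5000L,
                    mito_fraction = 0, uniquely_mapped_reads = 1L,
                    n_splices = 0L)
  ax <- quietly(select_severity_pc(list(scores = scores), ann))
  expect_equal(ax$selection_correlation, 1.0, tolerance = 1e-12)
  ann$clinical_score <- 2L
  ann$group <- "S"
  expect_error(select_severity_pc(list(scores = scores), ann), "severity contrast")
})

test_that("group_axis_test behaves at the null and at full separation", {
  n <- 20L
  ps <- c(seq(0, 0.4, length.out = n), seq(0.6, 1, length.out = n))
  ann <- data.frame(cell_id = paste0("c", 1:(2 * n)),
                    sample_id = rep(c("a", "b"), each = n),
                    group = rep(c("S", "L"), each = n),
                    clinical_score = rep(c(1L, 5L), each = n),
                    n_genes_detected = 5000L, mito_fraction = 0,
                    uniquely_mapped_reads = 1L, n_splices = 0L)
  axis <- structure(list(pseudo_severity = setNames(ps, ann$cell_id)),
                    class = "SeverityAxis")
  ## disjoint supports, n = 20 vs 20
  r <- group_axis_test(axis, ann, "S", "L")
  expect_lt(r$p_value, 1e-6)
  ## identical groups: the label split within one support
  axis2 <- axis; axis2$pseudo_severity[] <- rep(ps[1:n], 2L)
  r2 <- group_axis_test(axis2, ann, "S", "L")
  expect_gt(r2$p_value, 0.9)
})

test_that("axis is stable under removal of a random 10% of cells", {
  cs <- cached_sim(1L)
  set.seed(99)
  keep <- sample(cs$mat$cell_ids, round(0.9 * length(cs$mat$cell_ids)))
  mat_sub <- enccSeverity:::subset_matrix(cs$mat, cells = keep)
  ann_sub <- cs$ann[match(keep, cs$ann$cell_id), ]
  ax_sub <- quietly(build_severity_axis(mat_sub, ann_sub))
  med_full <- tapply(cs$axis$pseudo_severity,
                     cs$ann$sample_id[match(names(cs$axis$pseudo_severity),
                                            cs$ann$cell_id)], median)
  med_sub <- tapply(ax_sub$pseudo_severity,
                    ann_sub$sample_id[match(names(ax_sub$pseudo_severity),
                                            ann_sub$cell_id)], median)
  expect_lt(max(abs(med_full - med_sub[names(med_full)])), 0.05)
})

test_that("TCA samples are excluded from axis construction by default", {
  cs <- cached_sim(1L)
  ann <- cs$ann
  ann$group[ann$sample_id == "HSCR6"] <- "TCA"
  ann$clinical_score[ann$sample_id == "HSCR6"] <- 5L
  ax <- quietly(build_severity_axis(cs$mat, ann))
  expect_false(any(grepl("^HSCR6", names(ax$pseudo_severity))))
  ax_all <- quietly(build_severity_axis(cs$mat, ann, exclude_tca = FALSE))
  expect_true(any(grepl("^HSCR6", names(ax_all$pseudo_severity))))
})
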