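make_ann <- function(n_genes_detected, mito_fraction) {
  n <- length(n_genes_detected)
  data.frame(cell_id = paste0("c", seq_len(n)), sample_id = "s1",
             group = "control", clinical_score = 0L,
             n_genes_detected = n_genes_detected,
             mito_fraction = mito_fraction,
             uniquely_mapped_reads = 1000L, n_splices = 100L,
             stringsAsFactors = FALSE)
}

mat_for <- function(ann, n_genes = 5L) {
  set.seed(1)
  expression_matrix(matrix(rpois(n_genes * nrow(ann), 5) + 1, nrow = n_genes,
                           dimnames = list(paste0("g", seq_len(n_genes)),
                                           ann$cell_id)))
}

test_that("filter_cells applies strict exclusion bounds (boundaries retained)", {
  ann <- make_ann(c(2999L, 3000L, 9000L, 9001L, 5000L, 5000L),
                  c(0.1, 0.20, 0.1, 0.1, 0.21, 0.1))
  fc <- quietly(filter_cells(mat_for(ann), ann))
  ## 2999 genes -> removed; exactly 3000 with 20% mito -> retained;
  ## 9000 retained; 9001 removed; 21% mito removed
  expect_setequal(fc$annotation$cell_id, c("c2", "c3", "c6"))
  ## all-removed is fatal with per-criterion tallies
  ann_bad <- make_ann(c(100L, 100L), c(0.5, 0.5))
  expect_error(quietly(filter_cells(mat_for(ann_bad), ann_bad)), "all cells removed")
})

test_that("QC filters reproduce the committed fixture's survivor set and are idempotent", {
  fx <- quietly(read_fixture(fixture_dir()))
  ann <- fx$annotation
  ## independent row-by-row oracle over the annotation
  keep_oracle <- vapply(seq_len(nrow(ann)), function(i) {
    a <- ann[i, ]
    a$n_genes_detected >= 3000 && a$n_genes_detected <= 9000 &&
      a$mito_fraction <= 0.20
  }, logical(1L))
  expect_equal(sum(!keep_oracle), 5L)  # the five planted failures
  expect_setequal(ann$cell_id[!keep_oracle], fx$truth$qc_fail$cell_id)

  fc <- quietly(filter_cells(fx$matrix, ann))
  expect_setequal(fc$annotation$cell_id, ann$cell_id[keep_oracle])

  ## idempotence of both filters
  fc2 <- quietly(filter_cells(fc$matrix, fc$annotation))
  expect_equal(fc2$matrix$counts, fc$matrix$counts)
  g1 <- quietly(filter_genes(fc$matrix, min_cells = 3L))
  g2 <- quietly(filter_genes(g1, min_cells = 3L))
  expect_equal(g2$counts, g1$counts)
})

test_that("filter_genes keeps genes detected in at least min_cells cells", {
  counts <- rbind(four = c(1, 1, 1, 1, 0, 0),
                  five = c(1, 1, 1, 1, 1, 0),
                  zero = rep(0, 6))
  colnames(counts) <- paste0("c", 1:6)
  mat <- expression_matrix(counts)
  kept <- quietly(filter_genes(mat, min_cells = 5L))
  expect_equal(kept$gene_ids, "five")
  allzero <- expression_matrix(matrix(0, 2, 3,
                                      dimnames = list(c("a", "b"), c("x", "y", "z"))))
  expect_warning(res <- quietly2 <- suppressMessages(filter_genes(allzero)),
                 "no genes")
  expect_equal(length(res$gene_ids), 0L)
})

test_that("filter_sample_unique_genes drops genes confined to one sample", {
  toy <- toy_dataset()
  mat <- toy$mat
  ## make gene g01 exclusive to sample CTRLA
  a_cells <- toy$ann$cell_id[toy$ann$sample_id == "CTRLA"]
  mat$counts["g01", ] <- 0
  mat$counts["g01", a_cells] <- 5
  out <- quietly(filter_sample_unique_genes(mat, toy$ann))
  expect_false("g01" %in% out$gene_ids)
  expect_true("g02" %in% out$gene_ids)
})

test_that("normalize_expression matches its closed form", {
  counts <- matrix(c(0, 1, 199999, 5, 2, 8), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  mat <- normalize_expression(expression_matrix(counts))
  expect_equal(mat$lognorm["g1", "c1"], 0)
  expect_equal(mat$lognorm["g2", "c1"], log(2))  # count 1 of 200000 at sf 2e5

  ## brute-force recomputation on a random 10x10 fixture
  set.seed(7)
  counts <- matrix(rpois(100, 30), 10,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  mat <- normalize_expression(expression_matrix(counts), scale_factor = 12345)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    oracle[i, j] <- log(1 + counts[i, j] / sum(counts[, j]) * 12345)
  expect_equal(unname(mat$lognorm), oracle, tolerance = 1e-12)

  ## zero pattern and within-cell ordering preserved (monotone transform)
  expect_equal(mat$lognorm == 0, counts == 0)
  for (j in 1:10)
    expect_equal(order(mat$lognorm[, j]), order(counts[, j]))
})

test_that("rank_sum_rows agrees with stats::wilcox.test", {
  set.seed(11)
  M <- matrix(rnorm(5 * 40), nrow = 5)
  M[2, ] <- round(M[2, ])  # force ties
  ia <- 1:15; ib <- 16:40
  rs <- enccSeverity:::rank_sum_rows(M, ia, ib)
  for (i in 1:5) {
    w <- suppressWarnings(wilcox.test(M[i, ia], M[i, ib], exact = FALSE,
                                      correct = TRUE))
    expect_equal(rs$statistic[i], unname(w$statistic))
    expect_equal(rs$p_value[i], w$p.value, tolerance = 1e-10)
  }
})

test_that("consensus_deg requires agreement against both controls", {
  toy <- toy_dataset(seed = 5L)
  mat <- toy$mat; ann <- toy$ann
  case_cells <- ann$cell_id[ann$sample_id == "CASE1"]
  b_cells <- ann$cell_id[ann$sample_id == "CTRLB"]
  ## g05: shifted strongly vs both controls (recovered, direction up)
  mat$lognorm["g05", case_cells] <- mat$lognorm["g05", case_cells] + 2
  ## g06: shifted vs CTRLA only (its CTRLB cells shifted along) -> absent
  mat$lognorm["g06", c(case_cells, b_cells)] <-
    mat$lognorm["g06", c(case_cells, b_cells)] + 2
  deg <- quietly(consensus_deg(mat, ann, "CASE1", c("CTRLA", "CTRLB")))
  expect_true("g05" %in% deg$gene_id)
  expect_equal(deg$direction[deg$gene_id == "g05"], "up")
  expect_false("g06" %in% deg$gene_id)

  ## identical case and controls -> empty
  toy2 <- toy_dataset(seed = 6L)
  deg0 <- quietly(consensus_deg(toy2$mat, toy2$ann, "CASE1",
                                c("CTRLA", "CTRLB")))
  expect_equal(nrow(deg0), 0L)

  ## control with < 3 cells is fatal
  ann_small <- ann[!(ann$sample_id == "CTRLB" & seq_len(nrow(ann)) > 2L), ]
  keep <- ann$cell_id %in% ann_small$cell_id
  expect_error(quietly(consensus_deg(
    subset_mat <- enccSeverity:::subset_matrix(mat, cells = ann$cell_id[keep]),
    ann[keep, ], "CASE1", c("CTRLA", "CTRLB"))), "fewer than 3")
})

test_that("planted consensus DEGs are recovered from the generator", {
  cs <- cached_sim(1L)
  ctrl <- unique(cs$ann$sample_id[cs$ann$group == "control"])
  deg <- quietly(consensus_deg(cs$mat, cs$ann,
                               unique(cs$ann$sample_id[cs$ann$group == "L"]),
                               ctrl))
  ## late modules and hub targets change most in L cells
  m3 <- names(cs$truth$module_label)[cs$truth$module_label == "3"]
  expect_gt(mean(m3 %in% deg$gene_id), 0.9)
  expect_equal(unique(deg$direction[deg$gene_id %in% m3]), "up")
})
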