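corr_mat <- function(X) {
  m <- expression_matrix(matrix(1, nrow(X), ncol(X), dimnames = dimnames(X)))
  m$lognorm <- X
  m
}

plain_ann <- function(cells, group = "S") {
  data.frame(cell_id = cells, sample_id = "s1", group = group,
             clinical_score = if (group == "control") 0L else 2L,
             n_genes_detected = 5000L, mito_fraction = 0.05,
             uniquely_mapped_reads = 1000L, n_splices = 100L,
             stringsAsFactors = FALSE)
}

test_that("condition_correlation hits the exact extremes", {
  set.seed(31)
  n <- 60L
  hub <- rnorm(n)
  X <- rbind(hub = hub, same = hub, anti = -hub, noise = rnorm(n))
  colnames(X) <- paste0("c", 1:n)
  cc <- condition_correlation(corr_mat(X), "hub", plain_ann(colnames(X)),
                              groups = "S")
  expect_false("hub" %in% cc$gene_id)
  expect_equal(cc$r[cc$gene_id == "same"], 1)
  expect_equal(cc$r[cc$gene_id == "anti"], -1)
  expect_equal(cc$p_value[cc$gene_id == "same"], 0)
  expect_error(condition_correlation(corr_mat(X), "zz", plain_ann(colnames(X))),
               "not in matrix")
  Xc <- X; Xc["hub", ] <- 1
  expect_error(condition_correlation(corr_mat(Xc), "hub",
                                     plain_ann(colnames(X))), "constant")
})

test_that("null correlations match the large-sample spread", {
  set.seed(32)
  n <- 200L
  X <- matrix(rnorm(2000 * n), nrow = 2000,
              dimnames = list(paste0("g", 1:2000), paste0("c", 1:n)))
  X <- rbind(hub = rnorm(n), X)
  cc <- condition_correlation(corr_mat(X), "hub", plain_ann(colnames(X)))
  q95 <- quantile(abs(cc$r), 0.95)
  expect_lt(abs(q95 - 1.96 / sqrt(n - 1)), 0.02)
})

test_that("classify_hub_targets applies the three-step filter and sign rule", {
  cors <- data.frame(
    gene_id = c("act", "rep", "nobind", "nodeg", "nocorr", "signclash"),
    r = c(0.6, -0.6, 0.7, 0.8, 0.05, 0.5),
    p_value = 1e-6, q_value = c(1e-4, 1e-4, 1e-4, 1e-4, 0.9, 1e-4),
    stringsAsFactors = FALSE)
  deg <- data.frame(gene_id = c("act", "rep", "nobind", "nocorr", "signclash"),
                    log2fc = c(1, -1, 1, 1, -1),
                    p_value = 1e-5, q_value = 1e-4,
                    direction = c("up", "down", "up", "up", "down"),
                    stringsAsFactors = FALSE)
  binding <- c("act", "rep", "nodeg", "nocorr", "signclash")
  calls <- classify_hub_targets(cors, deg, binding)
  got <- setNames(calls$call, calls$gene_id)
  expect_equal(got[["act"]], "activated")
  expect_equal(got[["rep"]], "repressed")
  expect_equal(got[["nobind"]], "none")   # correlated + DEG, no binding
  expect_equal(got[["nodeg"]], "none")
  expect_equal(got[["nocorr"]], "none")
  expect_equal(got[["signclash"]], "none") # r > 0 but downregulated
  fs <- setNames(calls$failed_step, calls$gene_id)
  expect_equal(fs[["nobind"]], "binding")
  expect_equal(fs[["nodeg"]], "deg")
  expect_equal(fs[["nocorr"]], "correlation")

  ## empty binding set: warn, everything none
  expect_warning(calls0 <- classify_hub_targets(cors, deg, character(0)),
                 "vacuously")
  expect_true(all(calls0$call == "none"))

  ## monotone in evidence: adding a gene to binding never removes a call
  calls2 <- classify_hub_targets(cors, deg, c(binding, "nobind"))
  prev <- calls$gene_id[calls$call != "none"]
  expect_true(all(calls2$call[match(prev, calls2$gene_id)] != "none"))
  expect_equal(setNames(calls2$call, calls2$gene_id)[["nobind"]], "activated")
})

test_that("motif_enrichment_test matches closed forms and symmetries", {
  ## table a=30 b=70 c=10 d=90 -> OR 27/7
  deg <- rep(c(TRUE, FALSE), c(100, 100))
  motif <- c(rep(c(TRUE, FALSE), c(30, 70)), rep(c(TRUE, FALSE), c(10, 90)))
  r <- motif_enrichment_test(deg, motif)
  expect_equal(r$odds_ratio, 27 / 7, tolerance = 1e-12)
  ## chi-square against the independent implementation
  cs <- suppressWarnings(chisq.test(table(deg, motif), correct = FALSE))
  expect_equal(r$p_value, cs$p.value, tolerance = 1e-10)
  ## label symmetry: swapping DEG flags inverts the OR exactly
  r_sw <- motif_enrichment_test(!deg, motif)
  expect_equal(r_sw$odds_ratio, 7 / 27, tolerance = 1e-12)
  ## zero cell: Haldane-Anscombe correction keeps the OR finite
  motif0 <- c(rep(FALSE, 100), rep(c(TRUE, FALSE), c(10, 90)))
  r0 <- motif_enrichment_test(deg, motif0)
  expect_equal(r0$odds_ratio, (0.5 * 90.5) / (100.5 * 10.5), tolerance = 1e-12)
  expect_error(motif_enrichment_test(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "degenerate")
})

test_that("chi-square p-values are uniform under independent flags", {
  set.seed(33)
  ps <- replicate(2000, {
    d <- runif(120) < 0.4
    m <- runif(120) < 0.3
    if (length(unique(d)) < 2L || length(unique(m)) < 2L) return(NA_real_)
    motif_enrichment_test(d, m)$p_value
  })
  ## chi-square at n=120 is approximately calibrated; KS against uniform
  expect_gt(suppressWarnings(ks.test(ps[!is.na(ps)], "punif"))$p.value, 0.01)
})
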