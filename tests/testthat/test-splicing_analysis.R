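test_that("as_frequency is splices over mapped reads with NA at zero reads", {
  ann <- data.frame(cell_id = c("a", "b", "c"), sample_id = "s",
                    group = "control", clinical_score = 0L,
                    n_genes_detected = 5000L, mito_fraction = 0,
                    uniquely_mapped_reads = c(1000L, 500L, 0L),
                    n_splices = c(100L, 0L, 10L))
  expect_warning(fr <- as_frequency(ann), "zero uniquely mapped")
  expect_equal(fr$as_frequency, c(0.1, 0, NA))
})

test_that("AS frequency rises with severity in the generator", {
  cs <- cached_sim(1L)
  fr <- as_frequency(cs$ann)
  grp <- cs$ann$group[match(fr$cell_id, cs$ann$cell_id)]
  r <- rank_sum_test(fr$as_frequency[grp == "L"],
                     fr$as_frequency[grp == "control"])
  expect_lt(r$p_value, 1e-3)
  expect_gt(median(fr$as_frequency[grp == "L"]),
            median(fr$as_frequency[grp == "control"]))
})

test_that("compute_psi follows the inclusion/total rule with a coverage floor", {
  ev <- splice_event("e1", "g1", "SE", "i1", c("i1", "i2"))
  expect_equal(compute_psi(c(i1 = 30, i2 = 10), ev), 0.75)
  expect_equal(compute_psi(c(i1 = 5, i2 = 0), ev), 1.0)
  expect_true(is.na(compute_psi(c(i1 = 0.3, i2 = 0.1), ev)))  # total 0.4 < 1
  expect_error(compute_psi(c(i1 = 3), ev), "i2")
})

test_that("compute_psi_matrix matches brute force and complementarity is exact", {
  set.seed(41)
  iso <- matrix(rexp(8 * 6, rate = 0.2), nrow = 8,
                dimnames = list(paste0("i", 1:8), paste0("c", 1:6)))
  events <- list(
    splice_event("e1", "g1", "SE", "i1", c("i1", "i2")),
    splice_event("e2", "g2", "MX", c("i3", "i4"), c("i3", "i4", "i5")),
    splice_event("e3", "g3", "RI", "i6", c("i6", "i7", "i8")))
  pm <- compute_psi_matrix(iso, events)
  for (e in events) for (j in 1:6) {
    tot <- sum(iso[e$total_isoforms, j])
    want <- if (tot < 1) NA_real_ else sum(iso[e$inclusion_isoforms, j]) / tot
    expect_equal(pm$psi[e$event_id, j], unname(want), tolerance = 1e-12)
  }
  ## swapped isoform sets give 1 - PSI exactly
  flip <- splice_event("e1f", "g1", "SE", "i2", c("i1", "i2"))
  pf <- compute_psi_matrix(iso, list(events[[1L]], flip))
  keep <- !is.na(pf$psi[1L, ])
  expect_equal(pf$psi["e1", keep] + pf$psi["e1f", keep],
               rep(1, sum(keep)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("differential_psi handles nulls, skips sparse events, finds the driver", {
  cs <- cached_sim(1L)
  ctrl <- unique(cs$ann$sample_id[cs$ann$group == "control"])
  cases <- unique(cs$ann$sample_id[cs$ann$group != "control"])
  dp <- quietly(differential_psi(cs$psi, cs$ann, ctrl, cases,
                                 mode = "per_cell_ranksum"))
  drv <- dp[dp$event_id == cs$truth$driver_event, ]
  expect_lt(drv$q_value, 0.05)
  expect_gt(drv$delta_psi, 0.2)

  ## identical groups: delta 0-ish, large p
  half1 <- ctrl[1L]; half2 <- ctrl[2L]
  dp0 <- quietly(differential_psi(cs$psi, cs$ann, half1, half2,
                                  mode = "per_cell_ranksum"))
  nulls <- dp0[dp0$event_id %in%
                 names(cs$truth$driver_target_class)[cs$truth$driver_target_class == "none"], ]
  expect_lt(median(abs(nulls$delta_psi)), 0.05)
  expect_gt(median(nulls$p_value), 0.2)

  ## an event missing in > 50% of one group's cells is skipped
  psi2 <- cs$psi
  ctrl_cells <- cs$ann$cell_id[cs$ann$sample_id %in% ctrl]
  psi2$psi[5L, ctrl_cells] <- NA_real_
  dp2 <- quietly(differential_psi(psi2, cs$ann, ctrl, cases,
                                  mode = "per_cell_ranksum"))
  expect_false(rownames(psi2$psi)[5L] %in% dp2$event_id)

  ## per-sample mode needs >= 2 samples per group
  expect_error(differential_psi(cs$psi, cs$ann, ctrl[1L], cases,
                                mode = "per_sample_t"), ">= 2 samples")
})

test_that("psi_pca ranks planted events on top and behaves symmetrically", {
  cs <- cached_sim(1L)
  pax <- quietly(psi_pca(cs$psi, cs$ann))
  expect_gt(pax$selection_correlation, 0.5)
  planted <- c(cs$truth$driver_event,
               names(cs$truth$driver_target_class)[cs$truth$driver_target_class != "none"])
  top10 <- pax$event_rank$event_id[1:10]
  expect_gte(sum(top10 %in% planted), 9L)
  ## unit-norm weights
  expect_equal(sum(pax$weights[, pax$pc_index]^2), 1, tolerance = 1e-8)

  ## duplicated event rows receive equal weights
  psi_dup <- cs$psi$psi[c(rownames(cs$psi$psi), "E050"), ]
  rownames(psi_dup) <- c(rownames(cs$psi$psi), "E050dup")
  ev2 <- rbind(cs$psi$events,
               within(cs$psi$events[50L, ], event_id <- "E050dup"))
  pax2 <- quietly(psi_pca(psi_matrix(psi_dup, ev2), cs$ann))
  w <- pax2$weights[, pax2$pc_index]
  expect_equal(unname(w["E050"]), unname(w["E050dup"]), tolerance = 1e-8)

  expect_error(psi_pca(psi_matrix(cs$psi$psi[1:10, ], cs$psi$events[1:10, ]),
                       cs$ann), "fewer than 20")
})

test_that("driver_target_prediction gates on motif and disease evidence", {
  cs <- cached_sim(1L)
  ctrl <- unique(cs$ann$sample_id[cs$ann$group == "control"])
  cases <- unique(cs$ann$sample_id[cs$ann$group != "control"])
  dp <- quietly(differential_psi(cs$psi, cs$ann, ctrl, cases,
                                 mode = "per_cell_ranksum"))
  disease <- dp$event_id[!is.na(dp$q_value) & dp$q_value < 0.05]
  dt <- driver_target_prediction(cs$psi, cs$truth$driver_event,
                                 cs$truth$motif_target_events, disease)
  ## the MX partner is repressed with rho = -1 by construction
  mxB <- cs$truth$mxe_pair[2L]
  expect_true(mxB %in% dt$repressed)
  expect_equal(dt$table$r[dt$table$event_id == mxB], -1)
  ## a correlated event without the motif flag is excluded
  enh <- names(cs$truth$driver_target_class)[cs$truth$driver_target_class == "enhanced"][1L]
  dt2 <- driver_target_prediction(cs$psi, cs$truth$driver_event,
                                  setdiff(cs$truth$motif_target_events, enh),
                                  disease)
  expect_false(enh %in% c(dt2$enhanced, dt2$repressed))
})

test_that("overlap_with_known is exact set arithmetic", {
  expect_equal(overlap_with_known(c("a", "b"), c("a", "b")),
               list(n_overlap = 2L, n_predicted_only = 0L, n_known_only = 0L))
  expect_equal(overlap_with_known(c("a", "b"), c("c")),
               list(n_overlap = 0L, n_predicted_only = 2L, n_known_only = 1L))
  set.seed(44)
  p <- sample(letters, 10); k <- sample(letters, 12)
  r <- overlap_with_known(p, k)
  expect_equal(r$n_overlap, sum(p %in% k))
  expect_equal(r$n_predicted_only, sum(!p %in% k))
  expect_equal(r$n_known_only, sum(!k %in% p))
})

test_that("combined severity coordinates put controls low on both layers", {
  cs <- cached_sim(1L)
  pax <- quietly(psi_pca(cs$psi, cs$ann))
  co <- combined_severity_coordinates(cs$axis, pax, cs$ann)
  ctrl <- co$group == "control"
  terc_e <- quantile(co$expression_severity, 1 / 3)
  terc_s <- quantile(co$splicing_severity, 1 / 3)
  expect_true(all(co$expression_severity[ctrl] <= terc_e))
  expect_true(all(co$splicing_severity[ctrl] <= terc_s))
  ## identical layers -> identical coordinates
  co2 <- combined_severity_coordinates(cs$axis, cs$axis, cs$ann)
  expect_equal(co2$expression_severity, co2$splicing_severity)
})

test_that("zeroing the splicing effect decouples the splicing coordinate", {
  ds <- quietly(simulate_dataset(sim_config(seed = 77L, psi_effect_size = 0,
                                            cells_per_sample = 100L)))
  fc <- quietly(filter_cells(ds$matrix, ds$annotation))
  mat <- normalize_expression(quietly(filter_genes(fc$matrix)))
  ax <- quietly(build_severity_axis(mat, fc$annotation))
  psi <- psi_matrix(ds$psi$psi[, fc$annotation$cell_id], ds$psi$events)
  pax <- quietly(psi_pca(psi, fc$annotation))
  co <- combined_severity_coordinates(ax, pax, fc$annotation)
  sev <- ds$truth$sample_severity[co$sample_id]
  expect_gte(cor(co$expression_severity, sev, method = "spearman"), 0.9)
  expect_lt(abs(cor(co$splicing_severity, sev, method = "spearman")), 0.5)
})
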