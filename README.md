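# enccSeverity

Severity stratification of iPSC-derived **enteric neural crest cells
(ENCCs)** from single-cell transcriptomes, for researchers studying
Hirschsprung disease (HSCR) — the congenital absence of enteric neurons over
a variable colon length (short-segment S, intermediate, long-segment L,
total colonic TCA; clinical score 0–5, controls 0).

The package rebuilds, as a tested and reusable pipeline:

* **QC / normalization** — cells kept for 3000–9000 detected genes and ≤ 20%
  mitochondrial content, genes detected in ≥ 5 cells;
  `lognorm = ln(1 + count/total · 2·10⁵)`.
* **Consensus DEGs** — per-gene Wilcoxon rank-sum against *each of two*
  control lines (BH within comparison); a DEG must pass `q < 0.05`,
  `|log2FC| > 0.5` against **both**, same direction.
* **Pseudo-severity axis** — PCA of scaled HVGs; the axis is the PC
  maximizing |Spearman ρ| against clinical scores, oriented controls-low and
  rescaled to [0,1].
* **Dynamics** — spline likelihood-ratio test along the axis (`q < 0.01`),
  LOESS profiles clustered (Ward, 1 − Pearson) into 4 modules, and
  **switch timing**: 50 axis bins, per-bin OLS, significant-bin IQR as the
  activation/repression period.
* **Pathway & complex activity** — additive score (mean lognorm over a gene
  set) and geometric-mean complex activity (`0` if any subunit is silent).
* **Hub-regulator targets** — three-step differential co-expression filter
  (correlation q, consensus DEG, binding evidence) with the
  activated/repressed sign rule, plus the DEG-vs-non-DEG motif 2×2 test
  (odds ratio + χ²).
* **Splicing layer** — per-cell AS frequency (splices / uniquely mapped
  reads), PSI = inclusion/total isoform TPM (missing below 1 TPM),
  per-sample and per-cell differential PSI, PSI-space PCA with event
  weights, driver-event target prediction, and combined expression/splicing
  severity coordinates.
* **Synthetic data** — a generator planting all of the above with ground
  truth (severity-linked modules, near-step switch genes, a hub with
  activated/repressed targets, a PSI driver with motif-flagged targets and a
  mutually exclusive exon pair), used by every recovery test.

## Worked example

```r
library(enccSeverity)

ds  <- simulate_dataset(sim_config(seed = 1))      # 1500 genes x 1600 cells
fc  <- filter_cells(ds$matrix, ds$annotation)      # QC at paper thresholds
mat <- normalize_expression(filter_genes(fc$matrix))
ax  <- build_severity_axis(mat, fc$annotation)
ax
#> SeverityAxis: PC2, |rho| = 0.965 vs clinical score, 1440 cells

samp <- fc$annotation$sample_id[match(names(ax$pseudo_severity),
                                      fc$annotation$cell_id)]
round(tapply(ax$pseudo_severity, samp, median), 3)
#> CTRL1 CTRL2 HSCR1 HSCR2 HSCR3 HSCR4 HSCR5 HSCR6
#> 0.056 0.058 0.100 0.233 0.221 0.359 0.696 0.824
```

The severity signal was planted on the *second* variance component (a larger
nuisance factor owns PC1); the axis finds it by clinical-score correlation,
and the per-sample medians rise monotonically with the planted severities
(0, 0, 0.2, 0.4, 0.4, 0.6, 0.8, 1.0) — Spearman ρ = 0.988.

Running everything at once:

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "encc_out"))
```

writes `axis_cells.tsv`, `modules.tsv`, `switch_periods.tsv`,
`hub_target_calls.tsv`, `motif_enrichment.tsv`, `driver_targets.tsv`,
`severity_2d.tsv` … (17+ tables and a timestamp-free log; reruns with the
same seed are byte-identical). The same stages are available from the shell
via `exec/encc-severity <stage> --config cfg.yaml [--seed N]` with stages
`simulate, qc, axis, dynamics, pathway, targets, splicing, all`.

In `encc_out/severity_2d.tsv` the two coordinates per sample are the median
expression and splicing pseudo-severities; controls sit lowest on both, and
`motif_enrichment.tsv` reports the hub-motif odds ratio over the non-DEG
background with its χ² p-value.

## Vignette

`vignettes/severity-pipeline.Rmd` documents the model, every tunable
parameter with its default and rationale, what the synthetic world does and
does not emulate, numerical choices, and known limitations.
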