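---
title: "Methods: severity stratification of ENCC single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity stratification of ENCC single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enccSeverity)
```

# The problem

Hirschsprung disease (HSCR) is the congenital absence of enteric neurons over
a variable length of colon. Its clinical spectrum — short-segment (S),
intermediate, long-segment (L) and total colonic aganglionosis (TCA) — can be
scored 0–5 (controls 0, TCA 5). Patient-derived iPSC lines differentiated
into enteric neural crest cells (ENCCs) and profiled by single-cell RNA-seq
give a cellular window on this spectrum. This package reconstructs a
**pseudo-disease-severity axis** from such profiles and characterizes what
changes along it: gene-module dynamics, switch-like regulatory timing,
pathway and chromatin-complex activity, hub-regulator targets, and an
alternative-splicing (PSI) layer.

# The model and procedures

## QC and normalization

Cells are kept when 3000 ≤ detected genes ≤ 9000 and mitochondrial fraction
≤ 20% (exclusion criteria are strict inequalities, so the boundaries
survive); genes are kept when detected in ≥ 5 cells. Counts are
log-normalized, `ln(1 + count/total × 200000)`. The scale factor is the only
normalization constant the upstream protocol fixes; natural log and
pseudocount 1 follow the convention of the normalization it cites. The TPM
layer is a per-cell count scaling to one million: transcript-length
correction would require isoform-level quantification, which is out of
scope, and no analysis here depends on it.

## Consensus differential expression

Each case line is compared with *each of two control lines separately*
(two-sided Wilcoxon rank-sum per gene on lognorm, BH within comparison); a
gene is a consensus DEG only if it passes q < 0.05 and |log2FC| > 0.5
against both controls in the same direction. The reported fold change is
against the pooled controls on the expm1-mean scale with pseudocount 1; the
reported p/q are the conservative maxima of the two comparisons. Rank-sum
tests use the normal approximation with tie and continuity correction,
vectorized across genes.

## Severity axis

Highly variable genes (binned-dispersion z-score, top 4500 or all when fewer
exist) are centered and scaled, and a PCA with a deterministic sign
convention is computed. Rather than fixing "PC2" by inspection, the axis PC
is chosen as the one maximizing |Spearman| between per-cell PC score and
per-cell clinical score; it is oriented so controls sit low and min-max
rescaled to \[0,1\]. When severity is genuinely the second variance
component — as the synthetic generator plants, with a larger
severity-orthogonal nuisance factor on PC1 — this reproduces the "PC2"
behavior without a manual choice. TCA cells are excluded from axis
construction by default, since total colonic disease follows distinct
pathogenic routes. Clinical scores are used ordinally for selection only,
never as a regression response.

## Dynamics, modules and switch timing

Genes differential along the axis are found by a likelihood-ratio test of a
natural cubic spline (3 df) in pseudo-severity against an intercept-only
model, Gaussian errors on lognorm, BH q < 0.01. The named trajectory-DE
package used upstream specifies no formula; a spline LRT has the same
decision surface (smooth trend vs none) and is fully specified. Significant
genes are LOESS-smoothed (span 0.5) on a 100-point grid, z-scored, and
clustered by Ward linkage on 1 − Pearson correlation into 4 modules,
renumbered so module 1 is highest at low severity.

Switch timing divides the axis into 50 equal-width bins (half-open, last
closed), fits a per-bin OLS of expression on pseudo-severity where a bin has
≥ 10 cells, keeps bins with p < 0.05, and reports the interquartile range of
significant bin centers snapped outward to bin boundaries, with direction
from the mean significant slope. Two numerical consequences worth knowing:
with a bin width of 0.02 the within-bin leverage is tiny, so only genuinely
steep ("switch-like") changes reach per-bin significance; and at α = 0.05 a
handful of spurious bins per gene are expected, so the IQR is a robust but
not outlier-free summary. The procedure is exactly equivariant to axis
reversal (interval (a,b) maps to (1−b,1−a), direction flips).

## Pathway scores and complex activity

The additive pathway score is the per-cell arithmetic mean of lognorm over
resolved set members (mean, not sum, so scores are comparable across set
sizes; group comparisons are invariant to the choice). Deacetylase-complex
activity is the geometric mean over a closed subunit list and is exactly
zero when any subunit is unexpressed — a complex needs all of its parts.
Group tests compare each case group with the pooled controls by rank-sum,
BH across the comparisons of one call.

## Hub-regulator targets

A three-step filter: (1) genes significantly co-expressed with the hub
(Spearman within the case condition, BH q < 0.05 — the condition where the
regulation is hypothesized active); (2) genes whose expression is disrupted
(consensus DEGs, control vs pooled cases); (3) genes with binding evidence
(a user-supplied list standing in for ChIP-seq-derived targets). Survivors
are `activated` (positive correlation, upregulated) or `repressed` (negative
correlation, downregulated). Motif-site counts are carried per gene; the
"at least two sites" filter is exposed as `min_motif_sites = 2`. The
DEG-vs-non-DEG motif contingency test reports the odds ratio (Haldane–
Anscombe 0.5 correction only when a cell is zero) and a 1-df chi-square
without continuity correction.

## Splicing layer

Per-cell AS frequency is splices over uniquely mapped reads. PSI is the
inclusion-isoform share of event-total TPM, missing (never zero) below 1
TPM total. Differential PSI runs per-sample (one mean PSI per sample,
t-test; the Fig-4g-style comparison) or per-cell (rank-sum); events missing
in > 50% of either group are skipped. With only two control samples the
per-sample t-test is structurally underpowered after multiplicity
correction, so the driver-target step takes its disease-association
evidence from the per-cell mode, mirroring the per-cell analysis it pairs
with. PSI-space PCA mean-imputes missing entries per event (deterministic),
centers events without scaling (PSI already shares a scale), picks the
severity PC as above and ranks events by signed weight. Driver-target
prediction repeats the three-step pattern in PSI space: correlation with
the driver event, motif-flagged exons, disease-associated events. The
combined severity view reports per-sample medians of the expression and
splicing pseudo-severities.

# The synthetic world

`simulate_dataset()` plants exactly the structure the stages assume, with
full ground truth. Defaults (the stated world):

* **Design**: 2 control + 6 case lines (clinical scores 1,2,2,3,4,5 → 3 S,
  1 intermediate, 2 L), 200 cells each; per-cell severity = sample score/5
  plus N(0, 0.03) jitter truncated to \[0,1\], so a sample's cells stay
  contiguous on the axis.
* **Counts**: 1500 genes; compositional means (per-cell library ~
  lognormal, mean 40k) with effects multiplicative on the log-mean;
  negative binomial with dispersion 0.15 (Smart-seq2-like on a fairly
  homogeneous sorted population); abundance-dependent dropout (rate 0.1
  decaying exponentially with the NB mean) — uniform dropout would give
  well-expressed genes bimodal noise no local regression could survive.
* **Modules**: 4 × 75 genes with archetype curves — early bump (up then
  decay), rapid-early logistic decline, late logistic rise, late logistic
  fall — scaled by `effect_size = 1.5` (natural log; ≈ 2.2 log2-fold over
  the full range, comparable to top DEGs in real data). Planted dynamic
  genes draw baseline abundance from the upper range: they stand in for
  *detected* DEGs, which are by construction expressed.
* **Switch genes**: 20 near-step logistics (scale 0.008) at twice the
  module amplitude, centers planted within ±0.02 of interior sample
  severities — switch timing is only estimable where cells populate the
  axis, and "switch-like" means near-step.
* **Nuisance**: 150 genes loading a standard-normal latent at 1.5× the
  module amplitude, sign-balanced and block-renormalized so the factor
  contrasts genes without inflating per-cell totals; it owns PC1, severity
  lands on PC2.
* **Hub**: one regulator whose latent activity is severity plus N(0, 0.08);
  30 activated and 30 repressed targets share that latent with positive and
  negative signs. Binding evidence = all targets + 20 null decoys; motif
  hits ~ Poisson(0.3) background, 2+Poisson(2) for targets.
* **Splicing**: 100 events (the 7 standard types); driver PSI rises 0.3 →
  0.7 along severity (logistic mean, Beta noise with concentration 50);
  15 enhanced and 15 repressed events couple to the driver's *realized* PSI
  on the logit scale; a mutually exclusive pair is exactly (driver PSI,
  1 − driver PSI) with a shared missingness mask; 2% of entries are
  missing. `psi_effect_size = 0` ablates the splicing severity link while
  leaving expression effects intact.
* **QC covariates**: detected-gene counts and planted failure modes are
  *paper-scale* (N(6000,700), failures <3000 / >9000 genes or >20% mito) so
  the QC contract runs at its published thresholds even though the matrix
  itself is desk-scale; the annotation is explicitly a synthetic stand-in
  there. ~10% of cells carry planted failures, matching the ~11% loss in
  comparable QC.

What a green recovery test does establish: the estimators find the planted
structure through NB noise, dropout, compositional coupling and a dominant
nuisance factor. What it does not: robustness to batch effects, doublets,
ambient RNA, non-monotone severity confounding, or isoform-level
quantification error — none of which the generator emulates.

# Numerical choices and degenerate inputs

Single master seed with per-stage derived sub-streams; PCA via the smaller
Gram matrix with a fixed sign convention (largest-magnitude loading
positive), so duplicated cells get identical scores and reruns are
byte-identical. Constant genes get p = 1 in the axis test; a constant hub
or driver is fatal; an empty binding set warns and returns all-`none`
(vacuous step-3 failure); zero-mapped-read cells get missing AS frequency;
ties in PC selection break toward the lower index. Result tables are
written at 6 significant digits, sorted by primary key, `NA` literal —
byte-stable across reruns. Fixture files are written at full precision
(`%.17g`) so they round-trip exactly.

One caveat deserves emphasis: testing genes for change along an axis that
was itself computed from those genes' expression is circular — some genes
must vary along any principal component. The null calibration of the spline
test therefore uses an axis independent of the tested genes; on real data
the axis test should be read as descriptive ranking along the chosen axis,
as in all trajectory differential expression.

# Known limitations

The per-sample differential-PSI t-test with two controls cannot clear BH at
q < 0.05 regardless of effect size — a small-sample structural limit, not a
bug; use the per-cell mode when cells are exchangeable enough. The
switch-timing IQR tolerates but does not remove the ~α·(usable bins)
spurious significant bins expected per gene. Count-scaled TPM ignores gene
length. The pathway score treats genes as exchangeable (by design: an
additive model ignoring interactions).
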