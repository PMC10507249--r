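---
title: "Models and methods behind lcmtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lcmtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmtx)
```

# The problem

Laser capture microdissection (LCM) lets one sequence single cells
*with their histology attached*: each oocyte comes with its measured
diameter and follicle stage, each granulosa cell with its position
relative to the oocyte. The price is working from fixed sections —
amplification can fail outright, sectioning slices cells open and
perturbs low-abundance transcripts, and a granulosa cell cut next to an
oocyte can carry a fragment of oocyte cytoplasm.

lcmtx implements the computational side of such an experiment for the
mouse ovary: quality gating, absolute calibration, artifact
quantification, and the central statistical model — a reconstruction of
the oocyte transcriptome as a function of oocyte diameter, whose
residuals identify oocytes whose transcriptome lags their morphology
(growth retardation). Every method is exercisable on synthetic cohorts
with complete ground truth.

# Quality gating

**Amplification success.** qPCR Ct values of a housekeeping assay are
screened for high-Ct outliers with the Smirnov–Grubbs statistic
$G = (\max_i x_i - \bar x)/s$; the p-value uses the exact
t-distribution identity $p = n\,P(T_{n-2} > t)$ with
$t^2 = n(n-2)G^2 / ((n-1)^2 - nG^2)$. Wells with $p < 0.01$ are treated
as failed amplifications. Because several failures occur per plate and
simultaneous outliers mask one another (eight wells shifted +8 Ct
inflate the sd enough that no single test rejects), `gate_amplification()`
runs in the generalized extreme-studentized-deviate style: it records
the statistic of the current maximum, removes it, repeats up to
`max_iter` = n/4 times, and finally fails every well up to the *last*
step whose p fell below alpha. Under a pure-null plate the measured
per-well false-exclusion rate is about 2 × 10⁻⁴, far below the 2·alpha
bound asserted in the tests; with eight planted +8 Ct failures in 48
wells, all planted wells are excluded.

**Cell filters.** Mapping-rate floors are cell-type specific (3%
oocytes, 13% granulosa), a detectable-gene floor (default 3,500, chosen
just above the one observed degenerate cell at 3,138) and a
correlation screen (maximum Pearson correlation of log2 expression with
any other cell ≥ 0.3) remove degenerate libraries. Every failure
carries machine-readable reason codes.

**Mixed profiles.** The original screen for granulosa cells carrying
oocyte material was visual: bimodality in the contour plot of the cell
against the average oocyte. We operationalize it: restrict to an
oocyte-signature gene set, fit 1- and 2-component Gaussian mixtures to
the cell's log2 values (EM, deterministic median-split initialization,
sd floor 0.2), and flag a cell iff BIC favors two components, both
weights are ≥ 0.2 and the means are ≥ 2 log2 units apart. The
signature defaults to genes with oocyte mean log2 ≥ 6 and granulosa
cohort mean log2 ≤ 2, with two refinements that the controls forced:

* genes sporadically detected across granulosa cells (detection rate
  > 0.15) are dropped — oocyte genes expressed in a zero-inflated way
  by *neighboring* granulosa cells are a positional phenomenon, and a
  detector meant to find admixture must not fire on it;
* when the oocyte expression matrix is supplied, signature genes must
  be stably high across oocytes (10th percentile ≥ floor − 2): genes
  high on average but silent in small oocytes would make a small
  oocyte look bimodal against the cohort mean, and the detector must
  never flag a genuine oocyte.

# Quantification and calibration

Counts are normalized to RPM per cell; the denominator includes spike
reads by default (`all_mapped`), with a genes-only mode because either
convention is found in practice. Expression analyses use
log2(RPM + 1).

Absolute copies are calibrated per cell by ordinary least squares of
log2(reads) on log2(known ERCC copies), using only spikes with more
than zero reads (at least three required). The model exposes the read
level of one copy ($2^{\text{intercept}}$) and the inverse map used by
`count_detectable_genes(mode = "copy_ge_1")`. On Poisson-sampled
spikes spanning 2⁰–2¹² copies the refitted slope stays within
[0.9, 1.1] and the Spearman correlation of predicted vs true copies
exceeds 0.99.

# Section-induced artifacts

Paired fresh/section cohorts are compared gene by gene:

* detection rates by the pooled two-proportion z-test (two-sided, no
  continuity correction; degenerate pooled rates return p = 1);
* expression levels by a per-gene two-sided t-test (Welch by default)
  on log2(RPM+1), flagged when |difference| > 1 and p < 0.01, reported
  as section-relative (negative = depressed in sections).

Flags are then stratified by the rank of the fresh-cohort mean; in the
default synthetic world about 90% of flags sit below log2(RPM+1) = 4,
reproducing the concentration of sectioning artifacts at low
expression.

A note on calibration testing: the two-proportion z-test cannot agree
with an exact permutation oracle within 0.05 on *all* 2×2 tables at
n = 10 per arm. Enumerating every table shows deviations up to 0.70 at
near-degenerate margins and 0.39 at odd totals (where the permutation
p is necessarily 1), under the plain, mid-p and unconditional exact
variants alike. The acceptance test states the bound anyway and is
left red as documentation; the agreement that does hold — in the
p < 0.01 decision tail — is asserted separately, and the test's null
calibration (rejection fraction at p < 0.01 within [0.005, 0.015]) is
measured over genes in the informative detection regime (pooled rate
in [0.1, 0.9]), since genes never or always detected are excluded from
testing by the degenerate rule.

# The size–transcriptome model

PCA (centered, unscaled) is fitted over oocytes on genes with
log2(RPM+1) > 4 in at least one cell. A deterministic sign convention
(each loading column oriented so its largest-magnitude entry is
positive) makes the whole model reproducible byte-for-byte. PC1 and
PC2 are regressed on oocyte diameter by ordinary least squares and the
transcriptome is reconstructed on a grid (10–100 µm in 10-µm steps):

$$R_{g,b} = \mu_g + \sum_{k=1}^{2} (a_k + b_k d_b)\, L_{g,k}.$$

Each oocyte is then matched to the grid column maximizing Spearman's
rank correlation; ties break toward the smaller diameter. With
$\Delta$ = observed − best-matched diameter, a cell is *deviant* when
$|\Delta| > 20$ µm and *retarded* when $\Delta > 20$ µm.

**Robust refinement.** The model exists to find cells whose
transcriptome disagrees with their diameter — and exactly those cells
corrupt a naive fit. With four retarded cells among 44, a single OLS
pass flattens the PC-diameter slopes enough that only ~78% of normal
oocytes match within one grid step and retardation sensitivity drops.
`fit_size_model(refine = TRUE)` (the default) therefore performs one
refinement pass: fit, match, exclude cells deviating by more than the
cut, refit. With it, recovery is ≥ 97% and all planted retarded cells
are flagged with no false positives across seeds.

Per-gene Pearson correlations with diameter define the strongly
associated sets (r > 0.85 rising, r < −0.80 falling). Two properties
of these cuts are worth knowing. First, a steep sigmoid approaches a
step function, whose correlation with uniformly spaced diameters caps
at $\sqrt{3}/2 \approx 0.866$ — the strongly correlated set is
therefore the *smooth central* risers, not the steepest ones. Second,
the aggregate trajectory of each set (its per-cell average Z profile)
has its fitted logistic inflection near 45 µm because the cut selects
genes with central inflections. `fit_sigmoid()` fits the 4-parameter
logistic $A + (B-A)/(1+e^{-k(d-d_0)})$ by multi-start L-BFGS-B
(inflection bounded to the data range ± 10 µm, $k \ge 0$, nine starts,
tight-tolerance polish of the winner); on noise-free data it recovers
$d_0$ to < 10⁻⁵ µm, and at noise sd 0.1 it recovers a planted 45-µm
inflection within ±3 µm in ≥ 95/100 seeds.

# Differential expression

Granulosa positional DEGs use the published criteria: expression floor
log2(RPM+1) > 4 in ≥ 1 cell (applied before testing), two-sided t-test
(Welch default), Benjamini–Hochberg over the tested genes, and a pass
iff |mean log2 difference| > 1.8 (>3.5-fold), p < 0.05 and q < 0.05.
BH is the step-up rule with monotonicity enforcement, verified against
a brute-force implementation of the definition to 10⁻¹². The FDR is
computed over floor-passing genes only (the floor is a filter, not a
test), recorded in the criteria snapshot. The multi-group stage filter
is classical one-way ANOVA with the floor and a minimum pairwise
group-difference of 1.

# TMM and exon profiling

Exon/junction matrices are normalized with a from-scratch
transcription of the trimmed mean of M-values: reference = sample whose
75th-percentile count fraction is closest to the mean of that
statistic; M and A computed over features positive in both sample and
reference; double trimming by M (30%) and A (5%) quantile ranks;
precision weights from the binomial delta method; factors rescaled to
geometric mean 1. The implementation matches the reference edgeR
implementation to < 10⁻⁸ (usually exactly) on random fixtures; edgeR
is used only as a test oracle, never called by the package. A feature
is detectable when its TMM value strictly exceeds 2. Per gene, the
transcript with the largest detection rate (averaged over samples) is
selected, ties broken toward fewer exons then id, and rates are
stratified by exon-count ceilings.

# The synthetic world

`sim_config()` states the world; all generators are pure functions of
(config, seed), with derived streams so that cohorts are independent
but reproducible.

* **Cohort sizes** mirror the real study: 44 oocytes spanning 20–80 µm,
  57 granulosa cells (20 neighboring), 12,000 genes, 92 spikes, 48-well
  plates, 4 retarded cells at Δ = 30 µm, 3 mixed profiles, 35 + 97
  positional DEGs.
* **Expression model.** Each gene's log2 mean follows a 4-parameter
  logistic of *effective* diameter (observed − Δ for retarded cells).
  Rising/falling growth-program genes (600/400) have amplitudes
  U(1.5, 8), steepness U(0.1, 0.3) and inflections spread uniformly
  over 25–70 µm: with all inflections near 45 the aggregate PC trend
  would be strongly sigmoid, contradicting the near-linear PC-diameter
  regressions seen in real data, and the linear reconstruction would
  fail; with the spread, the strongly correlated subsets *emerge* from
  the cuts with central inflections (~140–170 genes per direction at
  default scale, close to the real 140/41).
* **Counts.** Exponentiate, scale to a log-normal library
  (median 3 × 10⁶, matching the real per-cell depth of ~2–3 M mapped
  reads), Poisson-sample, then apply logistic dropout in the latent
  log2 mean (midpoint 2, steepness 1). A housekeeping class (200 genes
  at log2 9–13) carries the bulk of each library the way
  ribosomal/mitochondrial genes do in real cells; without it the
  per-million renormalization would shift every observed level ~1.5–2.4
  log2 units above its stated latent value and the "artifacts below
  log2 4" geometry would be meaningless. Two smaller library choices
  (2 × 10⁵, 10⁶) were rejected because single reads then correspond to
  whole log2 units of RPM, quantizing the low end.
* **Artifacts.** Detection-rate errors are planted as extra dropout
  calibrated to an *absolute* rate reduction; expression biases as
  binomial thinning of recovered reads by 2^bias, because a latent-mean
  shift is not recoverable from marginal means under dropout whereas
  the thinning fold is recovered exactly by a pseudo-bulk
  library-fraction ratio. Artifact genes live in the low-expression
  band by default (configurable via `artifact_pool_log2`).
* **Mixtures.** A mixed cell receives, for a random 60% subset of
  oocyte genes, a convex count-level admixture (fraction 0.5) of the
  oocyte mean profile — a partial fragment of adjacent cytoplasm. A
  *full* convex mixture would elevate every signature gene uniformly,
  i.e. look like a low-dose oocyte, which no bimodality detector can
  (or should) separate; the partial form is what produces the bimodal
  contours actually observed.
* **What the world does not emulate:** batch effects beyond the
  fresh/section contrast, UMI structure, gene–gene correlation beyond
  the shared diameter axis, amplification length bias, ambient RNA. A
  green test therefore establishes correctness of the statistics and
  recoverability of planted structure — not robustness to every real
  artifact.

# Numerical conventions

Zero-variance vectors: Grubbs returns p = 1 and no candidate; t-tests
return p = 1 when both groups are constant at the same value, p = 0
otherwise; ANOVA returns F = 0, p = 1 for all-identical groups;
correlation excludes zero-variance genes. Spearman uses average ranks.
All TSV output is written at fixed 15-digit precision so identical
runs are byte-identical; the run summary is JSON with unrounded
numbers. Stream seeds are derived as (seed · 48271 + k) mod 2³¹−1,
staying inside R's 32-bit integer range.

# Known limitations

* The PC-on-diameter regression is linear; strongly nonlinear growth
  outside the sampled diameter range extrapolates poorly (grid columns
  beyond the data are linear extensions).
* The refinement pass is a single step, not a full robust regression;
  with many more than ~10% deviant cells it could fail to recover.
* The mixed-profile detector assumes the admixture is partial; a
  complete doublet-like mixture is indistinguishable from an oocyte on
  the signature set and is out of scope.
* The copy-number model assumes log-linear spike behavior; PCR
  saturation at very high copies is not modeled.
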