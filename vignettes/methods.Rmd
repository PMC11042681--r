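---
title: "Models and methods behind meripdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meripdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models inside the package, the
parameters that matter, the choices we made where the design was genuinely
open, and the limits of what the simulation-based validation shows.

## The measurement model

MeRIP-seq quantifies m^6^A methylation as antibody enrichment: fragments
of methylated RNA are immunoprecipitated (IP) and sequenced alongside a
non-IP input library from the same sample. Methylation signal at a locus
is therefore confounded with the transcript's expression level — a gene
that doubles its expression doubles its IP coverage with no change in
methylation. The pipeline's job is to separate the two.

Genes are tiled with consecutive 50-nt bins in transcript coordinates.
Transcript coordinates always run 5'→3' (minus-strand genes are reflected
at ingest), and bins are laid on the union-exon gene body. We chose the
union-exon body rather than a single representative transcript because it
is strand- and isoform-robust and matches how the metagene is anchored;
the bundled simulators emit single-exon genes, where the two coincide.
A read is projected through the exons onto the transcript and assigned to
the single bin containing the midpoint of its projected span. The
midpoint rule keeps every read counted exactly once within a gene, so bin
totals are conserved — the alternative (fractional assignment to every
overlapped bin) breaks the count distribution assumptions downstream. A
read overlapping two genes counts once in each; unassignable reads are
tallied and dropped.

## Normalization, adjustment, filtering

Library sizes are median-of-ratios factors (the geometric-mean-referenced
median of per-feature ratios), rescaled to geometric mean 1. This is the
natural companion to a negative-binomial testing framework; if no feature
is positive in every sample the code falls back to total-count ratios
with a warning.

The expression adjustment divides each normalized IP bin count by the
matched input library's *relative* gene expression: the subject's
normalized gene-level input count plus a pseudo-count `c = 1`, divided by
the cross-sample mean of the same quantity. The pseudo-count guards
zero-count input genes; because the divisor is a ratio of like
quantities, the adjusted values stay on the count scale of the IP
library. Subjects are matched within condition (each IP library is
divided by its own condition's input), so a paired design retains its
pairing after adjustment.

Two filters follow, in order:

* **Low counts** — a bin is removed when its mean adjusted count is below
  `min_mean = 10` in *both* the CTRL and CASE groups (a bin abundant in
  either group survives).
* **IP enrichment** — "enriched in IP" is not a self-defining phrase, so
  we define it per-base: a bin's mean adjusted IP signal per base must
  reach `enrich_ratio = 1` times the gene's mean normalized input signal
  per transcript base in at least one group. Both the ratio and the
  definition are exposed as arguments.

## The bin-level test

Rounded adjusted IP counts are modelled per bin as negative binomial with
a log link, `log mu = X beta`, fitted by iteratively reweighted least
squares (Fisher weights `mu/(1 + alpha mu)`, max 100 iterations,
log-likelihood tolerance 1e-8, linear predictor clamped to ±30). In
paired mode `X = ~ subject + condition`; in covariate mode
`X = ~ covariates + condition` (batch, gender, age, BMI in the
case/control preset). The condition coefficient is tested with a Wald
z-statistic against the standard normal. Bins that fail to converge are
flagged and excluded downstream with a message; all-zero bins return NA.

### Dispersion estimation

Per-bin dispersions are profile MLEs with the Cox–Reid adjustment
(`-0.5 log det(X'WX)`), found by golden-section search on log α over
[1e-8, 10]. At the design sizes this pipeline targets (six to fifteen
pairs, five to twenty-some residual degrees of freedom), a per-bin MLE is
extremely noisy — its log-scale sampling variance is close to 1 — and
feeding it directly (or half-weighted) into a normal-reference Wald test
inflates the null rejection rate well above nominal. We therefore shrink
on the log scale toward a lowess mean–dispersion trend with an
empirically estimated weight:

* the trend is fitted through the "interior" MLEs (those away from the
  search bounds) and rescaled by the mean MLE/trend ratio, because the
  left-skew of log-MLEs otherwise biases a median-type smoother downward;
* the sampling variance of a log dispersion MLE under the actual design
  is measured by a parametric bootstrap: 400 synthetic bins are drawn at
  the trend dispersion across the observed mean range and re-estimated
  (a fixed internal seed keeps the path deterministic);
* the between-bin dispersion variance is the excess spread of observed
  MLEs around the trend, floored at 0.02, and the shrinkage weight is the
  usual precision ratio.

When bins genuinely share one dispersion this collapses to the trend and
the Wald test attains its nominal size (empirically ~0.05 at 2000 null
bins, n = 6 pairs, α = 0.1); when dispersions are truly heterogeneous the
excess spread is detected and per-bin information is retained. A fixed
numeric weight (including the simpler 50/50 compromise) remains available
through `shrink =`, but it is measurably anti-conservative at these
sample sizes, which is why the adaptive weight is the default.

## Regions, Fisher combination, FDR

Bins with `p < 0.05` (configurable), in the same gene, on consecutive
ordinals and with the same fold-change sign merge into one region. The
same-sign requirement is our choice — it gives every region a direction,
matching how hyper-/hypomethylated sites are reported; `same_sign =
FALSE` preserves the alternative. A region's p-value is Fisher's
combination, `X = -2 Σ ln p ~ χ²(2k)`; zero p-values are clamped to the
smallest positive double with a warning.

Benjamini–Hochberg adjustment needs a family. Conditioning on the merged
regions alone is circular — every member bin was already below the
significance threshold, so under a global null essentially all regions
would pass any FDR cut. We therefore adjust over the full set of
candidate sites: the merged regions plus every non-significant bin
standing as its own candidate. This preserves the multiplicity of the
original bin-level scan and, in null simulations of the paired design,
holds the fraction of significant regions well below the nominal level.

Fisher's method assumes independent bins. Adjacent bins are not
independent here: they share the gene-level input adjustment, so input
measurement noise induces a common, condition-randomized shift across all
bins of a gene. At the region level this makes combined p-values
optimistic, increasingly so for long genes (more bins share the shift)
and larger cohorts (smaller per-bin standard errors make the shared shift
relatively larger). In our truth-scored simulations the realized
region-level FDR is controlled at the acceptance scale (~10 bins per
gene, n = 6 pairs) but climbs above nominal for 30-bin genes at n = 8–15.
This is a known limitation of the merge-then-combine design, inherited
from the underlying method; region q-values on long genes should be read
conservatively, and a dependence-corrected combination (Brown's method)
is the natural extension we deliberately left out of scope.

## Expression and single-cell stages

Input-library differential expression reuses the same NB Wald engine on
gene-level counts with median-of-ratios size factors as offsets and
covariates in the design. The count RNA-seq arms use the classical
linear-model path: CPM filtering (presets `nod-beta`: CPM > 1 in ≥ 3
samples; `oas-oe`: CPM > 0.49 in ≥ 4), weighted trimmed-mean (TMM)
normalization (30%/5% double trim, precision weights, upper-quartile
reference), logCPM with prior count 0.5, and a moderated t-test whose
prior degrees of freedom and variance are moment-matched on the log
residual variances (pooling to the arithmetic mean of variances when the
spread is no larger than the residual chi-square predicts). Precision
weights on logCPM (voom-style) are intentionally not implemented: at the
simulated depths they change little, and the moderated-t machinery is the
part under test. The total degrees of freedom are capped at the summed
residual degrees of freedom.

The single-cell stage applies inclusive QC thresholds (library size
≥ 2000, detected genes ≥ 1000, mitochondrial fraction ≤ 10%; we declare
boundaries inclusive since the source method does not say), removes
zero-total genes, and normalizes with a two-level scheme in the spirit of
pooling deconvolution: k-means clusters on a logCPM PCA, within-cluster
median ratios to the cluster pseudo-cell, and cross-cluster rescaling by
pseudo-cell library sums. This simplification keeps the within/between
cluster structure of the original deconvolution but replaces its linear
system with robust ratios — exact when cells are scalar multiples of
their pseudo-cell, and within 10% median relative error on simulated
depths. Highly variable genes are ranked by total variance minus a
delta-method Poisson technical variance; β-cells are the cells assigned
by maximum posterior to the two highest-mean components of a 4-component
Gaussian mixture on insulin log-expression (components are relabelled by
increasing mean so the call is invariant to fit order). β-cell
differential expression drops genes expressed in fewer than 10 β-cells,
then applies the moderated t.

## Bench formulas

ΔΔCt aggregates replicate Ct values by arithmetic mean — Ct is already a
log-scale quantity, so the arithmetic mean of Ct is a geometric mean of
abundances. The colorimetric m^6^A% and the LC-MS standard-curve
inversion implement their respective formulas directly, with guards
(negative sample-minus-NC clamps to 0% with a warning; zero-slope
calibration errors). Decay fitting regresses ln(abundance) on time
through the origin, because series are normalized to the t = 0 point; a
free-intercept variant is available via `through_origin = FALSE`, and the
flag also covers the ambiguity of whether time courses were renormalized
against a vehicle arm. Non-positive decay estimates are reported as
stable with infinite half-life.

## The simulators

The generators are pure functions of (configuration, seed); a root seed
is split per generator by hashing the generator label, so each stage can
be regenerated independently. They emulate:

* **`cytokine-paired`** — 15 subjects, each with paired CTRL/CASE IP and
  input libraries; NB counts with dispersion 0.1; gene-specific subject
  effects ~ Normal(0, 0.2²) on the log scale (visible but not dominant,
  so pairing demonstrably helps); library-size factors uniform on
  [0.7, 1.3]; IP bin rates from a Gamma(5,5)-shaped per-base enrichment
  with mean 2; DM regions planted as runs of 1–3 adjacent bins at
  log2FC 1.0 in 10% of genes; DE planted in a disjoint 10% of genes.
* **`t1d-covariate`** — 20 controls vs 7 cases, unpaired, with batch
  (2 levels, gene-specific sd 0.3), gender (sd 0.1) and age/BMI slopes
  (sd 0.005 per unit) as covariates.
* **single cell** — four insulin modes at log2 means (0, 2, 4, 6),
  sd 0.3, equal weights; ~6000-count cells; planted fractions of
  high-mitochondria (18% share) and low-depth cells sized to fail the QC
  thresholds.
* **assays** — Ct = constant − log2(expression) + noise, exponential
  decay with multiplicative noise, OD linear in analyte.

Where the source material gives no value (dispersion, effect sizes,
subject-effect scale, library-size spread), the defaults above are our
choices of what a bulk islet MeRIP-seq experiment plausibly looks like,
fixed once and reported here. The simulators deliberately omit several
features of real data: spliced multi-exon structure at scale, GC and
length biases, batch-by-condition interactions, antibody efficiency
variation between IP libraries, doublets and ambient RNA in single-cell
data. Passing tests therefore demonstrate internal statistical
correctness and calibration under the stated model, not robustness to
every artefact of real sequencing.

## Validation scale

The statistical acceptance checks run at desk scale, chosen so the whole
suite completes in minutes: the paired designs use 200 genes of
400–600 nt (~10 bins each) with n = 6 pairs — 50 replicates for null FDR,
12 for power; calibration checks use 2000 features; the single-cell check
uses 800 cells × 1800 genes; the determinism check runs the full
15-subject preset twice. The power reference (mean sensitivity 0.42 for
2-bin regions at log2FC 1.0, n = 6 pairs) was measured once over 50
replicates and frozen; the test asserts agreement within ±10 percentage
points. Sensitivity here is honest rather than flattering: the input
adjustment roughly doubles the effective dispersion (input measurement
noise propagates into the adjusted counts), which is the price of the
expression-confounding guard it provides — in the confounded simulations
adjustment cuts false DM sites by ~40× while keeping the realized FDR at
nominal.
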