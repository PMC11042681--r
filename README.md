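# meripdm

Bin-level differential m<sup>6</sup>A methylation analysis for MeRIP-seq
(m<sup>6</sup>A-seq), with the companion analyses that usually surround an
epitranscriptomic study of pancreatic islets: input-library differential
expression, Gaussian-mixture β-cell identification from single-cell
RNA-seq, and the bench-side calculations (ΔΔCt qPCR, colorimetric
m<sup>6</sup>A%, LC-MS m<sup>6</sup>A/A ratios, actinomycin-D decay
kinetics). It is aimed at analysts who want a transparent, fully tested,
desk-scale reimplementation of this pipeline whose every stage can be
exercised against simulators with known ground truth — no sequencing data
required.

## The method

MeRIP-seq measures methylation as immunoprecipitation (IP) enrichment over
a matched input library. For each gene, the transcript is tiled with
consecutive 50-nt bins and reads are counted per bin (a read is assigned
to the bin containing the midpoint of its exon-projected span). The core
model, per bin *b* and sample *s*:

1. **Normalization and adjustment.** Library sizes are estimated by
   median-of-ratios factors *f<sub>s</sub>*. IP counts are adjusted for
   expression using the same subject's gene-level input counts:

   A<sub>b,s</sub> = (IP<sub>b,s</sub>/f<sub>s</sub><sup>IP</sup>) ÷
   [ (IN<sub>g(b),m(s)</sub>/f<sub>m(s)</sub><sup>IN</sup> + c) /
   mean<sub>s'</sub>(IN<sub>g(b),s'</sub>/f<sub>s'</sub><sup>IN</sup> + c) ],

   with *m(s)* the input library of the same subject and condition and
   *c* = 1 a pseudo-count, so expression changes cancel and the remaining
   IP signal reflects methylation.
2. **Filtering.** Bins with mean adjusted counts below 10 in both groups
   are removed, then bins not enriched in IP relative to the per-base
   input signal.
3. **Testing.** Each bin's rounded adjusted counts follow a
   negative-binomial GLM, log μ = Xβ, with X either
   `~ subject + condition` (paired designs: each treated sample against
   its own baseline) or `~ batch + gender + age + BMI + condition`
   (case/control designs). The condition coefficient is tested by a Wald
   z-test; dispersions are Cox–Reid-adjusted profile MLEs shrunk toward a
   lowess mean–dispersion trend with precision weights estimated by a
   small parametric bootstrap.
4. **Regions.** Runs of adjacent significant bins (p < 0.05, same sign)
   merge into differentially methylated regions; region p-values are
   Fisher combinations (−2Σln p ~ χ²<sub>2k</sub>) and FDR is controlled
   by Benjamini–Hochberg over the full set of candidate sites.
5. **Annotation.** Regions are positioned on a 5'UTR/CDS/3'UTR metagene
   and their sequences scored for k-mer and RRACH-class motif enrichment
   by sequence-level hypergeometric tests.

Everything runs on tibble-in/tibble-out functions that chain with the
pipe, and fitted pipelines support `tidy()`, `glance()` and plotting
helpers.

## Worked example

Simulate a paired cytokine-treatment experiment (8 donors, treated vs PBS,
20% of genes carrying a planted methylation change of |log2FC| = 1.2) and
run the full pipeline:

```r
library(meripdm)

cfg <- sim_config("cytokine-paired", n_genes = 120, n_subjects = 8,
                  gene_len_range = c(400, 600), fraction_dm = 0.2,
                  dm_lfc = 1.2)
res <- run_merip_pipeline(cfg, seed = 42)
res
#> MeRIP-seq differential methylation result
#>   preset: cytokine-paired, seed 42
#>   bins tested: 1220 (non-converged: 0)
#>   DM sites at FDR < 0.05: 23 (9 hyper / 14 hypo) in 22 genes

head(tidy(res)[, 1:8], 5)
#> # A tibble: 5 × 8
#>   gene_id bin_start bin_end n_bins mean_log2fc direction p_combined      fdr
#>   <chr>       <int>   <int>  <int>       <dbl> <chr>          <dbl>    <dbl>
#> 1 g0069           2       3      2        1.70 hyper       6.14e-14 7.31e-11
#> 2 g0075           2       3      2       -1.60 hypo        5.51e-12 3.28e- 9
#> 3 g0054           8       9      2        1.45 hyper       3.29e-10 1.30e- 7
#> 4 g0117           6       8      3       -1.24 hypo        1.74e- 9 5.18e- 7
#> 5 g0055           2       3      2        1.40 hyper       3.02e- 9 7.19e- 7

score_dm_calls(res$regions, res$truth$dm_regions)
#> # A tibble: 1 × 5
#>   n_called n_true sensitivity false_discovery_rate sign_accuracy
#>      <int>  <int>       <dbl>                <dbl>         <dbl>
#> 1       23     24        0.75                0.217                1
```

Each row of `tidy(res)` is one differentially methylated region ("site"):
its gene, the span of 50-nt bins it covers, the mean log2 fold change of
IP enrichment (positive = hypermethylated in the treated condition), the
Fisher-combined p-value and its FDR. `score_dm_calls()` compares the
calls against the simulator's planted truth: here 18 of 24 planted
regions are recovered, every detected region has the correct direction,
and 5 calls land outside planted regions (adjacent bins share the
gene-level input adjustment, so the Fisher combination is optimistic
under that dependence — see the methods vignette for discussion).

The single-cell, expression and assay stages work the same way, e.g.

```r
sc  <- simulate_scrna(seed = 1)
qc  <- qc_filter(sc$counts, sc$mito_genes)        # 2000 / 1000 / 10% rules
nrm <- cluster_normalize(qc$filtered)
gmm_beta_call(nrm$log_norm["INS", ], K = 4)       # cells in the top 2 insulin modes
decay_fit(c(0, 4, 8), c(1, 0.5, 0.25))            # k = ln2/4, half-life 4 h
```

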