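---
title: "Finding commonly differentially expressed genes across microarray platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding commonly differentially expressed genes across microarray platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pooled microarray studies of a tumor type — here the motivating case is
urinary bladder cancer profiled on a single-channel platform together with
several public datasets — face two obstacles before any biology can be read
off: the platforms measure different probe sets on different scales, and
"differential expression" must mean something consistent across individual
samples, histological groups and platforms. `xplatde` implements one
complete answer: harmonize everything to a common NCBI-Gene-ID universe on a
shared log2-ratio scale, call differential expression in four complementary
comparison modes, and then reduce the calls by *set algebra* — a gene is
interesting when it is significant in **every** unit of a comparison family
simultaneously, not when a pooled statistic happens to be extreme.

## The procedure

1. **Spot-level preprocessing** (single-channel arrays). A spot is flagged
   when its signal `S` falls below `B_L + k_sigma * sigma_BL` (local
   background plus `k_sigma` local-background standard deviations). Signals
   are background-corrected by subtracting the array-level offset
   `median(B_L) - B_G` (global background median), clamped at a small
   positive floor, and spots below `cutoff_fold` times the median local
   background are removed. Each array is then divided by its median
   analyzable intensity (global-median normalization), and every sample is
   expressed as `log2(x / mean(controls))` per gene. Probes mapping to the
   same Gene ID are collapsed by the per-sample median.
2. **Harmonization.** The common gene list is the intersection of the
   per-platform Gene ID sets, sorted ascending. The combined
   genes-by-all-samples log2-ratio matrix is quantile-normalized: every
   column is replaced by the mean-of-sorted-columns reference mapped back
   through its ranks, so all samples share one empirical distribution.
3. **Differential expression.** Four modes: (i) all tumors vs all controls
   and (ii) each tumor group vs all controls, by two-tailed pooled-variance
   t-tests; (iii) an *intra-experimental* z-test standardizing each gene
   against the mean and SD of all genes within one sample's column; and
   (iv) an *inter-experimental* z-test standardizing each sample against
   the gene's own distribution across samples. Significance is `p < alpha`
   (strict), direction is the sign of the statistic. False discovery rates
   are Storey q-values computed per comparison family, with
   `pi0 = #{p > lambda} / (m (1 - lambda))`.
4. **Commonality.** Pure set rules over the call table: DE-in-all-units,
   simultaneous up/down sets, directional group-pair combinations,
   combined intra/inter cases (unchanged in one mode, DE in the other),
   incidence ranking, and group-common markers with a tolerance (a gene DE
   in all groups but one is the motivating pattern). Cross-platform
   commonality is the intersection of per-platform reports.
5. **Interpretation aids.** Chromosome distributions and per-chromosome
   mean expression of the up/down sets, chromosomal correlation maps
   (sample-by-sample Pearson or Spearman over one chromosome's genes),
   UPGMA and seeded k-means clustering, PCA, hypergeometric
   over-representation of term sets, motif-incidence tabulation, and
   multi-pathway gene selection.

```{r}
library(xplatde)
res <- run_pipeline(pipeline_config(seed = 1))
recovery_metrics(res$reports$cross_platform, res$sim$truth,
                 universe = attr(res$harmonized, "common_gene_list"))
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k_sigma` | 1.5 | low-signal flag multiplier (SD units of local background) |
| `cutoff_fold` | 2 | corrected signal must be at least this multiple of the median local background; the boundary is kept (inclusive `>=`) |
| `floor` | 1.0 | intensity floor after background correction |
| `alpha` | 0.05 | per-test significance threshold, strict `<` |
| `lambda` | 0.5 | Storey tuning parameter |
| `tolerance` | 1 | groups a gene may miss and still count as a group-common marker |
| `effect_common` | 1.0 log2 units | planted common shift, i.e. 2 noise SDs |
| `noise_sd` | 0.5 log2 units | per-measurement noise SD |

`k_sigma` deserves a note: the exact flagging constant used by single-channel
scanner software is not universal, so it is a visible configuration value
rather than a buried constant; 1.5 is the conventional choice. The
background-correction sentence admits two readings — subtract the
array-level offset `median(B_L) - B_G` (default), or subtract each spot's
own local background — and both are available via
`preprocess_config(background = )`.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the pooled design the pipeline targets:
a 2000-gene universe; three platforms carrying 5+10, 9+60 and 3+59
control+tumor samples (17 controls, 129 tumors); tumors assigned
round-robin to 11 stage-grade groups; per-gene log2 baselines `N(8, 1)`
(log-normal intensities); platform location/scale effects on the log2
scale; 30 genes shifted up and 80 down by `effect_common` in *every*
tumor; 10 extra genes per group shifted only there; each platform
measuring a 90% probe subset with 5% duplicated probes. These problem
sizes keep every test and the acceptance script in the seconds-to-a-minute
range while leaving the intersection geometry non-trivial.

The generator does **not** emulate spatial slide artifacts, dye chemistry,
probe-sequence effects, correlated gene modules, or outlier samples. A
passing recovery test therefore demonstrates that the *set-algebra
machinery and its statistics* behave as designed under idealized noise; it
does not certify performance on real arrays, where batch structure and
heavy-tailed noise can only reduce power.

Two structural consequences of the design are worth spelling out:

* **Recoverable truth.** With 90% probe subsets per platform, only about
  `0.9^3 = 73%` of the universe reaches the common gene list. A gene absent
  from one platform can never appear in a cross-platform intersection, so
  `recovery_metrics(..., universe = common_gene_list)` scores sensitivity
  against the planted genes that are measurable everywhere, and reports the
  unmeasured remainder separately.
* **Where the power lives.** The per-sample intra-experimental z-test
  standardizes against the spread of *all genes* in a sample, so a 2-SD
  planted shift yields a per-sample call probability near 0.5 — and the
  probability of being called in all 129 tumors is essentially zero. The
  intersection rules are therefore driven by the t-modes: each platform's
  tumors are tested against the pooled 17 controls *on the harmonized
  scale* (pooling controls is precisely what harmonization buys), and the
  per-platform direction sets are then intersected. The intra-z intersection
  remains available as a rule for data with much larger effects.

## Numerical choices

* Sample SD (`n - 1`) everywhere; pooled-variance Student t with
  `nA + nB - 2` df by default, Welch via `var_equal = FALSE`.
* Zero pooled variance with equal means gives `p = 1`; with unequal means
  the gene is flagged `degenerate` and excluded rather than called.
* Quantile-normalization ties receive the mean of the reference values over
  the tied rank span (an explicit run-length implementation; note that
  limma's `normalizeQuantiles` interpolates at the average rank instead,
  which differs on odd-length tie blocks).
* Storey q-values are the canonical step-down
  `q(p_(i)) = min_{j>=i} pi0 m p_(j) / j`, capped at 1, with `pi0` clamped
  to `(1/m, 1]`. No lower clamp at `p` is applied: when `pi0 < 1` the
  largest q-value is legitimately `pi0 * p_(m) < p_(m)`.
* Masked entries are excluded pairwise in all statistics; they are
  mean-imputed per gene **only** for clustering/PCA distance computations,
  and the imputation count is recorded on the result. Genes with any masked
  entry are dropped (and counted) before quantile cross-normalization,
  which needs complete columns.
* k-means uses k-means++ seeding under an explicit seed with 10 restarts,
  Lloyd iterations, best restart by inertia; UPGMA relies on
  `stats::hclust`, deterministic for a fixed input order.
* All generator randomness flows from one seed through per-component
  sub-streams, so partial regeneration is reproducible and two runs with
  the same configuration are byte-identical.

## Known limitations

* No batch-effect regression beyond quantile cross-normalization, and no
  meta-analytic effect pooling: platforms are combined by set intersection
  only, which is conservative by construction.
* The hypergeometric over-representation treats term sets as flat; no
  ontology topology, and under-representation is not tested.
* The z-modes assume approximate normality of log2 ratios within their
  standardization family; heavy tails inflate their calls.
* Public-style datasets are assumed to arrive already normalized; the
  spot-level path applies to single-channel raw tables only.
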