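---
title: "Methods: from knockout arrays to a phenotype-correlated anchor-gene network"
author: "anchornet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from knockout arrays to a phenotype-correlated anchor-gene network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchornet)
```

This vignette is the package's own account of its statistical machinery:
the models each stage assumes, the tunable parameters and their defaults,
the numerical choices made where the design was genuinely open, what the
synthetic-data generator does and does not emulate, and the known
limitations. Nothing stated here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The problem

A knockout of a broadly acting gene (the *anchor*; the package's examples
use a Fyn-like kinase) perturbs expression networks across brain regions.
The pipeline asks: which genes change with the knockout, do they form
coherent modules, and does a module's summary expression covary with a
behavioral phenotype across a genetic reference panel of recombinant inbred
(RI) strains? The chain is: pairwise array scoring, permutation testing,
clustering, gene-set over-representation, RI correlation screens, list
intersection, network assembly, eigengene–phenotype correlation.

## S-scores

Two arrays are compared probeset-by-probeset with

$$S_g = \frac{a_g - b_g}{\gamma\sqrt{\alpha\,(a_g + b_g) + 2\beta^2}}$$

an additive–multiplicative error model: `alpha` scales
intensity-proportional variance, `beta` is the additive noise floor, and
`gamma` is an empirical calibration factor. `calibrateErrorModel()` fits
`alpha` and `beta` by the method of moments (regressing squared differences
on intensity sums over all probesets of all same-condition pairs) and then
fixes `gamma` so the pooled same/same score SD is exactly 1. The only
property downstream stages rely on is this unit-normal null: |S| = 2
corresponds to a two-sided p of 0.0455. The scorer works on probeset-level
summaries; it is a deliberately small pluggable surface, so a probe-level
scorer with the same contract could be swapped in without touching the rest
of the pipeline.

Replicate averaging groups the `nA × nB` treated-vs-control pairwise score
vectors by *treated array*: one column per treated biological replicate,
each the mean of its `nB` comparisons. The alternative reading — pooling
all comparisons into a single averaged column — is exposed as
`replicateAverage(..., groupBy = "none")` but not used by the pipeline; the
per-treated-array reading keeps one score column per biological replicate,
which the SAM stage needs.

Finally each probeset's replicate scores are divided by
`max(1, SD of its same/same scores)`. This is a pure contraction — noisy
probesets are damped, quiet ones untouched — and with fewer than two
same/same comparisons the divisor defaults to 1. The same/same pool for a
contrast is all within-group array pairs of the two groups involved.

## SAM-style permutation tests

The moderated statistic is `d = effect / (se + s0)`. The fudge factor `s0`
defaults to the 5th percentile of the per-probeset standard errors (linear
interpolation); any explicit override, including 0, is honored. One-class
tests flip replicate signs (all `2^n` assignments enumerated for `n ≤ 12`
replicates), two-class tests permute class labels (all `C(nA+nB, nA)`
relabelings enumerated when at most 500). The FDR at a cut `c` is

$$\widehat{FDR}(c) = \min\!\left(1,\ \frac{\mathrm{median}_{\pi}\,\#\{|d^\pi| \ge c\}}{\#\{|d| \ge c\}}\right)$$

with the proportion of true nulls fixed at 1 (conservative), monotonized
across cuts in the Benjamini–Hochberg manner. The composite pass filter
requires both `|mean| ≥ 1.5` (for 3 replicates of unit-normal scores this
alone has `2(1 − Φ(1.5√3)) ≈ 0.0094 < 0.01`) and `FDR ≤ 0.05`.

Two properties of this design deserve honesty:

* **Granularity.** With 3 replicates the sign-flip null has 8 atoms and the
  label-permutation null 20; the FDR estimate is coarse, and the functions
  warn when fewer than 50 atoms are available. This mirrors the actual
  experimental design rather than papering over it.
* **Density dependence.** Because planted (truly differential) probesets
  also enter the permutation null ("leakage") and π₀ is fixed at 1, the
  sensitivity attainable under a 5% median-FDR cap grows with signal
  density: in the test suite's two-class simulations at effect 3 and
  3 vs 3 replicates, mean sensitivity is ≈0.46/0.61/0.72/0.83 at
  10/20/30/45% planted density while the realized false-discovery
  proportion stays ≤ 0.05 throughout. The recovery unit test therefore uses
  a dense (45%) signal, the regime of a strong global treatment response.
* **Exchangeability.** Replicate-averaged score columns within one table
  share control arrays and are positively correlated. Feeding such tables
  to the two-class test violates permutation exchangeability and makes it
  anti-conservative; this is a property of the replicate-averaging design
  itself. The pipeline's network construction path uses the one-class basal
  lists, which are unaffected.

## Clustering

Probesets passing any SAM analysis are assembled into a pattern matrix —
one column per (region, contrast) holding replicate-mean normalized
S-scores, union-of-pass-sets rows, so a probeset significant in one region
still shows its (non-significant) behavior elsewhere. Euclidean k-means
with `k = 12` (configurable), 50 restarts, clusters relabeled 1..k by
decreasing size. Rows are *not* re-standardized: S-scores already share a
scale, and magnitude is what separates "no change" from regulated patterns.

## Over-representation analysis

Set-based ORA is plain hypergeometric: `p = P(X ≥ k)` for an overlap of
`k` between an `n`-gene query and a `K`-gene set in an `N`-gene background,
BH-corrected across the retained sets (sizes 3–300 after background
intersection) at 5% FDR. The background defaults to the genes actually
measured, never the genome — portal-internal backgrounds are not
recoverable — and `N` is reported in every result row. The score-threshold
dialect first collapses probesets to genes by the best-scoring replicate
(maximal |score|), takes genes with |score| ≥ 1.5 as the query, and tests
at 10% FDR; unmapped probesets are dropped with a reported count.

The bundled `MYELIN_EXTENDED` set (12 genes: the five GO:0019911
structural-myelin genes plus seven classic myelin-associated genes) is a
labeled stand-in — curated extended myelin sets differ between
laboratories — suitable for exercising the machinery, not a reference
annotation.

## RI correlation screens and the network

`pearsonWithP()` uses the product-moment correlation with the exact
two-sided t transform `t = r√(n−2)/√(1−r²)`; `n` is counted per record
from pairwise-complete strains, because expression and phenotype panels
overlap imperfectly. Screens retain probesets reaching `p ≤ 0.01` against
any anchor probeset (or the phenotype) with **no multiplicity correction**
— deliberately, as a recall-oriented screen; every `CorrelationScreen`
records `alpha × nTested`, the expected false-positive count, so the cost
is visible. At 29 strains the effective effect-size floor is
`criticalR(29, 0.01) ≈ 0.47`.

The core gene set is the strict intersection of the knockout basal list and
the three screen lists (threshold mode, `≥ m` lists, is the configurable
escape hatch), with the anchor gene always appended. Network edges connect
core genes whose probesets correlate at `p ≤ 0.01` in the reference panel;
all probeset pairings are examined, the smallest-p pairing is stored,
multiple probesets collapse onto one gene node, and duplicate edges and
self-loops are removed. Isolated and panel-absent core genes remain as
(flagged) nodes.

## Eigengene

`networkPC1()` standardizes each gene (multiple probesets: mean of the
standardized probeset vectors, re-standardized), drops constant genes with
a warning and incomplete strains by complete-case, and takes the first
right-singular vector of the strains × genes matrix — correlation PCA,
since network genes share a scale only after standardization. The PC1 sign
is arbitrary; it is fixed so the loading sum is positive, and the
phenotype correlation reports |r| alongside the signed value. Variance
explained equals the leading-eigenvalue share of the gene–gene correlation
matrix (cross-checked against a direct eigendecomposition in the tests).

## The synthetic-data generator

The knockout generator emulates the study design: 4 genotype × treatment
groups, 3 pooled biological replicates each, 3 brain regions, log-scale
Gaussian intensities around per-probeset baselines (uniform 6–12, within
group SD 0.25). Planted structure:

* `nDE = 100` basal probesets shifted in the knockout everywhere (the
  anchor among them, forced down — it is deleted);
* `nDE = 100` ethanol-response probesets that respond in controls only;
* a coherent module (default 50 genes) sharing a per-sample latent factor
  (loadings uniform in [0.5, 1]) in all regions and additionally decreased
  in the knockout within two of the three regions — a myelin-like basal
  deficit confined to affected regions.

Shifts are expressed in S-score units via `delta = effectSize·√2·noiseSd`;
the module shift is additionally scaled by `√(1 + loading²)` because the
latent factor inflates module same/same SDs and the normalization stage
would otherwise dampen the realized effect below the requested value — the
generator's contract is that `effectSize` is the *post-normalization*
replicate-mean score.

RI panels (defaults: 30 strains for the phenotyped panel, 42 for the
second, 2000 probesets, 5% duplicated genes) draw a standard-normal latent
factor per strain; module probesets are `loading·z + noise` (residual SD
0.5), the anchor probeset is `ρ_a·z + √(1−ρ_a²)·noise` with
`anchorLoading = 0.9`, and the phenotype is
`ρ·standardize(z) + √(1−ρ²)·noise` with `phenoCoupling = 0.85`, targeting
the |r| ≈ 0.83–0.87 regime of interest and unit phenotype variance by
construction.

Not emulated, hence not demonstrated by passing tests: array QC metrics,
hybridization batch effects, probe-level (PM/MM) structure, the variance
reduction from pooling three animals per replicate (absorbed into the
within-group SD), population structure or kinship among RI strains, and
heavy-tailed or intensity-dependent noise beyond the fitted error model.
Passing recovery tests show the chain works when its assumptions hold; they
cannot certify behavior on real arrays.

## Problem sizes and seeds

The default pipeline conditions are 4000 probesets × 36 arrays and two
2000-probeset panels — sizes chosen so a full run takes seconds and a
20-seed recovery study minutes on one core, while keeping ≥ 50 genes in
the planted module and ≈ 2% planted differential probesets. All randomness
flows from explicit integer seeds; a master seed derives fixed per-stage
substreams, and the run manifest (seeds, thresholds, headline numbers, md5
hashes of every artifact, no timestamps) is bit-identical across runs with
the same configuration.

## Known limitations

* The median-FDR estimator is conservative at sparse signal (π₀ = 1,
  leakage) and coarse at 3 replicates; see above.
* The two-class test on replicate-averaged tables is anti-conservative
  under the shared-control-array correlation; interpret its pass sets as
  screens, not calibrated discoveries.
* Screen p-values are uncorrected by design; expected false-positive
  counts are reported instead.
* The strict four-list intersection trades recall for near-zero noise: in
  the acceptance simulations it keeps roughly two-thirds of the planted
  module with essentially no background genes; threshold mode recovers
  more at the cost of contamination.
* Gene symbols are uppercase-normalized for matching; species-specific
  casing is not preserved through intersections.
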