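# anchornet

Knockout studies of single genes with broad regulatory reach — kinases such
as Fyn above all — are hard to interpret: deleting the gene perturbs whole
expression networks, not just direct targets. `anchornet` implements, as a
tested and reusable R pipeline, an analysis chain that traces such an
"anchor" gene from a knockout microarray experiment to a coexpression
network whose summary expression correlates with a behavioral phenotype
(e.g. the duration of ethanol-induced loss of righting reflex, LORR, across
recombinant inbred mouse strains). Because the chain has many loosely
documented moving parts, every stage here runs against synthetic data with
planted ground truth, so calibration and recovery are measurable.

The stages, each exposed as an exported function over S4 containers:

1. **S-scores** — standardized pairwise array differences
   `S_g = (a_g − b_g) / (γ·sqrt(α(a_g + b_g) + 2β²))`, calibrated on
   same-condition ("same/same") array pairs so the null is standard normal
   (|S| = 2 ⇔ p = 0.0455), averaged into biological-replicate scores and
   divided by `max(1, same/same SD)` per probeset.
2. **SAM** — one- and two-class permutation tests on the moderated statistic
   `d = effect / (se + s0)` with a median permutation FDR, combined with the
   composite magnitude filter `|mean S| ≥ 1.5` (for 3 replicates,
   `2(1 − Φ(1.5·√3)) ≈ 0.0094 < 0.01`).
3. **Clustering** — Euclidean k-means of per-probeset pattern vectors
   assembled across brain regions and contrasts.
4. **ORA** — hypergeometric over-representation of gene sets
   (`p = P(X ≥ k)`, `X ~ Hyper(N, K, n)`, BH-corrected), in a set-based
   dialect (set sizes 3–300, 5% FDR) and a score-threshold dialect (best
   probeset per gene, |score| ≥ 1.5, 10% FDR).
5. **RI screens** — Pearson correlation (exact t-based p) of every probeset
   against the anchor gene's expression or against a strain phenotype,
   retained at p ≤ 0.01.
6. **Network** — strict intersection of the knockout and screen gene lists,
   then a correlation network over the core genes with probesets collapsed
   to single gene nodes, duplicate edges and self-loops removed.
7. **Eigengene** — PC1 of the standardized core-gene expression across
   strains (sign fixed, |r| reported) correlated with the phenotype.

A synthetic-data module generates the knockout design (4 genotype ×
treatment groups × 3 pooled replicates × 3 brain regions) and RI panels
(~20–45 strains) with a planted coherent module, an anchor probeset loading
on the same latent factor, and a phenotype coupled to it at a chosen ρ.

## Worked example

```r
library(anchornet)
res <- runPipeline(pipelineConfig(seed = 1, outdir = "demo", quiet = TRUE))

res$network
#> GeneNetwork (anchor FYN): 27 gene nodes, 341 edges

res$manifest$headline$moduleRecovery   # planted module genes in the core
#> [1] 0.52

varianceExplained(res$eigengene)
#> [1] 0.7045

res$pc1Corr
#> $r ... |r|(PC1, phenotype) = 0.83 (n = 30, p = 1.8e-08)

head(screenRecords(res$screens$anchorA), 3)
#>   probeset   gene         r  n            p anchorProbeset
#> 1 RPS00032 G00538 0.8878085 30 6.098188e-11       RPS00001
#> 2 RPS00045 G03482 0.8571255 30 1.477387e-09       RPS00001
#> 3 RPS00039 G03886 0.8365059 30 8.529432e-09       RPS00001
```

The run directory contains every stage's artifact (expression and S-score
TSVs, SAM results, cluster assignments, ORA tables, screen records, the
network as SIF and GraphML, the eigengene TSV) plus `manifest.json` with
seeds, thresholds, headline numbers and md5 hashes — bit-identical across
runs with the same seed. Here 52% of the planted 50-gene module survives
the strict four-list intersection with no noise genes, and the network
eigengene correlates with the phenotype at |r| = 0.83 against a planted
coupling of 0.85.

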