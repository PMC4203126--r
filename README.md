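# DominantPatterns

Transcriptome-analysis toolkit for two-genotype, multi-stage
developmental microarray experiments, built around the 16-array design of
a somatic-embryogenesis study in *Arabidopsis* (wild type vs. the
ascorbate-deficient *vtc2* mutant, sampled at the bent-cotyledon zygotic
embryo stage, days 7 and 14 of auxin induction, and the mature somatic
embryo stage, two biological replicates each).

It is written for transcriptomics practitioners who want the full
analysis chain of such a study as reusable, tested R components rather
than a one-off script stack:

* **Probe summarization** — quantile normalization + median polish
  (RMA-style, background correction omitted), replicate-correlation QC,
  and sample dendrograms with gene-resampling bootstrap support.
* **Detection calls** — a MAS 5.0-style analogue: discrimination scores
  `R = (PM − MM)/(PM + MM)`, exact Wilcoxon signed-rank p-values (ties
  handled exactly), P/M/A calls at `α₁ = 0.04, α₂ = 0.06`, and the
  two-replicate consensus rule ("detected" = P in *both* replicates).
* **Differential testing** — per-stage SAM statistic
  `d = (x̄_B − x̄_A)/(s + s₀)` with fully enumerated balanced
  relabelings, median-based permutation FDR with suffix-minimum
  q-values, BH as a secondary estimator, and the selection gate
  `q < 0.05` AND inclusive linear `|FC| ≥ 2`.
* **Dominant patterns** — the DP procedure: linear-scale ≤ 30 filter,
  FANNY-style fuzzy K-means (K = 15, membership exponent 2) minimizing
  `Σ_v (Σ_{ij} u²_{iv} u²_{jv} d_{ij}) / (2 Σ_j u²_{jv})` on
  `d = 1 − Pearson`, core prototypes at membership m ≥ 0.44, greedy
  prototype merging at r ≥ 0.90, and correlation-gated gene assignment at
  r ≥ 0.85.
* **Enrichment** — upper-tail hypergeometric over-representation of GO
  terms (GMT) and IUPAC promoter motifs (exact consensus, both strands)
  flagged at raw `P < 0.001`.
* **Transcriptional modules** — ChipEnrich-style TF → motif → target
  graphs with GO annotation nodes, exported as Cytoscape SIF + attribute
  files.
* **qPCR** — `2^−ΔΔCt` relative quantification.
* **Synthetic data** — a planted-truth generator (patterns, DE effects,
  absent genes, GO terms, promoter motifs, TF maps, Ct tables) that makes
  every stage testable end to end without external data.

## Worked example

```r
library(DominantPatterns)

design <- studyDesign(nGenes = 300)
design
#> StudyDesign: 2 genotype(s) x 4 stage(s) x 2 replicate(s) = 16 arrays
#>   genotypes: WT, vtc2
#>   stages:    zygotic -> D7I -> D14I -> matureSE
#>   genes: 300 | probe pairs per set: 11

truth <- simulateTruth(design, nPatterns = 9, seed = 7)
sim   <- simulateProbeIntensities(design, truth, noiseSd = 0.25, seed = 7)
expr  <- summarizeProbeSets(sim$probes)

range(replicateCorrelation(expr)$r)
#> [1] 0.998 0.999

detectionCalls(sim$probes)
#> DetectionCalls: 300 genes x 16 arrays; 4085 P / 6 M / 709 A calls

dominantPatterns(expr, seed = 7)
#> DominantPatternSet: 15 patterns over 8 cells; 233 of 255 genes assigned (r >= 0.85)

res <- runDifferential(expr, seed = 7)
lengths(selectDeg(res$D7I)[c("up", "down")])
#>   up down
#>   55   50

hypergeometricTest(12, 40, 30, 300)
#> [1] 9.63e-05
```

Reading the output: the replicate correlations near 1 confirm the low
simulated noise; the Absent calls are the planted undetectable genes
(MM ≈ PM, so their discrimination scores hover at zero); the
dominant-pattern run recovers the nine planted prototypes plus a few
clusters formed by planted differential genes; and the D7I selection
contains the planted ±3-log2 effects at that stage together with pattern
genes whose planted genotype difference genuinely exceeds the 2-fold
gate.  The hypergeometric example is the enrichment p for 12 annotated
genes in a 30-gene set against a 300-gene background with 40 carriers.

The full pipeline, driven by one configuration (all thresholds default
to the analysis values above), writes every stage's files plus a
manifest with content hashes:

```r
cfg <- defaultConfig(seed = 1, nGenes = 500)
runPipeline(cfg, outDir = "run1")
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/run_pipeline.R` (YAML configuration in, files out).

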