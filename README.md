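# emtsig

Derivation of a consensus epithelial–mesenchymal transition (EMT)
gene-expression signature from paired epithelial/mesenchymal RNA-seq
libraries, and its use to stratify breast-cancer expression cohorts into
EMT-up, partial-EMT and EMT-down states.

## Who this is for

Transcriptomics analysts who have (or want to emulate) a panel of cell-line
EMT models sequenced with one library per state, and who need the full
downstream chain: replicate-free differential expression, cross-model
consensus signatures, preranked gene-set enrichment, stability-validated
hierarchical stratification of tumour cohorts, and the survival /
driver-correlation / copy-number analyses that follow. A synthetic-data
module plants known structure so the entire pipeline is testable offline.

## The statistics at the core

* **Replicate-free DE.** Per gene, the two-library proportion z-test
  `z = (x₁/n₁ − x₂/n₂) / √(p₀(1−p₀)(1/n₁ + 1/n₂))` with
  `p₀ = (x₁+x₂)/(n₁+n₂)`, BH-adjusted; a gene is called only when it
  passes fold change > 2, FDR < 0.05 **and** |ΔCPM| > 5. The consensus
  signature is the cross-model intersection of direction-consistent calls.
* **Preranked GSEA.** Classic weighted running-sum enrichment score
  (hits add `|s|ᵖ/N_R`, misses subtract `1/(N−m)`), gene-permutation null,
  sign-stratified NES/FDR, set-size window [15, 1000].
* **Cluster-count stability.** Hierarchical clustering (correlation
  distance, complete linkage) scanned over k = 2..10 with connectivity
  (lower better), Dunn index and silhouette width (higher better);
  the recommended k minimises the mean rank across the three indices.
* **Cohort statistics.** Kaplan–Meier product-limit curves with log-rank
  comparison (5-year administrative censoring by default), Pearson
  driver-gene correlation grouped by gene cluster with Kruskal–Wallis,
  sign-thresholded CNV categories, and signature-response scoring of
  perturbation (e.g. knockout) experiments.

See `vignettes/emt-signature-workflow.Rmd` for the model, its assumptions
and every numerical convention.

## Worked example

```r
library(emtsig)

## three paired EMT models with a planted 134-up / 131-down consensus core
sim   <- simulateModels(modelSimConfig(seed = 1))
deriv <- runDerivation(sim$models, "out/derivation", seed = 1)
deriv$signature
#> SignatureSet: 134 up + 131 down = 265 genes

## a 1,000-patient cohort expressing that signature in planted blocks
cohort <- simulateCohort(cohortSimConfig(seed = 1),
                         signature = deriv$signature)
strat <- runStratification(deriv$signature, cohort$cohort,
                           "out/stratification",
                           driver = sigUp(deriv$signature)[1], seed = 1)
strat$selected_k
#> [1] 6
strat$annotation
#>   cluster n_genes frac_up       label
#> 1       1      91     1.0      EMT-up
#> 2       2      86     0.5 partial-EMT
#> 3       3      88     0.0    EMT-down
signif(strat$survival$logrank$p, 3)
#> [1] 1.05e-20
```

Reading the output: the derivation recovered the full 265-gene planted core
(134 up, 131 down). The stability scan recommended six patient clusters —
the planted count — and the three gene clusters annotate, by their fraction
of upregulated members (`frac_up` 1.0 / 0.5 / 0.0), as EMT-up, partial-EMT
and EMT-down. The log-rank p-value reflects the planted survival differences
between patient clusters (cluster hazards differ by up to 4-fold). Every
run writes its artifacts (DE tables, signature GMT, stability profile,
cluster labels, KM curves, ...) plus a manifest with parameter values and
per-file MD5 checksums; reruns with the same seed are bit-identical.

A thin command-line wrapper over the same functions is included at
`inst/scripts/emt.R` (`simulate-models`, `simulate-cohort`, `derive`,
`stratify` subcommands).

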