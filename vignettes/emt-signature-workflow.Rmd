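---
title: "Deriving and applying a consensus mammary EMT signature"
author: "emtsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying a consensus mammary EMT signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtsig)
```

# The problem

Epithelial-mesenchymal transition (EMT) reprograms gene expression as
epithelial cells acquire mesenchymal traits, and intermediate ("partial-EMT")
states are common in breast tumours. A recurring analysis pattern in this
field is:

1. sequence paired epithelial and mesenchymal libraries from several
   independent cell-line EMT models (one biological replicate per state per
   model is typical),
2. call differentially expressed genes per model, intersect the calls across
   models into a *consensus signature* of up- and downregulated genes,
3. check the signature against published EMT signature collections and
   against hallmark gene sets by preranked enrichment, and
4. use the signature to stratify tumour expression cohorts into EMT-up,
   partial-EMT and EMT-down states, with a stability-validated number of
   clusters, and relate the states to subtype, survival, driver-TF
   expression and copy-number categories.

`emtsig` implements that pattern as reusable, tested stages, together with a
synthetic-data module that plants known structure (a known consensus core,
known sample clusters, known overlaps) so every stage can be verified
end to end without external downloads.

# Data model

All expression data travel as an `ExpressionMatrix`, a
`SummarizedExperiment` with one assay and an explicit scale tag — `counts`,
`cpm`, `log2cpm` or `zscore`. Stages check the tag instead of guessing the
scale, which removes the classic failure mode of clustering raw counts.
Sample annotation (condition, subtype, survival time/event, CNV category)
lives in `colData`. Signatures are `SignatureSet` objects with disjoint up
and down member lists; gene-set collections round-trip through GMT.

# Differential expression without replicates

With one library per state, no within-condition dispersion is estimable, so
the per-gene test is the two-library proportion z-test on count fractions

$$ z = \frac{x_1/n_1 - x_2/n_2}
            {\sqrt{p_0 (1-p_0)\left(\tfrac1{n_1}+\tfrac1{n_2}\right)}},
\qquad p_0 = \frac{x_1+x_2}{n_1+n_2}, $$

the standard replicate-free test for count proportions. P-values are
BH-adjusted (`stats::p.adjust`), and a gene is called differential only when
it passes all three published-style filters: fold change > 2 (|log2FC| > 1,
computed on CPM with a pseudocount of 1 so zeros stay finite), FDR < 0.05,
and |CPM difference| > 5. The consensus signature is the cross-model
intersection of calls with consistent direction; genes called in every model
but with conflicting directions are excluded and reported, since the Venn
logic of a shared core admits only all-model agreement.

Interpretation choices worth stating explicitly (the upstream convention is
often left implicit in published workflows): "fold change > 2.0" is read as
|log2FC| > 1 with the sign giving direction; "FDR p-value" is read as
Benjamini-Hochberg; the overlap fraction against a reference signature
collection divides by the query size, with reference-size and Jaccard
denominators available as options; reference sets with fewer than 50 genes
are disregarded by default.

# Preranked enrichment

`buildRanking()` keeps genes with raw p < 0.05 and orders them by
descending log2 fold change (ties broken by gene identifier so the ranking
is identical across platforms). `enrichmentScore()` is the classic weighted
running sum: hits add $|s|^w / N_R$, misses subtract $1/(N-m)$, the score is
the extremum of largest magnitude, and the leading edge is the hit genes at
or before a positive extremum (after a negative one). Weight 1 is the
default ("classic weighted"); weight 0 reduces to a Kolmogorov-Smirnov
statistic. When the positive and negative excursions tie in magnitude
(possible at weight 0, where all increments are rational) the positive one
is reported — a documented convention, applied identically in the test
oracles.

The null model permutes gene labels (random same-size sets), not phenotypes:
with three samples per class a phenotype permutation null is degenerate, so
the "combined" multi-model analysis ranks genes by signal-to-noise across
the labelled samples and then scores that ranking against the same gene
permutation null. NES is the ES divided by the mean |null ES| of matching
sign; FDR q-values use the sign-stratified pooled-null convention of the
original GSEA method. Sets are restricted to the ranked universe and
excluded outside [15, 1000] members (the max-size override mirrors the
published setting; 15 is the customary minimum). Every set draws its own
permutation stream deterministically from the run seed, so results do not
depend on collection order.

# Clustering and the number of clusters

Cohorts are restricted to the signature genes (absent genes are dropped and
counted; the run aborts if fewer than half the signature is present),
row z-scored (n-1 denominator; zero-variance genes are set to zero, flagged
and removed before distance computation), and clustered hierarchically with
Pearson correlation distance `1 - r` and complete linkage on both axes —
the published stability scan states these parameters, and using the same
pair for the final clustering keeps the selected `k` meaningful for the
reported partition. Agglomeration is `stats::hclust`; its tie handling is
deterministic for a fixed input order, and inputs are always constructed in
a fixed order, so no bespoke agglomerator with a custom tie rule is needed.

The cluster count is scanned over k = 2..10 with three stability indices:

* **connectivity** (lower better): each sample's `L = 10` nearest
  neighbours contribute `1/j` when the j-th neighbour lands in a different
  cluster;
* **Dunn index** (higher better): minimum between-cluster distance over
  maximum cluster diameter;
* **silhouette width** (higher better): mean of `(b - a) / max(a, b)`
  (via `cluster::silhouette`; singletons score 0).

`selectK()` ranks k per index, averages the ranks and recommends the best
mean rank (ties to the smaller k, flagged) — but always returns the full
table, because the published practice also weighs subtype separation, a
judgement a function should inform rather than make.

Gene clusters (cut at 3 by default) are annotated by composition:
`frac_up` ≥ 0.75 reads as EMT-up, ≤ 0.25 as EMT-down, otherwise
partial-EMT. The thresholds are configurable and the fractions are always
reported next to the labels; a cluster of 91% upregulated genes is EMT-up
under any reasonable reading.

# Survival, correlation, CNV, knockout response

Kaplan-Meier curves and the log-rank test wrap the `survival` package, with
display-window truncation implemented as administrative censoring at the
horizon (1826 days = five years by default) rather than exclusion. Driver
correlation computes Pearson r of an EMT transcription factor (ZEB1, SNAI1,
...) against every signature gene, grouped by gene-cluster label and
compared by Kruskal-Wallis (the driver is excluded from its own group).
Thresholded CNV calls in {-2..2} map sign-wise to
deletion / normal / amplification. `signatureResponse()` scores perturbation
data: a signature gene is "affected" in a condition when its expected
direction versus baseline is not realised at |log2 ratio| > 1 — the same
2-fold criterion the signature itself was derived with (configurable). Group
expression comparisons default to Mann-Whitney (normal approximation with
tie correction), robust for skewed expression, with a t-test alternative.

# What the synthetic data emulates

`simulateModels()` draws per-gene baseline abundance from a log-normal
(rescaled to CPM; defaults `meanlog` 4, `sdlog` 1.2 give a realistic
right-skewed abundance profile with mean ~83 CPM at 12,000 genes), plants a
consensus core (134 up / 131 down by default) plus 800 + 800 model-specific
genes per model with |log2FC| uniform on [1.5, 4], and draws Poisson counts
at 2 million reads per library. Poisson (not negative binomial) is
deliberate: the emulated design has one library per state, so
within-condition dispersion is unobservable, and Poisson matches the
proportion-test model. Two generator choices deserve emphasis:

* **Expression floor for planted genes** (`min_planted_cpm`, default 20
  CPM). Signature genes are robustly expressed genes in their source models;
  an effect planted at the detection floor is unrecoverable at
  single-replicate depth and would test sequencing depth rather than the
  pipeline.
* **Mass-symmetric planting.** Each planted gene sits at baseline in its
  low state and is elevated by `2^|lfc|` in its high state (mesenchymal for
  up genes, epithelial for down genes). Elevating only the mesenchymal state
  in both directions would add ~60% transcriptional mass to one library and,
  because CPM is compositional, bias every unplanted gene's log-ratio by
  about -0.7 — leaking false consensus calls. The symmetric design keeps
  both libraries' mass comparable, so unplanted genes stay unbiased, while
  the planted direction and |log2FC| are preserved exactly.

`simulateCohort()` plants six sample clusters (multinomial, equal
probability) over three gene blocks (91 EMT-up / 86 partial-EMT / 88
EMT-down genes — consuming exactly a 134-up / 131-down signature; the
partial block mixes up- and down-genes, as the published partial-EMT
cluster does). Expression is gene baseline + cluster-by-block
mean shift + Gaussian noise on the log2 scale. The default shift patterns
are six amplitude-2 single-block activations/repressions — mutually
non-nested states, so the planted `k` is well defined for recovery tests —
with noise SD 0.5, giving clearly recoverable but non-trivial structure
(within-cluster sample correlation ~0.8). Subtype mixtures, per-cluster
exponential hazards (2-8 x 10^-4 per day, partial-EMT-high worst), uniform
censoring on [0, 3650] days and CNV probabilities echo the shape of
published breast-cancer stratifications, e.g. one basal-like-dominated,
amplification-rich, partial-EMT-high cluster.

What the generator does **not** emulate: overdispersion across biological
replicates, correlated gene-gene noise, batch effects, tumour purity
gradients, or continuous EMT trajectories. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct under its own model
assumptions, not that those assumptions capture every property of real
cohorts.

All generators draw from named per-component RNG streams fanned out from
one integer seed, so a fixed config is bit-reproducible and adding a new
generator never perturbs existing draws.

# Numerical conventions and degenerate inputs

* Zero-variance rows under z-scoring become all-zero and are flagged; the
  clustering stage drops them (correlation distance is undefined for
  constant profiles, which are rejected by name).
* `x1 = x2 = 0` in the proportion test returns p = 1 (no evidence).
* A permutation p-value of 0 is reported at the `1/n_perm` resolution limit
  and flagged, as is a set with no matching-sign null scores.
* Dendrogram cuts at k and k+1 always nest; ranks, neighbour orderings and
  score ties all break deterministically (by index or identifier).
* Singleton clusters: silhouette 0, diameter 0 (never inflating the Dunn
  denominator), flagged in the stability profile.
* Sets covering the whole ranked universe are excluded from enrichment
  (the miss term is undefined) with an explicit reason.

# Problem sizes used by the tests and the acceptance script

Signature recovery runs the full default generator (12,000 genes, 3 models,
2M reads) over 5 seeds; DE/FDR calibration uses 10,000 all-null genes;
enrichment and stability oracles compare against brute-force
implementations on 200 and 100 random instances; planted-k recovery runs 50
cohorts of 1,000 samples; log-rank calibration uses 2,000 null replicates
and 400 power replicates at hazard ratio 3 with 200 patients per group.
These sizes keep every quantity's Monte-Carlo error well inside its
acceptance band.

# Limitations

* The replicate-free proportion test is a declared substitute for the
  unnamed test of the original commercial workbench; per-model DE totals
  from that workbench are not expected to reproduce exactly.
* Cluster memberships of specific published figures are not reproduced
  (heatmap-package defaults in the original are unstated); what is
  reproduced is the methodology and its planted-truth behaviour.
* No Cox regression, consensus clustering, or PAM50 subtype calling:
  subtype labels are consumed, never computed.

# A minimal end-to-end run

```{r workflow, eval = FALSE}
sim <- simulateModels(modelSimConfig(seed = 1))
deriv <- runDerivation(sim$models, "out/derivation", seed = 1)
deriv$signature

cohort <- simulateCohort(cohortSimConfig(seed = 1),
                         signature = deriv$signature)
strat <- runStratification(deriv$signature, cohort$cohort,
                           "out/stratification",
                           driver = sigUp(deriv$signature)[1], seed = 1)
strat$selected_k
strat$annotation
```
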