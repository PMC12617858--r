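---
title: "Genomic prediction from obscured genotype similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction from obscured genotype similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Genomic prediction (GP) estimates a quantitative trait of an untested line
from genome-wide marker data, using a model trained on phenotyped lines.
`obscuredgp` implements a deliberately information-restricted GP model: the
predictor never sees marker *content*. For a pair of genotypes, the query A
and a reference B, the only genomic input is the **obscured vector** — a
binary vector with a 1 wherever A and B carry exactly the same marker code
and a 0 elsewhere (`obscured_vector()`). Together with B's trait value
`y_B`, this is used to predict `y_A`. The construction probes *shortcut
learning*: if a model predicts well from similarity positions alone, its
accuracy cannot be coming from marker effects, only from relatedness
structure — the same information that GBLUP compresses into a single
genomic-relationship number per pair, kept here as a full per-marker
pattern.

The base model (`obscured_net()`) is a small convolutional regression
network. The extractor applies a bank of 1-D convolution filters along the
obscured bits in marker order, ReLU, max pooling and dropout, then a fully
connected reduction to a low-dimensional embedding of where the two
genotypes differ. The embedding is concatenated with the scalar reference
phenotype and passed to a two-layer fully connected estimator with a single
linear output. Training (`train_obscured()`) minimizes mean squared error
over all ordered training pairs `(q, r)`, each contributing the row
`[obscured(g_q, g_r), y_r] -> y_q`, with mini-batch Adam for a fixed number
of end-to-end epochs (default 20).

A single pair prediction is weakly informative, so predictions for a query
genotype are formed by the **obscured ensemble** (`ensemble_predict()`): the
query is paired with a set of *reference instances* — training-fold
(genotype, phenotype) pairs fixed inside the model — and the pair
predictions are averaged. Reference instances can be all of the training
fold, a uniform random subset (`select_references_random()`), or a targeted
subset keeping the candidates whose pair predictions have the lowest mean
squared error across the training fold (`reference_mse_profile()` +
`select_references_targeted()`). The base network is trained once on the
full training fold; choosing a reference subset is purely an inference-time
decision, so fraction sweeps never retrain.

## Parameters that matter

* `w` (window, `window_dedup()`, default 8). Markers are scanned in genomic
  order and a marker is dropped when a *surviving* marker within the
  previous `w` positions is identical across all individuals. Redundant-pair
  counts (`count_redundant_pairs()`) stabilize around `w = 8` on dense
  panels, which motivates the default. Comparisons are against survivors, so
  the output is a fixed point in original coordinates: no two survivors
  within `w` of each other are identical. Note two consequences of this
  choice: survivor sets are *not* nested across `w` (an identical-column
  class at positions 1, 6, 10 keeps {1, 6} at `w = 4` but {1, 10} at
  `w = 5`), and re-running the filter on a *compacted* matrix can remove
  more, because compaction moves once-distant columns into the window.
* `k`, `bins` (`mi_rank()`). Marker relevance is the plug-in mutual
  information (empirical joint histogram, natural log) between the discrete
  marker codes and the trait cut into `bins = 10` equal-frequency bins.
  The estimator is deterministic and has an exact brute-force oracle, which
  is why it is preferred over nearest-neighbour MI estimators here; ties
  break toward the lower column index so selections replay exactly.
* Network shape (`net_config()`): 8 convolution filters of width 18, pool
  width 4, dropout 0.2 / 0.1, embedding width 32, estimator width 32.
  The filter width is clipped to the feature count for very small panels.
  Optimization: Adam, step size 1e-3, batch 64, 20 epochs. In exploratory
  runs larger step sizes reduced held-out accuracy (the pair dataset has
  only n distinct phenotypes among n(n-1) rows, so aggressive fitting
  memorizes pair fingerprints) and could collapse predictions to a constant.
* `fraction` (reference selection). The reference-set size is
  `max(1, round(fraction * n_train))`, rounding half away from zero.
* `heritability` (`sim_config()`): fraction of trait variance attributable
  to the simulated genetic value; the generator scales environmental noise
  to hit it in expectation.

## What the generator emulates — and what it does not

`simulate_gp()` produces a panel with the structural features the method
interacts with: a few hundred lines, 10^3–10^4 biallelic dosage markers
{0, 1, 2}, local LD blocks (each block copies a template column with a
per-entry flip probability, so adjacent markers are correlated and
cross-block markers are not), a planted fraction of *exactly duplicated*
columns at distance at most 8 (so the redundancy filter has a known right
answer), and a standardized additive polygenic trait with controllable
heritability. Defaults are n = 300, m = 1000, block size 10, flip
probability 0.1, 20 QTL, duplicate fraction 0.05, h² = 0.6.

It deliberately does **not** emulate pedigree or population structure: all
individuals are independent draws from the same block templates. That
matters for interpreting results. Real breeding panels (founders plus F1
hybrids, diversity panels with kinship) contain pairs of closely related
genotypes, and the obscured representation is at its most informative for
such pairs. On unrelated simulated lines, a single disagreeing bit at a
causal marker leaves the query's dosage ambiguous, so the attainable
*pair-level* accuracy is modest — on a noiseless three-QTL trait even an
oracle-style probe regression on `[bits, y_ref, bits x y_ref]` restricted
to the causal positions only reaches a pair-level correlation of about 0.3
— and the linear baselines (ridge, GBLUP), which see marker content,
outperform the obscured ensemble on this generator. Passing tests therefore
certify the machinery (representation, training, averaging, selection,
leakage-safety), the plateau behaviour of reference subsampling, and
parameter recovery by the baselines; they do not certify the absolute
accuracy the obscured model reaches on structured real panels. Dominance,
epistasis and admixture are out of scope.

## Numerical and design choices

* **Ordered pairs, both directions, no self-pairs** by default
  (`pair_dataset()`). Both orientations double the training data at no cost
  and keep the bit symmetry explicit; self-pairs (predict `y_A` from `y_A`
  and an all-ones vector) are available behind `include_self = TRUE`. Pair
  rows are materialized lazily from indices (`pair_design()`), so the full
  n² x m design never has to exist at once.
* **Standardization is fold-scoped.** Traits are z-scored with the n−1
  sample standard deviation, fit on the training fold only and applied to
  the held-out fold; all metrics are reported on the standardized scale (on
  which an uninformative predictor has MSE near 1). The loader refuses
  constant traits.
* **Missing marker codes are an error by default**: equality-based
  obscuring is undefined for missing data. Column-mode imputation is
  offered explicitly (`missing_policy = "mode_impute"`, ties to the smaller
  code).
* **Undefined correlations stay visible.** `pcc()` raises an error on a
  constant vector and the harness records the row with an explicit
  `pcc_defined = FALSE` flag instead of a silent 0 — near-constant
  predictions are precisely the failure mode that motivates reporting MSE
  alongside the correlation, and every report row carries both.
* **ReLU subgradient.** Backpropagation uses gradient 0 at a pre-activation
  of exactly 0 and routes max-pool gradients to the first maximum under
  ties; the engine is verified against central finite differences away from
  those kinks.
* **Targeted profile excludes the self term** (`i = j`): with self-pairs
  untrained it would inject an arbitrary constant into every candidate's
  mean.
* **GBLUP without REML.** The GRM is VanRaden method 1 with (by default)
  in-sample allele frequencies, and the mixed model is solved in ridge form
  with a fixed penalty standing in for the error-to-genetic variance ratio
  (`model_gblup()` can pick it from {0.01, 0.1, 1, 10} on an internal split
  of the training fold). The GRM-form solution is checked against
  marker-form ridge to 1e-8, the standard duality.
* **Random forest and direct-prediction comparators** are thin wrappers
  (`model_rf()` around the randomForest package; `model_deepgs()` reuses
  this package's own convolutional engine on raw dosages) so density sweeps
  can include them; they are not part of the bespoke oracle surface.
* **Degenerate inputs**: single-individual folds, empty reference sets,
  monomorphic-only marker sets for the GRM, constant traits and
  shape mismatches all raise typed, early errors rather than propagating.

## Problem sizes used by the test suite

The suite validates every fast path against brute-force oracles at small
sizes (n ≤ 30, m ≤ 120), trains networks end to end at n = 200 / m = 100
(noiseless recovery) and runs the reference-fraction experiment at the
generator defaults (n = 300, m = 1000, h² = 0.6) with dedup `w = 8` plus
fold-scoped MI selection of 64 markers, a single 200/100 split per seed and
five seeds. These sizes were chosen so a complete run stays comfortable on
one CPU while leaving the qualitative findings intact: 20% of the reference
instances match the full ensemble to within 0.05 PCC, and random selection
performs comparably to targeted selection relative to across-seed spread.

## Known limitations

* The generator's lack of relatedness structure (above) is the main gap
  between what is tested and what the method is for.
* MSE-profile computation is O(n²) pair predictions per training fold;
  at panel sizes beyond a few thousand lines it becomes the dominant cost
  of targeted selection.
* Variance components are never estimated; GBLUP here is a comparison
  baseline, not a replacement for an REML fit.
* Multi-trait and multi-environment prediction are out of scope.
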