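---
title: "Hybrid gene selection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid gene selection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veh)
```

## The selection problem

Given an expression matrix of *n* samples by *p* genes (*n* ≪ *p*, the
usual transcriptomics regime) with a class label per sample, we want a
small gene subset that preserves — ideally improves — class
discriminability. `veh()` chains three complementary strategies: a cheap
unsupervised *filter* (variance threshold), a supervised *embedded* ranking
(tree-ensemble importance), and a *wrapper* search (a binary Harris Hawks
optimizer driven by classifier accuracy). The filter and gate shrink the
search space by orders of magnitude so the expensive wrapper operates on a
few hundred candidate genes instead of tens of thousands.

## Preprocessing

Missing entries are filled by **mean substitution** (the mean of the gene's
observed values; this leaves per-gene means untouched), then every gene is
**min-max scaled** to [0, 1]. Constant genes, whose scaling denominator
vanishes, map to zero; they are removed by the variance filter regardless.
Preprocessing order is fixed (impute, then normalize): imputation on the
raw intensity scale is what "substitute the mean" means physically.

By default normalization is fitted once on the whole dataset before
cross-validation, which is the convention in this literature and is what
published subset accuracies refer to. Because the test folds then influence
the scaling (a mild information leak), `leakage_safe_cv = TRUE` re-estimates
min-max parameters inside every training fold; expect slightly lower, more
honest accuracy estimates in that mode.

## Stage 1: variance filter

Genes with per-gene variance strictly below `variance_threshold` (default
0.05) are dropped; a gene exactly at the threshold is kept. Variance is the
population kind (divide by *n*) by default, `variance_kind = "sample"` is
available.

**On which scale is the threshold applied?** By default the variances are
computed on the *raw* (imputed, unnormalized) intensities. The alternative
— variance after min-max scaling, available as
`variance_scale = "normalized"` — looks attractive because scaled variances
live in [0, 0.25] with a known maximum, but it has a sharp failure mode: a
unimodal gene scaled by its own sample range has variance ≈ (sd/range)²,
which for Gaussian-profile data at n ≈ 100–250 is about 0.02–0.04 —
*below* 0.05. On such data the normalized-scale filter removes essentially
every gene, informative ones included, and aborts the pipeline. Raw-scale
filtering keeps the stage meaningful for both raw-intensity data (where
near-constant probes are the target) and simulated Gaussian data. The
filter is order-compatible with normalization (scaling is monotone per
gene), so applying it before or after scaling keeps the same columns.

## Stage 2: extremely-randomized-tree gate

An ensemble of `ert_trees = 100` extremely randomized classification trees
is grown on the full sample (no bootstrap). At each node √p candidate
genes are drawn; each receives one uniform random cut point within its
node range; the candidate with the largest weighted Gini decrease splits
the node. Trees grow best-first to at most `ert_max_leaf_nodes = 10`
leaves with at least `ert_min_samples_leaf = 20` samples per leaf — small,
strongly regularized trees suited to tiny-n cohorts (note a split needs at
least 2 × 20 samples, so the stage requires n ≥ 40). Importance is the
per-tree-normalized total impurity decrease, averaged over trees and
renormalized to sum to one. The gate keeps genes with importance **strictly
greater than zero** — no epsilon; a gene passes iff it earned at least one
split anywhere in the ensemble. With 100 trees of ≤ 9 internal nodes, at
most ~900 split slots exist, so the gate typically passes a few hundred
genes at most — this cardinality cap is what makes the wrapper affordable.

No installed R tree package exposes this exact combination of constraints
(best-first growth to a leaf budget, a leaf-size floor, per-node feature
subsampling), so the package carries its own small tree grower; the same
grower, with exhaustive split search, serves as the decision-tree
classifier below.

## Stage 3: binary Harris Hawks search

Hawks are continuous vectors in [0,1]^D; the mask is `round(x)` with 0.5
rounding **up** (a fixed, documented tie rule). A mask that rounds to all
zeros is repaired by switching one uniformly chosen coordinate to 1 (in the
mask and the position) — the fitness is undefined for an empty subset.

Per iteration, each hawk redraws its initial energy E₀ ~ U(−1, 1), jump
strength J = 2(1 − r₅), capture draw r and branch draw q, and moves by:

* |E| ≥ 1 (exploration): perch relative to a random flock member
  (q ≥ 0.5) or relative to the rabbit and the flock mean (q < 0.5);
* r ≥ 0.5, 0.5 ≤ |E| < 1 (soft besiege):
  X′ = (X\* − X) − E·|J·X\* − X|;
* r ≥ 0.5, |E| < 0.5 (hard besiege): X′ = X\* − E·|X\* − X|;
* r < 0.5 (progressive rapid dives): a first candidate
  Y = X\* − E·|J·X\* − X| is accepted only if it improves on the hawk's
  current fitness; otherwise a Lévy dive Z = Y + S ∘ LF(D) is tried
  (S ~ U(0,1)^D); if neither improves, the hawk stays put.

Positions are hard-clipped to [0,1] after every move. The rabbit is the
best-fitness candidate ever evaluated; ties keep the earliest. The
best-fitness trace is therefore non-increasing by construction, an
invariant the tests assert on every seed.

**The two dive variants.** The soft and hard dive differ, in the method's
source tradition, only in the anchor of the first candidate: the hard dive
uses the population mean where the soft dive uses the hawk's own position.
Some printed descriptions collapse the two into identical formulas. The
package's default is the distinct-anchor form
(`dive_variant = "original"`); `"as_printed"` reproduces the collapsed
form exactly.

**Lévy flights.** The dive step uses the Mantegna construction,
`scale · u·σ(β)/|v|^(1/β)` with u, v standard normal, β = 1.5 and
scale = 0.01 — the convention of the optimizer's original formulation,
which the method description leaves unstated. Both are configurable; a
test checks the realized tail index against β by a Hill estimator.

**Fitness.** `fitness = α(1 − KNN_acc) + (1 − α)·f_num/F_num` with
α = 0.99. KNN_acc is the pooled stratified 5-fold cross-validation accuracy
of 5-nearest-neighbours (Euclidean distance) on the masked genes. The fold
assignment is frozen once per optimizer run, so all candidates are scored
on identical folds and fitness differences are attributable to the masks,
not to fold luck; KNN distance ties are broken under a fixed RNG state so
a mask's fitness is a pure function of the mask. Fitness values are
memoized by mask; the cache is contract-transparent (identical results on
or off, asserted in tests). The k and the split protocol are this package's
choices — 5 folds bound the per-evaluation cost at the ~30 × 100
evaluations a run performs.

**Randomness.** A run derives three child seeds from its seed — population
initialization, the search stream (per-hawk draws, Lévy steps, repairs),
and the fitness folds — and restores the caller's RNG state on exit, so
results do not depend on what ran before.

## Evaluation protocol

`repeated_cv_evaluate()` scores a gene subset with a classifier over
`repeats = 10` independent stratified `folds = 10`-fold splits. Within a
repeat, held-out predictions are pooled over all folds before computing
metrics — with 10–30 samples per class, per-fold metrics would often be
undefined. Accuracy is the pooled correct fraction; precision, recall and
F1 are computed per class and macro-averaged with equal weights, defining
0/0 as 0 (a class never predicted contributes zero precision). The
reported SD is the standard deviation of the 10 per-repeat accuracies
(matching the "10 independent repetitions" framing); the mean within-repeat
per-fold SD is logged alongside. Stratification requires every class to
have at least as many members as folds; smaller classes raise an error
rather than silently degrading.

Classifiers, at fixed conventional settings: decision tree (our grower,
exhaustive splits over ≤ 10 randomly drawn candidate features per node —
capped at the available count for tiny subsets — depth ≤ 8, feature
subsampling seeded by `random_state = 0` per fit); SVM with RBF kernel and
C = 1 via `e1071::svm` (one-vs-one multiclass, libsvm's native scheme);
and l2-regularized logistic regression with C = 1 by a damped
Newton/IRLS solver (intercept unpenalized, gradient tolerance 1e−4,
iteration cap 100, non-convergence recorded on the fit object,
one-vs-rest multiclass). The solver is in-package because the fixed
subsets it must score can have a single gene, below the two-predictor
minimum of the usual penalized-regression packages, and because its
convergence contract is part of the protocol's reproducibility.

Across the `runs = 10` independent optimizer runs, the final subset is the
one with (1) highest CV accuracy under the selection classifier (SVM by
default), then (2) smallest size, then (3) highest frequency of the
identical gene set across runs, then earliest run — a deterministic rule
for a stochastic search. Per-run subsets are ranked with one classifier
and only the winner is scored with all three, which keeps the protocol at
`runs + 3` CV campaigns instead of `3 × runs`.

## The synthetic generator

`make_synthetic_expression()` draws informative genes from class-conditional
normals whose means are `shift · noise_sd` apart between consecutive
classes, against class-independent Gaussian noise genes, with optional
uniform missingness and class imbalance; a log-normal mode adds the
right-skewed, strictly positive intensity scale of raw chips. This is the
minimal structure under which every stage behaves as intended — variance
distinguishes nothing (it is deliberately uninformative about class), the
tree gate and the KNN fitness respond only to the planted signal — and it
provides exact ground truth for scoring selections.

What it does **not** emulate: gene–gene correlation blocks, probe-level
artifacts, batch effects, heavy-tailed outliers, or the real-data property
that a handful of genes separate classes almost perfectly. Passing tests on
this generator therefore demonstrate protocol and optimizer correctness,
not expected accuracy on any real cohort.

`make_separable_toy()` plants one noiseless label-encoding gene — the
canonical fixture where the correct selection and its accuracy (100%) are
known exactly. `make_synthetic_benchmark()` generates clearly-labelled
synthetic stand-ins with the shapes of eight public microarray collections
(60–253 samples, 2,308–22,283 genes, 2–4 classes) and plants the
collections' published optimal probe subsets as per-class markers
(elevation 6 SD, missingness confined to noise genes), so the fixed-subset
protocol has a same-shaped, separable input when the real collections are
not on disk. They are stand-ins for protocol exercise, not substitutes for
the real measurements.

## Convergence behaviour and known limitations

* **Search scale.** With rounding binarization, uniformly initialized
  positions decode to masks holding about half the gated genes. When such
  half-dense masks already classify well (many partially informative or
  correlated genes — and, on the Gaussian generator at moderate shift,
  even noise dilution still leaves KNN accuracy ≈ 0.9), their fitness beats
  any small candidate, and the elitist rabbit can settle in a large-mask
  basin: α = 0.99 makes the size reward (0.01/F_num per gene) far smaller
  than one accuracy quantum (1/n). Small subsets win immediately when
  single genes are strong separators — the regime of the real microarray
  collections this method is aimed at. On weak-signal data, expect larger
  selections at T = 100, or run longer; the acceptance script reports the
  measured recovery quantities rather than assuming convergence.
* **Fold overfitting.** Because fitness folds are frozen per run, the
  optimizer can ride genes that look good on those specific folds. The
  cross-run selection step counteracts this by re-scoring subsets with an
  independent repeated-CV campaign, but selected subsets may still carry a
  few such passengers.
* **Stage coupling.** The importance gate is fitted once on all samples
  (before cross-validation), as the three-stage design prescribes;
  stage-level selection is therefore not leakage-free even in
  `leakage_safe_cv` mode, which only concerns normalization inside the
  final evaluation.
* **Degenerate inputs.** Every stage raises a labelled error instead of
  returning an empty result: an all-absent gene at imputation, an
  empty variance or importance stage, an all-zero importance vector, an
  empty mask at fitness, classes smaller than the fold count, unknown
  feature IDs (named in the message).

## Problem sizes in the test suite

The suite is sized for a single CPU: toy fixtures of 30–60 samples ×
8–40 genes for operation-level oracles; 200 × 100–300 for the
tree-importance and recovery properties; benchmark stand-ins at their full
published shapes for the fixed-subset protocol (their evaluation restricts
to ≤ 10 genes, so they are cheap); the optimizer's surrogate benchmark at
D = 12 against exhaustive enumeration of all 4,096 masks, 20 seeds at the
full 30-hawk, 100-iteration settings. The informative-gene recovery check
runs the complete stated protocol (10 runs × 30 hawks × 100 iterations) on
the 200 × 300 fixture.
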