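---
title: "Clustering-based negative sampling for miRNA-disease association prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering-based negative sampling for miRNA-disease association prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the similarity models, the positive–unlabeled sampling problem, the
clustering-based construction of the negative class, the ensemble, and
the design decisions taken where the method description left genuine
freedom.

## Setting and notation

The data is a curated list of verified miRNA–disease associations,
stored as a binary matrix `MD` with `Nm` miRNA rows and `Nd` disease
columns (entity order is lexicographic everywhere, so matrices are
reproducible across runs and platforms). Verified pairs form the
positive set `P`; all other pairs form the unlabeled set `U`; the total
pair set is `T = P ∪ U` with `|T| = Nm × Nd`. The setting is
positive–unlabeled: `U` contains an unknown number of *hidden
positives*, and the whole point of the sampling stage is to draw a
negative class that contains as few of them as possible.

## Similarity models

**Disease semantic similarity.** Each disease maps to a node of a
MeSH-style ontology; its DAG is the node plus all ancestors, `T(D)`.
Model 1 gives term `t` in `T(D)` the contribution
`D1_D(t) = 1` if `t = D`, else `max{Δ · D1_D(t') : t' ∈ children(t) ∩ T(D)}`,
a decay by Δ per generation; model 2 gives `t` the disease-independent
weight `D2(t) = −log(n_t / Nd)` where `n_t` counts modeled diseases
whose DAG contains `t`. Each model scores a pair by the sum of both
diseases' contributions over shared DAG terms, normalized by the two
semantic values (the column sums `DV`), and the final `SS` is the mean
of the two model scores. Diseases absent from the ontology have empty
DAGs and all-zero `SS` rows.

Three points the method description leaves open, and this package's
choices:

* **Δ = 0.5**, configurable. This is the standard value of the
  decay-factor convention this similarity family has used since its
  introduction.
* **Natural log in model 2**, configurable via `log_base`. The base
  does not cancel anywhere, so it is exposed rather than hidden.
* **The denominator of model 2 is `Nd`**, the number of modeled
  diseases, not the ontology node count: the modeled diseases are the
  only defined disease universe, and terms occurring in every DAG then
  get weight exactly 0, which is the intended "ubiquitous terms are
  uninformative" behavior.

The recursive max rule for `D1` is solved by fixed-point iteration over
the DAG-restricted edge list; because Δ ∈ (0, 1), the fixed point equals
`Δ^(shortest ancestor-path length)` on trees and general DAGs alike, and
the test suite checks both this identity and agreement with a
brute-force memoized recursion to 1e-12.

**Interaction-profile kernels.** The Gaussian interaction profile
kernel treats row/column profiles of `MD` as binary vectors:
`G(i, j) = exp(−γ ||IP(i) − IP(j)||²)` with
`γ = γ′ / mean(||IP||²)` and `γ′ = 1`. The bandwidth therefore adapts
to the density of the association matrix. Degenerate input (all
profiles all-zero) leaves γ undefined; the kernel is then the identity
matrix — no self-dissimilarity, no spurious cross-similarity — with a
warning.

**Integration.** The integrated disease similarity `IDS` takes `SS`
where it is nonzero and the kernel `GD` elsewhere; `IMS` does the same
with functional similarity `FS` and `GM`. `FS` is taken from a supplied
MISIM-style matrix when available and is the zero matrix otherwise, so
the integrated miRNA similarity falls back entirely to the kernel;
recomputing functional similarity from scratch is out of scope for the
real-data path (the synthetic generator, below, does compute one).

**Pair features.** A pair (d, m) is the concatenation of d's `IDS` row
and m's `IMS` row, disease block first — length `Nd + Nm` (878 at the
495 × 383 scale of the curated database).

## Clustering-based negative sampling

`T` is clustered into `K` clusters by mini-batch k-means. No installed
clustering package provides the mini-batch variant, so it is
implemented in the package: k-means++ initialization, per-batch nearest
center assignment, streaming-mean center updates (each center moves
toward the running mean of all points ever assigned to it), stop on
center displacement below `1e-6` or after `max_iter = 100` batches.
When the batch covers the data the first sweep is an exact Lloyd
update. The objective is Euclidean within-cluster sum of squares —
the general Minkowski exponent appears only in the silhouette distance
(default p = 2), because k-means centroid updates are only consistent
with the Euclidean case.

"Clustering repeated ten times" is interpreted as ten seeded restarts
(`seed, seed+1, …`) keeping the run with the lowest full-data inertia;
voting or averaging across runs would require a label alignment the
method never describes. Labels are canonicalized (cluster 1 = largest)
so reruns are comparable.

Each cluster is scored by its positive fraction
`p(i) = |C(i) − U| / |C(i)|`. Clusters are ranked by ascending `p(i)`
with ties broken toward the larger cluster (maximizing `|N|`), then the
lower cluster id; the `n_select < K` best clusters are harvested and
`N` is their union minus all positives. `N ∩ P = ∅` is asserted on
every build. Degenerate cases: an empty cluster gets `p(i) = 1` (never
selectable, with a warning); a harvest containing no negatives is a
hard error suggesting a larger `n_select`. `n_select` defaults to 1
because the default `K = 2` forces it.

**Choosing K.** The mean silhouette coefficient
`SC(o) = (b(o) − a(o)) / max{a(o), b(o)}` is scanned over a K range
(default 2–25); singleton clusters score 0, coincident points score 0,
and above 10,000 samples the index is computed on a seeded uniform
subsample because the distance matrix is quadratic. `K = 2` is the
package default: it is the silhouette-selected value on the curated
benchmark this method family was developed on, and the acceptance
script recomputes the desk-scale selection from scratch.

## Ensemble

Ten balanced subsets (all of `P` plus an independent without-replacement
draw of `|P|` negatives from `N`; draws are independent *across*
subsets rather than a partition of `N`, which matches the motivation of
using many draws without mandating coverage). Per subset, a
100-tree random forest ranks features by impurity importance
(permutation importance is an opt-in) and the top
`round(fraction × (Nd + Nm))` are kept — rounding half away from zero,
documented because 0.75 × 878 = 658.5 and the intended count is 659;
ties break toward the lower feature index. Each member trains only on
its own selected-feature view, at fit and predict time alike (a test
perturbs non-selected features and asserts the prediction is
unchanged).

Base learners: gradient-boosted trees (xgboost; the default), random
forest and extremely randomized trees (ranger), and AdaBoost. No
boosting package for AdaBoost is among the dependencies, so a Real
AdaBoost (SAMME.R-style) over depth-limited `rpart` trees is
implemented in the package; it exists for the base-classifier ablation,
not as the recommended learner. Hyperparameters are deliberately plain
and exposed — 100 trees/rounds, depth 6, learning rate 0.1 — because
the method description mentions tuning without reporting values, and
documented defaults beat hidden ones.

Prediction is soft voting: the score is the arithmetic mean of member
scores and a pair is associated iff the mean strictly exceeds 0.5 (an
exact 0.5 is not associated).

## Evaluation

Cross-validation builds a balanced set (`P` plus an equal-size draw
from `N`), splits it into stratified folds, and refits the *entire*
chain — subset draws, feature selection, members — inside each training
fold, drawing subset negatives from `N` minus the held-out fold so no
test pair ever enters a training subset (asserted per fold). Feature
selection is refit per fold rather than once globally: the method
description does not say which was done, and the per-fold choice is the
leak-free one, at the cost of not matching a hypothetical
globally-selected variant.

The test-set composition of the original evaluation protocol is
ambiguous (a held-out fold "merged with unlabeled samples" cannot yield
precision/recall, which need labels). Default mode
`balanced_fold` computes all six metrics on the balanced held-out fold;
`fold_plus_unlabeled` merges the fold with all unlabeled pairs outside
the training set and reports ranking metrics (AUROC/AUPR) only. AUROC
is the trapezoid integral over the tie-grouped ROC curve (equal to the
Mann–Whitney concordance statistic, checked to 1e-9 against a
concordance oracle); AUPR is step-integrated average precision.
Zero-denominator precision/recall are reported as 0 with a warning;
single-class truth makes the ranking metrics `NA` with a warning while
threshold metrics are still returned.

Similarities (the kernels depend on `MD`) are computed once on the full
matrix by default, as the original protocol does; this leaks held-out
positive entries into the kernel features. `strict_cv = TRUE`
recomputes the kernels inside each fold with the held-out positives
masked out of the association matrix (semantic and functional
similarity do not depend on `MD` and are unaffected), trading protocol
fidelity for leak-freedom. The leave-one-disease-out case study
avoids the analogous leak completely: every pair involving the target
disease is removed from positives and negative draws before training,
and all `Nm` candidate miRNAs are then scored for that disease.

## The synthetic generator

The generator emulates the three real inputs at configurable scale with
known ground truth:

* **Association list.** Entities carry Zipf(1) activity weights over a
  random permutation — curated databases are heavy-tailed, a few hub
  miRNAs account for most records, and the tail's zero-degree entities
  are what makes hidden-positive eligibility meaningful. miRNAs and
  diseases belong to latent blocks and a pair's sampling weight is
  multiplied by 0.1 across blocks, so similar diseases share miRNAs and
  the kernels are informative.
* **Ontology.** A random forest of `ontology_branching` disjoint
  category trees (depth-capped, child-capped) covering every disease,
  mirroring MeSH's disjoint top-level categories. The blocks *are* the
  categories, so cross-category disease pairs share no ancestors, their
  semantic similarity is exactly zero, and the kernel fallback path is
  exercised — on a single rooted tree every pair would share the root
  and the fallback would never fire.
* **Functional similarity.** A MISIM-style matrix computed the way the
  real resource is defined: best-match-average of disease semantic
  similarity over the two miRNAs' association sets, zero for miRNAs
  with no associations.
* **Hidden positives.** `round(contamination_rate × |U|)` unlabeled
  pairs, drawn from the same planted pair-weight distribution as the
  verified positives, restricted to pairs whose miRNA and disease are
  each already active — uncurated true associations, sitting in the
  same feature-space region as the curated ones. The truth list is
  returned for sampler-purity tests and is disjoint from `P` by
  construction.

Default conditions, chosen once: 60 miRNAs × 40 diseases, 150
positives (≈ 6% density, the same order as the curated database's
≈ 2.9%), depth 4, branching 3, contamination 0.05, everything a pure
function of the seed. What the generator does **not** emulate: real
MeSH depth and multi-parent structure, miRNA family structure, biased
curation (ascertainment toward well-studied diseases), and noise in the
similarity resources themselves. Passing tests on this generator
therefore demonstrate that the machinery behaves as specified and that
the sampler's purity advantage materializes when hidden positives
resemble positives — not that the headline metrics of any particular
curated benchmark are reproduced, which would require the real HMDD,
MeSH and MISIM inputs.

## Problem sizes and numerical conventions

The test suite and acceptance script run at desk scale: the
combinatoric checks build one 495 × 383 dataset; purity and paired
cross-validation use 20 seeds of the default 60 × 40 generator with
`m = 3` members per ensemble and single-repeat five-fold CV — sizes at
which the complete suite runs in a few minutes on one CPU while every
stage still exercises its full code path. Reported summary values are
means over seeds; win fractions are paired comparisons on identical
data.

Conventions collected in one place: lexicographic entity indices;
miRNA-major pair order; cluster labels relabeled by size; k-means
restarts at consecutive seeds; one master seed fanning out to stage
seeds by fixed offsets (recorded in the pipeline manifest);
half-away-from-zero rounding for feature counts; strict voting
threshold; silhouette singleton convention `SC = 0`; kernel of all-zero
profiles = identity; empty-cluster contamination = 1.

## Known limitations

* The negative set still contains hidden positives — the method lowers
  the contamination rate, it cannot drive it to zero.
* Only mini-batch k-means is offered; other clustering algorithms might
  harvest purer clusters but are outside this package's scope.
* `FS` for real data must be supplied; the package does not recompute
  MISIM from scratch on real inputs.
* Computing similarities on the full association matrix (the default,
  matching the protocol's convention) is mildly optimistic; the
  `strict_cv` mode removes the leak at the cost of diverging from the
  protocol.
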