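---
title: "OPLS-HDA: hierarchical discriminant analysis with two-class OPLS-DA models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OPLS-HDA: hierarchical discriminant analysis with two-class OPLS-DA models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplshda)
```

## The problem

Two-class OPLS-DA is the workhorse discriminant model of metabolomics and
related omics fields: it regresses a 0/1 class-membership dummy on the data
matrix and splits the predictor variation into a *predictive* part (the
direction used to model class membership, i.e. between-class variation) and
*orthogonal* parts (systematic variation uncorrelated with the response,
i.e. within-class variation). It discriminates strongly and its loadings are
interpretable. It does not, however, extend gracefully to many classes: a
one-vs-rest reduction anchors every decision boundary on the global data
centre, which misplaces boundaries whenever classes lie along a shared
direction at different scales, and a manual web of one-vs-one models is
laborious and hard to read.

OPLS-HDA (hierarchical discriminant analysis) automates the one-vs-one
approach into a single, data-driven classifier:

1. **Pairwise models.** For each unordered pair of the N classes, fit a
   two-class OPLS-DA model on just those samples and cross-validate it —
   N(N−1)/2 models in total (66 for 12 classes).
2. **Distances.** Convert each pair's cross-validated predictions ŷ~cv~ into
   a Cohen's d separability: d = |m₁ − m₀| / s~p~, where m₀, m₁ are the
   class means of ŷ~cv~ and s~p~ = √((ss₀ + ss₁)/(n₀ + n₁ − 2)) is the
   pooled standard deviation from the within-class sums of squares.
3. **Hierarchy.** Cluster the classes agglomeratively on the symmetric
   Cohen's d matrix; the dendrogram's height axis stays on the Cohen's d
   scale.
4. **Decision tree.** Populate every internal dendrogram node with a fresh
   two-class OPLS-DA model that discriminates the pooled left classes
   (dummy 0) from the pooled right classes (dummy 1). A new sample starts
   at the top split and follows the node predictions down to a leaf.

Cross-validated (rather than fitted) predictions drive both component
selection and the distances, which is what protects the hierarchy from
overfitting-induced optimism.

## Model and algorithms

### OPLS core

With a single response, the PLS weight has the closed form
w = Xᵀy/‖Xᵀy‖, so no iterative NIPALS loop is required and fits are exactly
deterministic. Orthogonal components are extracted before the final
predictive component (the classic O-PLS order): for each component, the
y-orthogonal part of the current loading, w~o~ ∝ p − (wᵀp)w, defines scores
t~o~ = Xw~o~ that are projected out of X. Because t~o~ ⊥ y, the predictive
weight is invariant under these deflations. Every fitted model satisfies,
to 1e−8 or better: X = t~p~p~p~ᵀ + T~o~P~o~ᵀ + E, y = q·t~p~ + f,
t~p~ ⊥ T~o~, and w~p~ ⊥ W~o~.

Each two-class model uses exactly **one predictive component**: a single
dummy response spans a one-dimensional predictive subspace, so more would
be inconsistent with the decomposition. For prediction, OPLS with *a*
orthogonal components is identical to (a+1)-component PLS; the test suite
verifies this identity against an independent NIPALS PLS implementation to
1e−8 over random matrices.

Predictions are reported on the original 0/1 dummy scale (the training
response mean is added back), which makes decision thresholds directly
comparable to the 0/1 targets.

### Cross-validation and component selection

Folds are stratified by class: within each class, samples are shuffled
under a seeded RNG and dealt round-robin, with the round-robin position
carried across classes so that all k folds are used even when a class has
fewer samples than folds. No training fold can lose a class. The
preprocessor (centring/scaling) is refit inside every fold on the in-fold
samples only and applied to the held-out samples — the same rule applies at
every tree node — so ŷ~cv~ contains no leakage. PRESS = Σ(y − ŷ~cv~)² and
Q² = 1 − PRESS/SS~y~.

The number of orthogonal components is chosen sequentially: A+1 is kept
over A only when Q² improves by more than `q2GainThreshold` (default 0.01,
a small-gain rule in line with common chemometrics practice); selection
stops at the first failure, at `maxOrth` (default 5), or when the data
cannot support another component. Selection is re-run independently for
every pairwise model and every tree node, because each sees a different
class pooling. Defaults: 7 folds, fold seed 0, unit-variance scaling (the
dominant chemometrics convention; centre-only, Pareto and none are
available — for spectral data where scaling conventions differ, the choice
is exposed rather than guessed).

### Distances, clustering, thresholds

Cohen's d uses the absolute mean difference (a dendrogram needs a
dissimilarity); the degenerate case s~p~ = 0 with distinct means (perfect
noiseless separation) is capped at 1e6, far above any realistic value, so
linkage stays finite without affecting tree shape. Pairs are iterated, and
the matrix ordered, lexicographically by class name for reproducible
artifacts.

Clustering delegates to `stats::hclust` (Lance–Williams updates). Average
linkage (UPGMA) is the default: the Cohen's d matrix is not a Euclidean
distance, and average linkage is the least-assumption choice in that
setting; single, complete and Ward (`ward.D2` form) are available, with
Ward flagged as nonstandard for non-Euclidean input. Ties between equal
merge heights follow `hclust`'s deterministic rule; on real-valued Cohen's
d matrices exact ties have measure zero. The test suite checks the merge
sequence exactly against a brute-force O(N³) re-scan agglomerator on
hundreds of random matrices.

Each split's decision threshold is the **midpoint of the two
training-group mean fitted predictions**, not a fixed 0.5: pooled node
groups are typically unbalanced, and 0.5 is principled only for balanced
data. A prediction exactly at the threshold routes right (an arbitrary but
fixed tie rule; ties are again measure-zero). Splits are numbered 1..N−1 by
decreasing dendrogram height, so split #1 is always the top split.

### Reporting surfaces

Per split, the package produces volcano statistics (per-variable log2 fold
change on the original unscaled data, two-sided Welch t-test p-value, and
the significance gate p < 0.01 AND > 2-fold difference; a
Benjamini–Hochberg column is included for users who want multiplicity
control, but the gate itself uses raw p-values to match standard volcano
practice) and cross-validated score tables with 95% Hotelling's T²
ellipses. The ellipse semi-axes are √(λ~j~ · p(n−1)/(n−p) · F₀.₉₅(p, n−p))
along the score-covariance eigenvectors; with no orthogonal score the
region degenerates to the 1-D case, which reduces to a Student
t-interval. Variables with a nonpositive group mean are excluded from
ratio fold changes and flagged, never silently dropped.

## Synthetic data generators

Two seeded generators make every claim testable without external data:

* `makeIrisLike()` — three Gaussian classes in 2-D whose means are exactly
  collinear (petal-style measurements), one compact outlying class and two
  adjacent ones. This is precisely the geometry where one-vs-rest
  boundaries fail (they share a centre point) and a hierarchical model
  places both boundaries in the actual gaps.
* `makeHierarchical()` — a nested grouping tree (default: 12 classes as 4
  groups × 3 subclasses, echoing a two-factor design such as species ×
  processing state with one factor dominating) is walked from the root;
  each child's mean is its parent's plus an offset of magnitude
  `betweenScale · levelDecay^depth` along a random direction. Directions
  are drawn **mutually orthogonal** (Gram–Schmidt against all earlier
  offsets), so realized separations equal their nominal values exactly
  rather than only in expectation — with unconstrained random directions,
  occasional near-parallel offsets would silently violate the declared
  between/within separation. This requires at least as many informative
  variables as tree edges (16 for the default tree). Defaults: 40
  samples/class, within-class SD 1, betweenScale 4 (groups ≥ 4 within-SD
  apart, sibling subclasses √2·2 apart), decay 0.5, plus 5 pure-noise
  variables to exercise scaling and component selection.

What these generators deliberately do **not** emulate: correlated or
heavy-tailed noise, realistic NIR spectra or mass-spectrometry peak
tables, batch effects, class imbalance. Passing tests therefore
demonstrate the method's geometric and statistical machinery, not
robustness to every failure mode of real instruments.

## Numerical choices and degenerate inputs

* Scales are floored at 1e−12; constant columns transform to ~0 and are
  retained, keeping variable names aligned.
* Missing values are rejected at ingestion with an error naming the cell;
  imputation is upstream work.
* A constant response, a request for more orthogonal components than the
  rank supports, or a variable-count mismatch at prediction all raise
  informative errors; during component selection a rank failure simply
  stops the search.
* All randomness flows through two named seeds (fold seed, generator
  seed); model fitting itself is seed-free and bitwise reproducible.
  Models serialize to JSON with 17 significant digits, which round-trips
  IEEE doubles exactly, so a reloaded model predicts bitwise-identically.

## Problem sizes used in the tests

The property suite runs at deliberately desk-friendly sizes chosen as
representative rather than exhaustive: 50 random datasets
(n ∈ [10, 40], p ∈ [3, 60]) for the OPLS/PLS identity, 100 random 4–8
class matrices per linkage for the clustering oracle, 40 seeded replicates
of the 12-class generator for hierarchy recovery, and 20 seeds of the
three-class fixture for the hierarchical-vs-one-vs-rest comparison. The
`scripts/acceptance.R` script recomputes all of these quantities from
scratch against the installed package.

## Known limitations

* The class hierarchy is estimated from ŷ~cv~-based Cohen's d. When *all*
  class pairs are extremely well separated, every d is large and dominated
  by cross-validation noise rather than geometry, and tree topology above
  the obviously-separated level becomes arbitrary — the dendrogram is most
  informative when separability is graded, as in real biological data.
* There is no rejection option: every sample is routed to some leaf, even
  far outside the training support. Per-node Q² values are surfaced in
  logs and records so weak splits are visible, but they never refuse to
  classify.
* No probability calibration; outputs are hard labels plus per-node raw
  predictions in the path records.
* Multi-response OPLS, kernel variants, and spectral preprocessing (SNV,
  derivatives, baseline correction) are out of scope.

## A worked example

```{r example, eval = FALSE}
library(oplshda)

d <- makeIrisLike(seed = 1, nPerClass = 30)
model <- buildHda(d)
model
#> HdaModel: 3 classes, 2 splits, linkage = average
#>   split 1: {setosa} | {versicolor,virginica}  (A = 0, Q2 = 0.867)
#>   split 2: {versicolor} | {virginica}  (A = 0, Q2 = 0.802)

toNewick(model@dendrogram)
#> (setosa:12.99083757,(versicolor:3.966985979,virginica:3.966985979):9.023851589);

pred <- predict(model, datasetValues(d))
attr(confusionMatrix(datasetLabels(d), pred$labels), "accuracy")
#> [1] 1
```

The dendrogram heights are Cohen's d values: the compact outlying class
sits ~13 pooled-SD units from the adjacent pair, which are ~4 units apart
— the tree is the class map, and each split carries its own fully
interpretable two-class OPLS-DA model.
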