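---
title: "Methods: two-layer machine-vision grading of Daqu blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-layer machine-vision grading of Daqu blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daqugrade)
```

## The grading problem

Light-flavor Daqu is a solid-state fermentation starter pressed into blocks
of barley and peas. Its quality is judged from the block cross-section:
fermentation conditions leave visible traces — the color and uniformity of
the center, the presence of red mold spots or lines, cracks and blackened
rings from moisture loss, and the thickness of the raw starchy rim
("Pizhang") that never fermented through. Practitioners sort blocks into
premium (P), first grade (F) and second grade (S). `daqugrade` casts this
as a hierarchical image-classification problem: P and F look similar to each
other and different from S, so the first layer separates S from the pooled
{P, F}, and a second, more specialized layer separates P from F.

## Why a two-layer structure

A direct three-class model must spend capacity on the easy S-versus-rest
boundary and the hard P-versus-F boundary simultaneously. Splitting the
decision lets each layer use its own feature set: 14 coarse color/pixel
factors suffice for layer 1, while layer 2 adds 24 histogram factors (38
total) and a feature-selection stage, because the P/F difference is subtle
(a red spot, slightly different dark-area and rim statistics). Routing is
strict: an image decided as S by layer 1 never reaches layer 2.

## The synthetic image generator

The factory images behind this kind of system are proprietary, so the
package ships a seeded generator (`generate_daqu_image()`) that emulates the
grade cues at a configurable working size (default 400 × 600 px, one tenth
per axis of the 6000 × 4000 native acquisition resolution; the test suite
and acceptance script use 200 × 300 px, stated here as the package's chosen
problem size). Each image contains:

* a bright, lightly textured background (mean gray ≈ 220), chosen so the
  Otsu foreground/background polarity is unambiguous;
* a roughly rectangular block (rounded-corner rectangle, area fraction 0.62,
  jittered position);
* a Pizhang rim of pale starch color whose thickness grows with grade
  number (defaults 8/12/25 px at the 400 × 600 size, ±10% jitter);
* a grade-dependent center: concentrated grayish-blue for P; a red spot *or*
  line plus small dark edge patches for F; dark cracks, a black ring and
  larger dark edge patches for S;
* husk/straw debris as small elongated bright-yellow blobs touching the
  block boundary;
* optional multiplicative shadow gradient (off by default) and per-pixel
  Gaussian channel noise (sd 5, clipped to [0, 255]).

No quantitative palette for the grades is published anywhere we know of, so
the default colors encode only the qualitative descriptions (grayish-blue
versus warm gray versus dark gray centers). Identical `(grade, params,
seed)` triples give bit-identical rasters, and per-image seeds are derived
from a dataset master seed so any single image can be regenerated from the
manifest alone.

**What passing tests do and do not show.** The generator produces idealized
blocks: single connected component, controlled lighting, no perspective,
no real mold texture. Tests against it validate the *mechanics* of the
pipeline (masks, geometry, feature arithmetic, selector and classifier
behavior, routing, determinism) and the *relative* claims (morphological
fusion degrades least under shadows; the planted discriminative structure
is recoverable). They do not certify accuracy on real factory images.

## Segmentation

* **Otsu thresholding** scans all 256 thresholds for the maximum
  between-class variance, taking the smallest maximizer on ties. The method
  itself does not decide which class is foreground; we label as foreground
  the class whose mean is farther from the image-border mean, so
  a dark block on a bright background is always foreground. The mask keeps
  the largest connected component with holes filled. Constant images are
  flagged degenerate.
* **K-means** clusters per-pixel RGB vectors (k = 3 by default) with seeded
  k-means++ initialization and Lloyd iterations until the maximum center
  movement falls below `kmeans_tol` (1e-3) or `kmeans_max_iter` (50). The
  within-cluster sum of squares is recorded per iteration; it is
  non-increasing by construction and tested as such. Foreground clusters
  are those whose center lies closer (Euclidean) to a configurable block
  palette prior than to the border-sampled background color — the cluster
  count alone does not identify the target, and the choice of RGB space is
  a documented assumption.
* **Morphological fusion** runs a Canny detector (Gaussian pre-smoothing
  σ = 1.4; Sobel gradients; non-maximum suppression; hysteresis thresholds
  at 0.1/0.3 of the maximum gradient magnitude), dilates edges with a disc
  (radius 5 px at the 400 × 600 size) to close boundary gaps, fills holes as
  the complement of border-connected background, removes components smaller
  than `min_object_px` and keeps the largest. Hysteresis fractions are
  relative to the *maximum* gradient, so images with very strong internal
  edges (the cracks of S blocks) can miss part of the faint rim/background
  edge; this is an accepted property of the parameterization rather than a
  defect, and the feature stage is robust to it.

## ROI geometry

The block's minimum bounding rectangle is computed axis-aligned — the
acquisition geometry fixes block orientation, and the axis-aligned form is
deterministic and simple. The center ROI is a fixed rectangle (width 200 ×
height 500 px for layer 1, 120 × 500 for layer 2 at native resolution),
scaled linearly per axis to the working size, rounded to the nearest even
integer, centered on the bounding-rectangle center (the centroid was the
other candidate; the bounding-rect center is invariant to internal intensity
structure) and clipped to the bounding rectangle. The Pizhang ROI is the
remaining foreground; the partition is exactly disjoint and exhaustive, and
an empty Pizhang (center rectangle covering the whole block) is flagged, not
fatal.

## Features

The 14 base factors use the center ROI for the twelve color statistics and
the whole block mask for the two pixel factors, since the dark-area cue
explicitly concerns the block's edge region. Choices worth noting:

* HSV channels are normalized to [0, 1]; hue is circular, so `MeanHue` is
  the resultant-vector direction and `StdHue` the circular standard
  deviation `sqrt(-2 log R)/(2π)` — naive averaging misbehaves at the 0/1
  wrap (red hues).
* Standard deviations use the population (n) divisor.
* `DarkArea` counts foreground pixels with HSV value below 0.25. The
  threshold is a package choice (no published definition of "dark" exists
  for this task) and is exposed in the configuration.
* Histograms are stored as proportions (each channel's four bins sum to 1)
  so features are invariant to working resolution.
* The layer-1 task uses per-grade sample weights 1/1/2 by default, which
  balances the pooled {P, F} side against S exactly: with 100 images per
  grade, both sides carry 2800 weighted data points (200·1·14 = 100·2·14),
  and the layer-2 task carries 3800 per grade (100·38). The weights are
  passed through to learners that support them.

## Feature selection

All four selectors operate on the layer-2 task with binary labels coded 0/1,
which lets the regression-form penalized objectives apply as written.

* **RF-MDA**: a random forest is fitted once; each feature's score is the
  mean drop in per-tree out-of-bag accuracy when that feature's column is
  permuted, averaged over `n_repeats` permutations with the forest held
  fixed. Per-tree accounting (each tree scored on its own out-of-bag
  samples) is used deliberately: ensemble-level out-of-bag accuracy barely
  moves when one of several redundant informative features is permuted,
  while per-tree accounting still credits them. A constant column scores
  exactly 0.
* **RFE** computes the full elimination order (refitting after every drop;
  ranking by |coefficient| of a regularized logistic fit, or impurity
  importance of a forest) and keeps the top `n_keep` (default 20).
* **LASSO** standardizes features, centers the response and minimizes
  RSS + λ‖β‖₁. The solver is glmnet with the penalty mapped as
  λ_glmnet = λ/(2n); correctness is pinned by closed-form tests
  (soft-threshold solution for one predictor, OLS at λ = 0, all-zero
  coefficients beyond λ_max = 2·max|X'y|). Selected features are exactly
  the nonzero coefficients at the cross-validated λ.
* **Ridge** is solved in closed form, β̂(λ) = (X'X + λI)⁻¹X'y on
  standardized features, cross-validated over the default grid of 100
  log-spaced λ in [0.01, 100] with 10 folds. The original description of
  this λ search interposes a Gaussian-process regression inside the
  cross-validation loop, which cannot be reconciled with the ridge
  objective itself; this package takes the standard reading — the ridge
  model is fitted per λ and the λ minimizing mean squared error wins.
* Retention for RF-MDA/RFE/ridge: positive score after rounding at 1e-4,
  capped at the top 20 (a scale at which all four methods return subsets of
  comparable size); LASSO retains nonzero coefficients. Both cutoff and cap
  are configurable; a cutoff of −∞ yields the identity selector.

## Classifiers and stacking

Defaults (none are prescribed by the task): SVM with RBF kernel and C = 1;
random forest with 500 trees; logistic regression with unit-strength L2
regularization (stable under perfect separation, supports observation
weights); KNN with k = 5, Euclidean distance on standardized features and
distance ties broken by the smallest training index so prediction is
deterministic. SVM/LR/KNN consume standardized features (training-set
mean/variance bound at fit time); trees consume raw features.

Stacking trains RF, LR and KNN as base learners and aggregates their
*out-of-fold* positive-class probabilities (5 folds by default) into an
n × 3 meta-feature matrix for the meta-learner (RF → S-RF, LR → S-LR).
Out-of-fold construction is chosen over in-sample base predictions to keep
the meta-learner from learning the base learners' training error (the
leakage-safe variant); hard-label meta-features are available via
configuration.

## Evaluation protocol

Positive classes are fixed so precision/recall are well defined: the pooled
{P, F} at layer 1 and P at layer 2. Metrics follow the standard confusion
arithmetic; zero-denominator cells return a flagged 0 instead of raising, so
experiment grids always complete. ROC curves sweep the distinct scores with
ties grouped; the trapezoidal AUC then equals the Mann–Whitney concordance
statistic with half credit for ties, which is the oracle used in tests. The
data protocol is a stratified 60/20/20 train/validation/test split plus
stratified k-fold cross-validation; both are exposed independently
(`stratified_split()`, `cross_validate()`) because published descriptions of
such protocols often mix the two — callers choose. Runtime columns in the
benchmark harness are reported but never asserted.

## Numerical and degenerate-input policy

Constant images, blank edge maps, empty selector outputs and empty Pizhang
regions are flagged rather than fatal wherever an experiment harness must
survive them, and errors elsewhere name the failing stage. All randomness is
seeded: dataset seeds fan out from a master seed, pipeline stages derive
seeds by fixed offsets from the configuration's master seed, and forests,
folds, permutations and k-means++ draws all take explicit seeds. Identical
configuration plus master seed reproduces every artifact bit for bit
(timings excluded).

## Problem sizes used by the shipped checks

The test suite and acceptance script generate corpora of up to 100 images
per grade at 200 × 300 px, run 20 seeded selector-recovery replicates
(n = 200, 38 features, planted effect size 1.5 on two features) and evaluate
the full two-layer system over 5 seeded corpora — sizes chosen as a
practical desk-scale study design. Selector-recovery replicates reduce the
RF-MDA budget to 150 trees and 2 permutation repeats; all other settings are
the package defaults.

## Known limitations

* The generator's idealizations (see above) mean synthetic accuracies say
  nothing quantitative about factory images.
* The axis-aligned bounding rectangle and fixed-size center ROI assume the
  standardized acquisition geometry; rotated or partially occluded blocks
  are out of scope.
* K-means operates in RGB; a perceptually uniform space might segment
  differently.
* No probability calibration and no hyperparameter search beyond the λ grid
  are performed.
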