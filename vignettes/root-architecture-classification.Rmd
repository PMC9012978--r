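---
title: "Classifying root system architecture from root-crown images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying root system architecture from root-crown images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootarch)
```

## The problem

Breeding perennial forage crops such as alfalfa for root system
architecture (RSA) requires classifying excavated, washed and photographed
root crowns into discrete types: **branch-rooted (B)** — a thinner taproot
carrying 4–6 thick lateral roots at 1–2 cm intervals; **tap-rooted (T)** —
a dominant taproot with fewer than four thin laterals spaced 3–4 cm apart;
and an **intermediate (TB)** type — four or more laterals spaced more than
2 cm apart, plus anything neither clearly B nor T. Visual scoring of these
types is slow and rater-biased. `rootarch` implements an objective
pipeline: binary root-crown images are reduced to a 38-trait morphological
vector, six classifiers are benchmarked on those traits under repeated
stratified cross-validation, and every prediction carries a class
probability that is banded into confidence tiers for selection decisions.

Because the pipeline must be testable without any image downloads, the
package includes a first-class synthetic generator that renders labelled
binary crowns with the statistical structure of the three phenotypes.
Externally segmented images ingest through the same path
(`ingest_external()`), so the pipeline applies unchanged to real archives.

## The synthetic generator

`generate_root_image()` renders a crown as a vertically descending taproot
(quadratic diameter taper from a class-specific crown diameter down to
0.6 mm, mild sinusoidal wobble), lateral roots emerging at class-rule arc
spacing on alternating sides at 20–70° below horizontal, and fine 1-px
rootlets. Class parameters follow the phenotype rules directly; where the
rules are silent the defaults were fixed once at values a field root
phenotyper would call realistic, and are not tuned thereafter:

| parameter | B | TB | T | rationale |
|---|---|---|---|---|
| lateral count | 4–6 | 4–5 | 0–3 | class rules |
| lateral spacing (mm) | 10–20 | 21–25 | 30–40 | class rules ("1–2 cm", ">2 cm", "3–4 cm") |
| lateral thickness (mm) | 2.0–3.2 | 1.0–2.4 | 0.5–1.2 | "thick" vs "thin"; TB straddles the gap |
| taproot crown diameter (mm) | 5–8 | 6–12 | 9–13 | thin taproot for B, dominant for T; TB spans both |
| fine rootlets per cm | 0.5 | 0.35 | 0.2 | creates tips, holes and diameter-range-1 signal, ordered B > TB > T |

The taproot is 110 mm long on a default 1200 × 900 px canvas; each image
in a dataset draws its own pixel scale from `px_per_mm_range`
(default 8–10 px/mm), emulating the varying camera working distance of
field photography. The intermediate class deliberately overlaps B in
lateral count and both extremes in thickness and spacing, which makes TB
the hardest class for every classifier — matching what raters experience.
Spacing draws that would overrun the taproot are redrawn from the same
interval (falling back to the interval minimum), so the recorded ground
truth always satisfies the class rule.

What the generator does **not** emulate: soil occlusion, broken or
overlapping crowns, segmentation errors, photographic noise, and the
biological correlation structure of real trait tables. Passing tests on
synthetic data therefore demonstrate that the pipeline's machinery is
correct and that its qualitative orderings hold under controlled
conditions; they do not certify accuracy values on any real archive.

## Trait extraction

`extract_traits()` computes 38 traits (`trait_names()` gives the column
order). The core quantities:

* **Skeleton**: Zhang–Suen thinning gives the 1-px medial axis; spur
  branches of ≤ 2 px (configurable) are pruned. Tips are degree-1 skeleton
  pixels; adjacent degree-≥3 pixels merge into one branch point.
* **Lengths** sum the skeleton pixel graph's edges (1 px orthogonal,
  √2 px diagonal, with shortcut diagonals removed).
* **Diameters** come from the Euclidean distance transform: the local
  radius at a skeleton pixel is its distance to background minus half a
  pixel. Surface area and volume integrate 2πr and πr² along the skeleton.
* **Diameter ranges** bin each skeleton step by its *pixel* diameter at
  breakpoints 10 and 20 px before any unit conversion, because the ranges
  are defined on pixel images while the per-image scale varies. The
  per-range length/projected-area/surface/volume traits sum exactly to the
  whole-root totals.
* **Angles**: local orientation from the principal axis of the skeleton
  inside a 7 × 7 px window (single-pixel orientations are unstable; the
  window is a settings knob), length-weighted into shallow [0°, 30°),
  medium [30°, 60°) and steep [60°, 90°] frequencies.
* **Holes** are 4-connected background components not touching the image
  border (foreground uses 8-connectivity — the standard complementary
  convention).
* **Convex hull** is taken over pixel corners so solidity =
  area/hull ≤ 1 even for thin shapes; **lower root area** is the
  foreground below 1/3 of the crown depth from the top (the fraction is
  configurable, since the trait has no canonical formula).
* All pixel quantities convert to mm, mm², mm³ with the per-image scale.

Degenerate images whose skeleton has no edges return length-type traits
of 0 with zero angle frequencies and a `degenerate` flag rather than
failing; `batch_extract()` collects per-image errors into a report and
never drops a batch silently.

This trait set is a faithful re-implementation of the standard whole-root
crown analysis, not a bit-for-bit clone of any existing tool; the exact
38-column composition is documented by `trait_names()` and should not be
assumed identical to other software's output.

## Augmentation

`augment_dataset()` applies, per source image, ten (configurable)
independent transforms with rotation ~ U(−20°, 20°) and isotropic scale
~ U(0.8, 1.2), by nearest-neighbour inverse mapping on an enlarged canvas
(binary stays binary; nothing is clipped). The pixel scale is inherited
unchanged, so a scale factor really changes measured mm sizes — the same
effect as moving the camera. Every transform is logged
(source id, replicate, rotation, scale, seed) and the augmented images are
re-extracted with the same trait module; trait-space augmentation is
deliberately not offered. Cross-validation groups augmented descendants
with their source by default so that no augmented sibling of a test crown
is seen in training; `grouped_by_source = FALSE` reproduces the literal
ungrouped protocol, whose accuracy benefits from that leakage by an amount
the package does not attempt to adjudicate.

## The six classifiers

`rsa_classifier()` is the single fitting surface; `predict()` always
returns the three class probabilities, the argmax class (ties break
B < T < TB) and the maximum probability.

* **k-means** (`stats::kmeans`, Hartigan–Wong, `iter.max = 100`,
  10 restarts) and **PAM** (`cluster::pam`, Euclidean) cluster the min-max
  normalized trait matrix with k = 3. Clusters are mapped to classes
  *after* fitting by the agreement-maximizing one-to-one assignment over
  the 3! permutations (`align_clusters()`); the labels never influence the
  clustering itself. Cluster assignments are reported as one-hot
  probability triples, since a partition carries no calibrated
  probability.
* **Random forest** (`randomForest`, `ntree = 500`,
  `mtry = floor(sqrt(38)) = 6`): probabilities are tree-vote fractions.
* **Naive Bayes** (`e1071`, Gaussian class-conditionals; the
  `laplace = 1` argument is accepted and recorded but inert for continuous
  predictors, matching that implementation's semantics).
* **Classic MLP**: layers 38–15–10–5–3, logistic activations, summed
  cross-entropy on logistic outputs, trained full-batch by resilient
  backpropagation with weight backtracking (η⁺ = 1.2, η⁻ = 0.5,
  Δ₀ = 0.1, Δmax = 50 — the standard Rprop constants), gradient threshold
  0.01, `stepmax = 1e5`. Hitting the cap warns and returns the model,
  mirroring the known overfitting/instability of this architecture on
  small trait tables. A 1000-step loss plateau also halts training, since
  continuing a flat full-batch optimization only costs time. Output
  activations are normalized to sum to one.
* **Modern MLP**: same layer sizes with ReLU hidden units, softmax
  output, categorical cross-entropy, Adam (lr 0.001, batch 32, up to
  200 epochs, early stop after 20 epochs without improvement). Batch size
  and epoch budget are recorded in the fitted object so runs are
  reproducible.

Normalization is fit on the training fold only for supervised models (a
leakage guard); the unsupervised models normalize and cluster the full
matrix once by default — matching the benchmark protocol — and score the
fixed partition inside each test fold. `unsupervised_mode = "per_fold"`
provides the methodologically stricter variant. Supervised models are
trained on normalized traits by default; this is a package decision
(`normalize = FALSE` is available), as the original protocol states
normalization only for the clustering methods.

## Evaluation and confidence tiers

`evaluate_model()` runs 3× repeated stratified 5-fold CV (or a 70/30
holdout) and returns per-fold and pooled reports of the seven quality
metrics computed one-vs-rest from the confusion matrix: sensitivity,
specificity, PPV, NPV, precision (= PPV by definition), prevalence and
balanced accuracy = (sensitivity + specificity)/2. The "prevalence"
reported by the benchmark tables this package mirrors is the *predicted*
class share; `compute_metrics()` carries both `prevalence_predicted` and
`prevalence_true` under unambiguous names. Balanced accuracy is
implemented as the per-class mean of sensitivity and specificity — the
definition every published cell of those tables satisfies — while the
plain proportion correct is exposed separately as `overall_accuracy()`.
Macro means are unweighted over the three classes; zero-denominator
classes yield NaN and are excluded with a warning. `compare_models()`
performs the two-sided (optionally paired) t-test on per-fold balanced
accuracies, degenerating gracefully to p = 1 for identical vectors.

`assign_tier()` bands the maximum class probability into seven
right-closed tiers LLL (0, 0.4], LL (0.4, 0.5], L (0.5, 0.6], M
(0.6, 0.7], H (0.7, 0.8], HH (0.8, 0.9], HHH (0.9, 1]. The published tier
bounds contain two obvious typos ("0.810 to 0.900", "0.0901 to 1.00");
the canonical bounds above repair them into a contiguous partition. A
`"table"` mode widens LL to (0.400, 0.510] because the published worked
examples grade printed 0.508 values as LL; the canonical mode is the
default and the regression fixtures use the table mode. Two of the 17
shipped worked-example rows are internally inconsistent at printed
precision (a max-probability that does not match its own probability
triple) and are excluded from regression assertions rather than guessing
which figure is wrong. `select_high_confidence()` retains predictions
with max probability strictly above a threshold (default 0.9) and reports
retention and subset accuracy.

## Problem sizes, seeds and numerical choices

The package's full-scale default is the 617-crown design
(B 237 / T 245 / TB 135) at 1200 × 900 px. Tests and the acceptance
script use the quick profile — one fifth of the counts (48/49/27) on a
480 × 360 px canvas at 3–4 px/mm — which preserves every qualitative
property of the full design while keeping a complete run to a few
minutes; this is the package's chosen benchmark size, stated here so
readers know what the shipped checks actually executed. Every stochastic
stage takes an explicit integer seed and derives per-image sub-seeds below
2³¹; identical seeds give bit-identical images, folds and fitted models.
Ties in probability argmaxes break deterministically in class order
B < T < TB; cluster-to-class alignment ties break on the first-enumerated
permutation.

Known limitations: synthetic crowns are cleaner and more separable than
field images, so absolute synthetic accuracies sit near the ceiling and
should not be quoted as expected field performance; the classic MLP is
genuinely unstable (that instability is the published finding, and the
package reproduces rather than repairs it); and clustering "probabilities"
are one-hot by construction, so confidence tiers are only meaningful for
the supervised models.
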