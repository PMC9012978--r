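# rootarch

Objective classification of root system architecture (RSA) from
root-crown images, for breeders selecting rooting types in perennial
crops such as alfalfa.

Excavated root crowns fall into three architecture types: **B**
(branch-rooted: 4–6 thick lateral roots at 1–2 cm intervals along a
thinner taproot), **T** (tap-rooted: a dominant taproot with fewer than
four thin laterals 3–4 cm apart) and **TB** (intermediate: four or more
laterals spaced more than 2 cm apart, or anything neither B nor T).
`rootarch` replaces visual scoring with a reproducible pipeline:

1. **Images → traits.** A binary crown raster is skeletonized
   (Zhang–Suen thinning, spur pruning), local root radii are read from
   the Euclidean distance transform, and 38 morphological traits are
   computed: tips, branch points, branching density, total length, depth,
   width, network/convex-hull area, solidity, lower root area, perimeter,
   surface area, volume, hole statistics, angle frequencies
   (shallow/medium/steep from horizontal), diameter summaries, and
   length/area/volume inside three pixel-diameter ranges (≤10, 11–20,
   ≥21 px), all converted to mm units with the per-image pixel scale.
2. **Traits → class.** Six classifiers behind one interface
   (`rsa_classifier()`): k-means (Hartigan–Wong) and PAM with
   post-hoc agreement-maximizing cluster→class alignment; random forest
   (ntree = 500, mtry = ⌊√38⌋ = 6); Gaussian naive Bayes; and two
   15–10–5 multilayer perceptrons (logistic/Rprop+ "classic" and
   ReLU/softmax/Adam "modern"). Traits are min-max normalized,
   y' = (y − y_min)/(y_max − y_min).
3. **Benchmarks.** 3× repeated stratified 5-fold cross-validation (or a
   70/30 holdout) with seven one-vs-rest metrics per class — sensitivity,
   specificity, PPV, NPV, precision, prevalence and balanced accuracy
   = (sensitivity + specificity)/2 — plus macro means, per-fold mean/SD
   summaries and pairwise t-tests between models.
4. **Confidence tiers.** Each prediction's maximum class probability is
   banded into LLL…HHH tiers; retaining only calls with probability
   > 0.9 yields near-perfect selection, which is the decision rule a
   breeder actually needs.
5. **Augmentation.** Constrained image augmentation (rotation ±20°,
   scale 80–120 %, 10 replicates per image, fully logged) enlarges small
   labelled sets; cross-validation keeps augmented descendants in the
   same fold as their source by default.

A built-in synthetic generator (`generate_root_image()`,
`generate_dataset()`) renders labelled binary crowns obeying the three
class rules — including class imbalance, per-image pixel-scale variation
and a deliberately overlapping TB class — so the whole pipeline is
testable offline; externally segmented PNG archives load through
`ingest_external()`.

## Worked example

```r
library(rootarch)

# a small labelled synthetic study: 31 crowns at 3-4 px/mm
ds <- generate_dataset(c(B = 12L, T = 12L, TB = 7L),
                       px_per_mm_range = c(3, 4), canvas = c(480L, 360L),
                       seed = 42)
labels <- vapply(ds$truths, `[[`, "", "label")
traits <- batch_extract(ds$images)

fit <- rsa_classifier(traits[, trait_names()], labels, method = "rf",
                      seed = 1)
cv <- evaluate_model(traits[, trait_names()], labels, "rf",
                     plan = cv_plan(seed = 1))
cv
#> <rsa_cv: rf, 15 scored folds; pooled macro balanced accuracy 0.993>

head(predict(fit, traits[1:3, trait_names()]), 3)
#>   prob_B prob_T prob_TB predicted_class max_probability
#> 1  0.000      1   0.000               T           1.000
#> 2  0.980      0   0.020               B           0.980
#> 3  0.988      0   0.012               B           0.988
```

The CV object holds per-fold and pooled reports of all seven metrics
(`cv$pooled`), the per-root probability table (`cv$predictions`), and
feeds the confidence module:

```r
sel <- select_high_confidence(cv$predictions, threshold = 0.9,
                              truth = cv$predictions$truth)
sel$report
#> $n_total 93  $n_selected 45  $retention_rate 0.484  $accuracy 1
```

Here 48 % of cross-validated calls exceed probability 0.9 and every one
of them is correct — the high-confidence retention rule in action.
`run_experiment(run_config(quick = TRUE))` drives the whole pipeline
(simulate → extract → augment → benchmark all six models → confidence
report) and writes every stage table as CSV.

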