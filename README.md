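# morphopotency

Donor variation is the chronic problem of adult stem-cell therapy: cells
from different donors differentiate with very different efficiency, and the
assays that measure multipotency (e.g. SSEA-3 immunofluorescence) are
terminal. `morphopotency` implements a morphology-based alternative for
two-channel single-cell fluorescence images: detect single cells in the
cell-body (CD105) channel, label them multipotent/non-multipotent from the
potency-marker (SSEA-3) channel by an intensity threshold, train a small
convolutional network to predict that label from cell shape alone, and
report per-donor multipotency ratios with bootstrap intervals — the quantity
a cell-therapy lab would use to rank donors.

The package is a complete, tested R implementation of that pipeline:

* **`imaging_sim`** — a synthetic cohort generator (`donor_profile()`,
  `generate_cohort()`) with planted per-donor multipotency fractions and a
  configurable shape–potency *coupling*; cell shapes are calibrated to the
  reference family means (round: circularity 0.469, aspect ratio 1.528;
  elongated: 0.262, 4.162). Because the original images are not public, all
  tests and examples run on this generator, where the ground truth is known.
* **detection** — `detect_cells()`: Otsu/connected-components fallback and a
  selective-search emulation (`oversegment()` graph partition +
  `hierarchical_merge()` by color/texture/size/fill similarity), with IoU
  deduplication and congruent two-channel crops.
* **labelling & datasets** — `label_crop()` (Positive iff marker statistic
  > 90 on the 0–255 scale), `stratified_split()` (largest-remainder 70/10/20;
  1850 items give exactly 1295/185/370), `normalize_resize()` (224×224,
  min–max), `augment_train()` (exact ×4: rot90, h-flip, v-flip).
* **classifier** — `build_model()` / `train_cnn()` / `predict_cells()`: a
  scratch CNN (three 16/32/64 conv blocks) under the fixed head
  dropout(0.4) → global max pool → dropout → dense(64, ReLU) → batch norm →
  dropout → dense(2, softmax), trained with Adam and categorical
  cross-entropy, ≤ 50 epochs, early stopping at patience 10. The engine is
  pure R on BLAS matrix products; no deep-learning framework is required.
* **evaluation** — `compute_metrics()` (confusion matrix, accuracy,
  sensitivity, specificity, F1, trapezoidal AUC) and `crossvalidate()`
  (stratified 5-fold, "mean ± sd" reporting).
* **learning-rate search** — `gp_fit()` / `expected_improvement()` /
  `optimize_learning_rate()`: Matérn-5/2 GP surrogate, EI acquisition on
  log10(lr) ∈ [−5, −1], 3-point initial design, 10 iterations × 5 pooled
  repeats.
* **morphometry** — `extract_contour()` (sub-pixel marching squares),
  `resample_equidistant()` (50 points), `register_contours()`,
  `eigenshape_pca()`, `cluster_shape_modes()` (k-means++, 20 modes,
  top-5 reporting), `shape_descriptors()` (circularity 4πA/P², best-fit
  ellipse aspect ratio), `donor_shape_distribution()`.
* **reporting** — `donor_potency()` (ratio + 95% percentile bootstrap CI +
  Rogan–Gladen-corrected column), `rank_donors()`, `recovery_report()`, and
  the one-call chain `run_potency_pipeline()`.

## Worked example

Five donors with planted multipotency fractions 0.20–0.80 at coupling 0.9
(round cells are multipotent with probability 0.9); 60 cells per donor for
training, classifier input side 112:

```r
library(morphopotency)

profiles <- mapply(donor_profile, paste0("S", 1:5), 60,
                   c(0.2, 0.35, 0.5, 0.65, 0.8), 0.9, SIMPLIFY = FALSE)
pipe <- run_potency_pipeline(profiles, cohort_image_config(), seed = 101,
                             side = 112L,
                             spec = model_spec(input_side = 112L),
                             config = train_config())
print(pipe)
```

```
potency_pipeline (seed 101): 300 cells detected, test accuracy 0.836
  donor_id n_cells     ratio    ci_low   ci_high truth_fraction  abs_error
1       S1      60 0.2166667 0.1166667 0.3166667      0.2333333 0.01666667
2       S2      60 0.3833333 0.2666667 0.5166667      0.3333333 0.05000000
3       S3      60 0.6333333 0.5166667 0.7500000      0.6833333 0.05000000
4       S4      60 0.5500000 0.4166667 0.6833333      0.5500000 0.00000000
5       S5      60 0.7833333 0.6666667 0.8833333      0.8333333 0.05000000
```

Reading: the model was trained only on the body-channel crops, yet the
estimated per-donor ratios (`ratio`, with 95% bootstrap intervals) track the
planted fractions (`truth_fraction`) within five points everywhere, and
ranking donors by `ratio` recovers the ordering of the planted fractions
this cohort actually realized (at 60 cells/donor the S3/S4 binomial draws
landed at 0.68 and 0.55, inverting their nominal 0.50/0.65 order — which the
estimates reproduce faithfully). On larger, independently generated
evaluation cohorts (200 cells/donor) the same model scores held-out accuracy
near 0.89. The residual compression toward
0.5 at the extreme donors is the expected misclassification bias of the raw
ratio (≈ s·π + (1 − p)(1 − π)); the `corrected_ratio` column removes it when
sensitivity/specificity estimates are supplied.

Morphometry on the same cohort:

```r
masks <- lapply(pipe$cohort$masks, `[[`, "mask")
model <- fit_shape_modes(masks, n_points = 50, k_modes = 20, seed = 1)
head(model$explained_variance, 3)
```

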