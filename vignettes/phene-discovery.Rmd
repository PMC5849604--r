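---
title: "Tissue phene discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue phene discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenescan)
```

This vignette documents the statistical model behind `phenescan`, the
parameters that matter, what the synthetic cohort generator does and does
not emulate, and the design decisions taken where the methodology was
genuinely open. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` compute.

## The region system

Object-level input — marker-labelled cell coordinates (µm) and classified
gland polygons — is aggregated on a raster of 100 µm/px by default
(`rasterize_objects()`). Regions are derived from the gland raster
(`define_rois()`):

* the **tumor** region is the support of the non-intact (cancerous) gland
  area fraction, smoothed by morphological opening then closing with a
  disc of 1 pixel radius (the operators are standard; the radius is our
  choice — at 100 µm/px a 1-px disc removes single-pixel speckle without
  erasing small gland clusters);
* **border1** (112.5 µm) and **border2** (225 µm) are outer bands cut from
  the Euclidean distance transform of the tumor mask — distance-transform
  thresholding rather than iterated structuring elements, so band geometry
  is resolution-independent;
* the **innerBorder** spans 56 µm to each side of the tumor boundary;
* **healthy** is the smoothed intact-gland support outside the tumor;
  **stroma** is the remaining tissue; **ws** is all tissue.

A pixel's distance to the tumor boundary is taken as
$(d_{px} - 0.5)\,\mathrm{res}$, i.e. centre-to-region-edge; the brute-force
oracle in the test suite uses the same convention, so the tests check the
geometry, not the convention. Label precedence when zones overlap is
tumor > innerBorder > border1 > border2 > healthy > stroma; the raw labels
partition the grid, while the *measurement* regions are cumulative
(`border2` spans the full 225 µm band and therefore contains `border1`).
Tissue is the union of gland supports and a 300 µm neighbourhood of any
cell-bearing pixel (`tissue_radius`); real pipelines detect tissue on the
raw slide, which is unavailable at the object level, so the rule is
config-exposed. `tissue_radius = Inf` declares the whole slide tissue and
is what the synthetic generator uses.

## Measurement families and the candidate grammar

Per region we compute counts and densities (cells/mm²) per marker, mean
distances of each region's cells to their 4 or 8 nearest neighbours of a
second marker (neighbours searched slide-wide: relevant partner cells, e.g.
vessels supplying border macrophages, may lie just outside the region),
count ratios of ordered marker pairs (same region, plus a few cross-region
pairs anchored on the tumor border), and a Haralick correlation over the
gland-class co-occurrence matrix (8-neighbourhood, symmetric accumulation;
gland size classes are cohort-wide area terciles). Ratios with a zero
denominator, distances with fewer than `k` neighbour cells and densities
of empty regions are missing values — never imputed — and candidates
missing in more than 20% of patients are dropped before ranking. The
default grammar yields 553 candidates, deliberately "several hundred" for
a 90-patient cohort, the regime in which honest cross-validation matters.

Whether ratios should use counts or areas is ambiguous in practice; we use
object counts (the `#marker_region` notation), which for cells of roughly
constant size differ from area ratios by a near-constant factor that a
threshold absorbs.

## Cutpoint optimization

For one candidate, thresholds are the midpoints of consecutive sorted
unique values restricted to the closed interval between the medians of the
event and non-event class. For each threshold and operator direction a
patient is classified non-progression if `value OP threshold`; accuracy is
the fraction of patients whose predicted class matches the binary event
flag, and the split's log-rank p-value is computed from the hypergeometric
moments at each event time. **The selected model maximizes accuracy, with
ties broken by smaller p-value, then smaller threshold.** We initially
implemented the opposite order (p first) and rejected it on mathematical
grounds: with well-separated classes the log-rank chi-square is maximized
by splitting off the few earliest events, not by the separating threshold,
so a pure minimum-p rule *never* selects a perfectly separating cutpoint —
a degenerate behaviour of minimum-p cutpoint selection at small n.
Accuracy-first matches the accuracy-centric ranking used throughout the
pipeline and reduces the p-value to an arbiter among equally accurate
cutpoints. Candidates with identical values, equal class medians, or no
midpoint between the medians are unrankable and ranked last.

The implementation scores all thresholds of a candidate in one pass
(at-risk and event indicator matrices times a threshold-membership
matrix), which is what makes leave-one-out ranking of ~500 candidates and
100 permutations affordable; the log-rank core is validated against
`survival::survdiff` to 1e-8 in the tests. Censored patients carry the
non-progression class label throughout — how censored patients entered the
published accuracy is not stated anywhere we could find, and this is the
main interpretive risk of the accuracy measure; it is at least consistent
between training, cross-validation and the permutation null.

## Cross-validated ranking, selection, stratification

Leave-one-out cross-validation re-optimizes every candidate's threshold on
each n−1 training set, records per-fold top-5 membership (robustness), and
classifies the held-out patient. Candidates are finally ranked by
cross-validated accuracy, then top-5 count, then the log-rank p-value of
the aggregated out-of-fold predictions. The per-fold lists are ranked by
training accuracy (ties by training p) — the alternative, ranking by
training p, is noted but not used, consistent with accuracy-based final
ranks. The operator direction of the reported model is the majority
direction across folds.

Selection proceeds in fixed order: accuracy floor (cv accuracy ≤ 50%
removed, inclusively), iterative correlation filter in rank order keeping
the higher-ranked member of any pair with |r| ≥ 0.75 (zero-variance
columns count as correlation 0 and are flagged), multiple-testing
correction of the aggregated-prediction log-rank p-values (Holm step-down
by default; Bonferroni and Benjamini–Hochberg available), then CART
subset selection: depth-2 Gini trees with minimum leaf size 5 under
LOOCV, counting per phene the folds that used it at any split.

Stratification evaluates the selected set uni-variately (per-fold
threshold models) and multi-variately. Feature z-scoring uses fold-train
statistics only; missing values sit at the training mean (0 after
z-scoring). "Bayes classifier" is Gaussian naive Bayes and "linear
predictor" a least-squares score thresholded at 0.5 — the generic terms
name families, and these are their simplest members; the RBF-SVM
bandwidth uses the median pairwise training distance and cost 1.
Hierarchical clustering uses 1 − Pearson correlation between patient
profiles with average linkage, cut after the top-most branching; mapping
the two clusters to classes by majority true label is an evaluation-time
device and makes the clustering accuracy optimistic relative to the
supervised LOOCV numbers — it is reported, as is conventional, with that
caveat.

## The permutation null

Shuffling patient-to-outcome alignment and re-running the (non-CV)
training ranking 100 times yields the distribution of the best accuracy
attainable by pure selection. With ~90 patients and hundreds of
candidates this null concentrates near 0.68–0.69 — far above the 0.56
majority-class fraction — which is precisely why cross-validation and the
permutation test are needed. The per-phene empirical p-value uses the
add-one estimator (1 + exceedances)/(n_perm + 1).

A finding worth stating plainly: the log-rank p-values on LOOCV-aggregated
predictions of *null* candidates are not uniformly distributed — per-fold
cutpoint optimization leaves a residual anti-conservative tail, so Holm
correction of these p-values controls the family-wise error only
approximately (the package's acceptance suite measures the rate; in our
null experiments roughly one seed in six yielded a non-empty
Holm-significant set). Discoveries should therefore always be read
together with the permutation null, which is selection-aware by
construction.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 90 patients, 40
events, follow-up 2–118 months, one slide per patient with clustered
non-intact glands (log-normal radii around 110 µm), scattered intact
glands, and marker cells placed by an inhomogeneous Poisson process over
the region raster with region multipliers concentrating immune cells at
the tumor border. Baseline densities (cells/mm²: CD3 60, CD8 40, CD68 30,
CD163 30, CD34 50, negative 100) are in the range a practitioner would
call realistic for prostate tissue at these markers; slides default to
4000 × 4000 µm (2500 × 2500 µm in the heavier multi-seed experiments, a
problem-size choice documented here once).

A planted effect `(phene, coef)` draws a latent score z ~ N(0,1) per
patient and adds `coef · z` to the latent hazard
`η = Σ coef_j z_j + ε`, ε ~ N(0, 0.5). The n_events patients with the
largest η progress (event count is exact by construction); their event
times are drawn from a Weibull proportional-hazards model given η (shape
2, chosen for closed-form sampling; any monotone link suffices for
recovery tests) and mapped monotonically into the follow-up window;
censored patients get uniform follow-up and the non-progression label.
The frailty scale 0.5 makes a coefficient of 1 twice the unexplained
hazard noise — "large" planted effects dominate, which is what the
recovery experiments require. Spatially, z multiplies the phene's
numerator marker density in its region by `exp(0.5 z)` (denominator or
neighbour marker by `exp(−0.5 z)`), so the measured phene carries the
planted association through genuine Poisson sampling noise.
CORR_HARALICK names cannot be planted (no density-shift realization
exists) and are rejected at config time. An optional flag reproduces the
36-month event-time aggregation artefact seen in registry data with
approximate recurrence dating (off by default).

What the generator does **not** emulate: stain intensity and segmentation
errors, section co-registration error, realistic gland morphology (discs
suffice — downstream statistics see only class labels and positions),
informative censoring, and correlated multi-marker biology beyond the
planted effects. Passing recovery tests therefore demonstrates that the
*mining machinery* finds planted spatial signal through measurement
noise; it says nothing about biological validity on real cohorts.

One identifiability point shapes the recovery experiments: spatial
planting of a ratio A/B creates a whole family of informationally
overlapping candidates — B/A is a decreasing monotone transform of A/B
and provably attains identical cutpoint accuracy, and ratios of the same
markers in wider regions carry diluted copies of the signal. Exact-name
rank 1 is therefore only well-defined against candidates that do not
share the planted markers, and that is how the planted-recovery
acceptance experiment is constructed.

## Reproducibility

All randomness flows from explicit seeds; `run_phenomics()` derives
independent per-stage streams from one global seed and records content
digests of every stage output in its manifest, so a re-run with the same
config and seed is digest-identical and any stage can be re-run in
isolation from stored intermediates. Cohorts round-trip through plain
CSV/GeoJSON (`write_cohort()`/`read_cohort()`).
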