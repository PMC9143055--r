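---
title: "Methods: from pixel spectra to per-core diagnoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pixel spectra to per-core diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msitma)
```

`msitma` turns per-pixel DESI-MSI spectra of tissue-microarray (TMA) slides
into per-core tumour/normal calls. This vignette is the package's own
account of the method: the processing model and its assumptions, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## 1. Processing model

One MSI run (one slide) is a dense matrix of M pixels × N mass-axis
entries, with integer grid coordinates per pixel. The pipeline is:

1. **Peak detection** (profile data): local maxima with intensity at least
   `snr_min` times a robust noise scale; centroids by intensity-weighted
   mean over the contiguous above-half-maximum bins. Centroided input
   skips detection and is SNR-filtered directly.
2. **Common mass axis**: peak centroids pooled across runs and merged by a
   greedy single-linkage walk with a relative tolerance `ppm_tol`; each
   cluster contributes its intensity-weighted mean m/z.
3. **Recalibration**: each run's global mass shift is the median relative
   deviation of its peaks from their nearest axis entries (within
   tolerance); the shift is divided out. A single global shift assumes the
   dominant run-to-run error is a calibration offset, not a
   mass-dependent drift.
4. **Rasterisation**: run intensities are reassigned to the nearest
   common-axis entry within tolerance; unmatched features are dropped,
   collisions summed.
5. **ROI segmentation**: k-means over pixels; clusters far dimmer than the
   brightest cluster are background, the rest form the tissue mask.
6. **Spatial feature filter**: a feature survives if it is non-zero in at
   least `spatial_filter_min_fraction` of tissue pixels *and* its mean
   on-tissue intensity exceeds its mean off-tissue intensity. This is a
   deliberately simple two-rule reading of "keep ion images that look like
   tissue"; it replaces heavier spatial statistics and is fully testable.
7. **Reference scaling**: every slide carries a reference kidney core;
   each run is multiplied by a scalar proportional to the inverse median
   TIC over its reference pixels, scalars normalised to mean 1. After
   scaling, reference medians are equal across runs (at their harmonic
   mean) and within-run relative intensities are untouched.
8. **Core averaging**: pixels belong to the nearest annotated core centre
   within its radius, intersected with the tissue mask; each core is
   summarised by the arithmetic mean spectrum of its pixels.
9. **Median fold change (MFC) normalisation**: each core spectrum is
   divided by the median ratio of its features to the dataset-wide
   feature-median spectrum (over features positive in both). This corrects
   dilution-like global differences; afterwards every spectrum's median
   fold change against that reference is exactly 1.

### Classification

With labels tumour = 1 / normal = 0, the classifier is a weighted
L2-regularised logistic regression. Class weights are inverse-frequency,
$w_c = n / (2 n_c)$, so both classes contribute equally to the likelihood
no matter the imbalance; the objective is maximised by Newton iterations
with step halving on internally standardised features (convex, hence
deterministic). Generalisation is estimated by stratified K-fold
cross-validation (default K = 10) in which each test fold's class ratio is
within one core of the global ratio and each test fold spans at least two
slides whenever the dataset has two; class weights and standardisation are
recomputed inside every training fold. Metrics: TPR, TNR, FPR, balanced
accuracy, F1, and the ROC AUC computed by trapezoid over the tie-grouped
threshold sweep, which equals the Mann–Whitney concordance exactly.

### Feature selection

Two independent screens are intersected:

* **Multivariate arm**: per feature, a likelihood-ratio test of the
  weighted single-feature logistic model against the weighted
  intercept-only model, $2(\ell_1 - \ell_0) \sim \chi^2_1$, kept at raw
  $p < \alpha$.
* **Univariate arm**: a Kruskal–Wallis test per feature (tie-corrected;
  for two groups a monotone transform of Mann–Whitney U), with
  Benjamini–Hochberg adjustment, kept at $q < \alpha$.

The reduced model on the intersection is cross-validated on the *same*
fold assignment as the full model, so the two metric sets are directly
comparable. Absolute standardised coefficients of the full fit are
reported as an importance ranking but play no part in the selection rule.

The single-feature form of the LRT is a deliberate choice: with features
approaching or exceeding the core count, a full-multivariable
drop-one-feature test is dominated by the ridge penalty and ill-defined
without it, whereas univariable screening is well-posed at any dimension.
The LRT arm carries no multiplicity correction (only the univariate arm
does); the intersection with the FDR-controlled arm is what limits false
selections, and the null simulations in the test suite confirm the
combined rule rarely selects anything on pure noise.

## 2. Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `ppm_tol` | 10 | ppm | mass-matching window for axis building, recalibration, rasterisation and axis comparison; 10 ppm at m/z 500 is 0.005 Th |
| `snr_min` | 3 | – | peak acceptance threshold; instrument-dependent, deliberately exposed |
| `kmeans_k` | 4 | clusters | resolves tumour / stroma / tissue background / slide background; k = 2 suffices for a plain tissue mask (the pipeline's ROI step uses 2) |
| `background_tic_fraction` | 0.2 | – | clusters dimmer than this fraction of the brightest cluster's mean TIC are background |
| `spatial_filter_min_fraction` | 0.01 | – | minimum tissue occupancy of a genuine feature |
| `lambda` | 0.01 | – | L2 strength; per-core averaged spectra are often linearly separable, so some ridge keeps the optimum finite and the CV stable |
| `K` | 10 | folds | cross-validation folds |
| `alpha` | 0.05 | – | significance threshold of both selection arms |
| `pixel_size_um` | 85 | µm | DESI raster pitch; metadata only, no algorithm depends on it |

## 3. The synthetic generator

`simulate_dataset()` emulates the structure the pipeline must survive:

* several slides, each an MSI run with its **own multiplicative batch
  factor** (log-normal, sd `slide_batch_sd`) and its **own global
  mass-axis shift** (normal, sd `ppm_jitter_sd`);
* cores on a grid, each a disc of pixels; per-pixel intensities are a
  class template times the batch factor times log-normal noise
  (`noise_sd`, natural-log scale) — multiplicative noise matches the
  fold-change normalisation and guarantees positivity;
* tumour cores scale `n_markers` features by `2^marker_log2_effect`
  *before* batch factors and noise, so the marker effect is exact in the
  noise-free limit;
* one **reference kidney core per slide** with a fixed profile shared
  across slides (what makes reference scaling identifiable);
* **background pixels** drawn from the noise floor only, giving
  segmentation a real contrast to find;
* imbalance defaulting to 8:1 tumour:normal, the regime in which
  cost-sensitive weighting actually matters.

The defaults of the bundled demonstration — 3 slides × 43 annotated cores
(129 cores), 8:1 imbalance, 60 features, 5 markers at a 2-fold effect,
pixel noise sd 0.3, batch sd 0.3, jitter sd 2 ppm — are the package's
standing study conditions; the magnitudes of the batch and noise terms are
free parameters of the simulation (no public dataset pins them down) and
are documented as such.

What the generator does **not** emulate: chromatographic or within-run
drift, isotope patterns and adducts, peak-shape variation, correlated
(structured) biological heterogeneity between patients, stromal gradients
within a core, or partial/missing cores. Consequently, a clean metric on
synthetic data shows the *pipeline machinery* is correct — alignment,
scaling, weighting, fold construction, selection — not that clinical
tissue is this easy; real cohorts have weaker, correlated effects, and
performance there must be established on real data.

`simulate_ffpe_from_ff()` emulates the peak loss of formalin fixation: a
uniform subset of `round(retention × n)` peaks survives, each m/z is
jittered, and surviving lipid-range (600–900 m/z) intensities are
multiplied by `lipid_attenuation^(1 - retention)` — an attenuation that
grows with the simulated processing loss and vanishes at full retention,
so the identity case is exact.

## 4. Numerical choices and degenerate inputs

* **Noise scale**: `1.4826 × median(median(x) − x_below-median)` — the
  MAD consistency constant applied to the below-median half, so peaks
  (always above the median) cannot inflate the estimate. All-constant
  spectra return 0.
* **Peak merging**: apexes whose half-maximum supports overlap are one
  peak (tallest apex wins); without this, noise riding on a broad peak
  splits it.
* **Axis clustering tie-break**: the greedy walk closes a cluster when the
  next centroid is beyond tolerance of the running weighted mean *or*
  would stretch the cluster span beyond tolerance; pooling and sorting
  first makes the result independent of run order.
* **Recalibration with < 3 matches** warns and applies a zero offset.
* **Reference scaling** uses the median TIC of the reference pixels
  (robust to a few hot pixels); an empty reference mask on any slide is an
  error naming that slide. Scalars are normalised to mean 1, which keeps
  the dataset's overall intensity scale and reproduces the closed-form
  two-run case (factors 4/3 and 2/3 for runs differing by 2×).
* **MFC normalisation** leaves a spectrum unchanged (factor 1, with a
  warning) when it shares no positive feature with the reference.
  Renormalising against the *stored* reference is the identity; a second
  pass that re-derives the reference from already-normalised data is not
  exactly idempotent, which is why the returned reference is part of the
  result.
* **Segmentation representation**: k-means runs on `log1p` intensities.
  TIC-normalising first — superficially attractive — removes precisely the
  intensity contrast that separates tissue from slide background and makes
  the tissue mask unrecoverable under the generator's noise model; `log1p`
  keeps both intensity and composition information and stabilises
  variance. Background flagging is relative to the brightest cluster
  rather than the median pixel, so it survives slides where background
  pixels are the majority.
* **Pixel-to-core ties** (a pixel equidistant from two centres) go to the
  lexicographically lower core id; overlapping discs resolve by nearest
  centre with a warning.
* **Registration** optimises the six affine parameters in centre-referenced
  coordinates from the identity, on a coarse-to-fine Gaussian smoothing
  schedule (σ = 6, 3, 1.5 px). Steps follow the damped Gauss–Newton
  direction of the squared loss with backtracking halving — a plain
  fixed-step gradient descent mixes badly-scaled linear and translation
  parameters and stalls on rotation + scale fixtures. Divergence (loss
  above its initial value for 50 consecutive accepted iterations) returns
  the identity with a warning. The returned `A` is the resampling map:
  fixed-frame pixel p reads the moving image at `A [p; 1]`.
* **Axis matching** accepts candidate pairs in order of increasing ppm
  distance, each peak used once; the shared fraction is relative to the
  smaller axis. At realistic peak spacings (inter-peak distances far above
  the tolerance) this greedy rule coincides with the exhaustive
  minimum-distance assignment, which the test suite verifies by brute
  force on small axes; in pathologically crowded windows the greedy and
  exhaustive optima can differ.
* **Mann–Whitney U convention** in `pca_separation()`: the reported `u` is
  `min(U, n₁n₂ − U)` ("min-rank"), so complete separation reports 0
  regardless of direction; the raw statistic is also returned.
* **Fold repair**: stratified folds are repaired toward the ≥ 2-slides
  constraint by same-class swaps, lowest core index first — one concrete
  reading of "minimise slide-to-slide bias". Patient ids are recorded but
  folds are not patient-grouped, and spectra enter the model untransformed
  (no log), both deliberately config-visible simplifications.

## 5. Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make every stochastic
check stable yet quick: the bundled demo (3 slides, 129 cores, 60
features) for end-to-end classification across 10 replicate simulations;
150 cores × 200 features × 20 replicates for marker-recovery; 500–2000
replicates for null calibration of the LRT and Kruskal–Wallis p-values;
n = 2000 for logistic parameter recovery; 64 × 64 masks for registration.
The acceptance script reruns the demo ten times and reports the median
out-of-fold F1.

## 6. Known limitations

* The imzML reader covers continuous and processed files with external
  binary arrays (the common imaging case) but no vendor raw formats and no
  compressed binary arrays.
* Recalibration is a single global shift per run; mass-dependent drift is
  out of scope.
* The spatial filter is a two-rule heuristic, not a full spatial-statistics
  battery; it is meant to discard speckle and off-tissue chemical noise,
  not to rank image quality.
* Registration is affine only and operates on binary masks, not raw
  intensities; non-rigid deformation is out of scope.
* The generator's independence assumptions (pixels, features, patients)
  make synthetic tasks easier than clinical ones; see §3.
* No metabolite annotation: selected features are m/z values, and naming
  them requires external resources by design.
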