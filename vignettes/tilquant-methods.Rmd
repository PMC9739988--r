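---
title: "Methods: quantifying tumor-infiltrating lymphocytes from H&E tiles"
author: "TILquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying tumor-infiltrating lymphocytes from H&E tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TILquant)
```

# Overview

TILquant scores tumor-infiltrating lymphocytes (TILs) on
hematoxylin-and-eosin (H&E) histology and relates the score to overall
survival. The pipeline runs in six stages: stain estimation and
deconvolution, watershed nucleus detection, per-cell feature measurement
with neighborhood smoothing, neural-network cell classification, TILs
variable computation, and survival analysis (optimal dichotomization,
Kaplan-Meier, Cox regression). A synthetic-data module generates H&E-like
tiles with exact ground truth and proportional-hazards cohorts, so every
stage is validated quantitatively without clinical images.

# Stain model and deconvolution

Transmitted light follows Beer-Lambert absorption: a pixel with stain
concentrations $c = (c_H, c_E, c_R)$ produces intensity
$I_k = I_{0,k}\,10^{-(Mc)_k}$ in channel $k$, where the columns of $M$ are
unit optical-density (OD) direction vectors for hematoxylin, eosin and a
residual. `rgbToOD()` computes $\mathrm{OD} = -\log_{10}(\max(I,1)/I_0)$;
the clamp at intensity 1 keeps saturated pixels at a large finite OD
($\log_{10} 255 \approx 2.41$ for 8-bit input) and is monotone. When no
calibration white is available the per-channel 99.9th-percentile intensity
serves as a robust background estimate.

`estimateStainVectors()` implements automatic plane-fitting estimation:
pixels with summed OD above `odMin` (default 0.15) are projected onto the
plane of the two leading singular vectors of the OD cloud, and the
directions at the 1%/99% quantiles of the in-plane angle become the two
stains. Hematoxylin is the vector with the larger blue-channel component;
the residual is their normalized cross product. Both the foreground
threshold and the percentile are exposed because they are the only tuning
points of the estimator. Estimation is per image; whether a slide-level or
region-level estimate is preferable depends on staining heterogeneity, and
per-image estimation is the conservative choice for mixed-provenance
collections.

Deconvolution solves the $3\times 3$ system $\mathrm{OD} = Mc$ per pixel
and clips negative concentrations to zero. Note the residual direction
generally has negative OD components (it is a cross product, not a
physical dye), so only the hematoxylin/eosin subspace composes to a valid
absorbance image; round-trip identities are exact on that subspace.

# Cell detection

`detectCells()` operates on the hematoxylin OD channel at a working
resolution of 0.5 um/px (resampling uses exact area-overlap averaging,
which is anti-aliased and mean-preserving). The stages, all in physical
units:

1. optional median filter (radius 0 um by default, i.e. skipped);
2. Gaussian smoothing, sigma 1.5 um;
3. background estimation by grayscale morphological opening with an
   8 um radius element, subtracted from the smoothed image;
4. foreground threshold at 0.1 OD on the background-corrected image;
5. hole filling, then a distance-transform watershed to split touching
   nuclei (seed maxima separated by at least 2 um, raster-order
   tie-breaking, so detection is deterministic);
6. nucleus area filter: 10-400 um^2; nuclei whose local background
   estimate exceeds 2 OD are discarded as artifacts (pen marks, folds);
7. cell territory: each nucleus is expanded by up to 5 um, constrained by
   a distance-limited Voronoi partition so neighboring cells never
   overlap.

The opening uses an octagonal structuring element (maximum radial error
about 8% of the radius), assembled from axial and diagonal line elements;
this keeps the filter exact in spirit while running in a handful of
vectorized passes. Thresholding the *corrected* image makes detection
robust to slowly varying haze at the cost of slightly eroding very large
pale structures — which the 400 um^2 ceiling would reject anyway.
Detections are confined to the region of interest by rasterizing the ROI
polygon into the foreground mask. Coordinates are micrometers, origin at
the tile's top-left corner, x rightward, y downward, polygon vertices at
pixel centers.

# Features and neighborhood smoothing

For each cell, intensity statistics (mean, sd, min, max) of hematoxylin
and eosin OD are computed over nucleus, whole cell and cytoplasm (cell
minus nucleus; empty rings fall back to cell statistics and are flagged),
plus shape descriptors: area, perimeter, circularity $4\pi A/P^2$,
eccentricity from polygon second moments, and max/min caliper widths. For
rasterized contours the perimeter uses the Vossepoel-Smeulders chain-code
correction (0.948 per axial, 1.340 per diagonal step); the naive polygon
perimeter of a digitized disk is biased high and would push circularity of
a perfect circle down to ~0.83.

`smoothFeatures()` adds, for every base feature and each radius $r$ (25 um
and 50 um by default), the Gaussian-weighted neighborhood average with
$\sigma = r/2$, truncated at $2r$ and including the cell itself. The
kernel is a design choice — any smooth, local, convex weighting would do —
and both intensity and shape features are smoothed, giving each cell
context that separates, say, a lymphocyte inside a tumor nest from one in
a stromal band. Radius 0 is the identity.

# Cell classification

The classifier is a small multilayer perceptron over
{TUMOR, IMMUNE, STROMA, IGNORE}: tanh hidden layers, softmax output,
full-batch gradient descent (step 0.01, momentum 0.9, tolerance 1e-5, at
most 1000 iterations), seeded initialization so training is
bit-reproducible. Momentum is used because plain gradient descent at step
0.01 does not reliably converge within 1000 iterations. The description
"eight hidden layers" in legacy ANN tools is ambiguous (layer count vs
unit count); the default is one hidden layer of 8 units, and
`ClassifierConfig(hidden = rep(8L, 8L))` gives the deep preset. Features
are z-standardized with statistics from the stratified 80% training split
only — the held-out 20% never influences standardization or gradients and
supplies the reported confusion matrix. Zero-variance columns are dropped
with a warning; classes with fewer than 10 examples abort training by
name. Iterative annotate-and-retrain workflows are supported simply by
retraining on the augmented label table.

# TILs variables

With lymphocyte count $T$, tumor count $U$, stromal count $S$ and analyzed
tumor-region area $A$ (mm^2):

$$\mathrm{eTILs\%} = \frac{100\,T}{T+U},\quad
\mathrm{esTILs\%} = \frac{100\,T}{T+S},\quad
\mathrm{etTILs\%} = \frac{100\,T}{T+U+S},\quad
\mathrm{eaTILs} = \frac{T}{A}.$$

IGNORE-class detections (false detections, debris, background) are
excluded from the etTILs% denominator by default because they are not
cells; `includeIgnoreInTotal = TRUE` switches to the all-detections
convention. Zero denominators yield 0 with a QC flag rather than NaN.
Multi-region aggregation pools counts and areas and recomputes the
ratios — averaging percentages across regions of different size would be
biased. The analyzed area is the annotated tumor ROI actually processed,
not the whole slide.

# Optimal cut-point

`findOptimalCutpoint()` scans every midpoint between consecutive sorted
unique marker values, skips candidates leaving either group below 10% of
the cohort, computes the two-group log-rank chi-square at each, and
returns the maximizer (smallest threshold on ties; subjects at the
threshold are "high"). Because the maximum of many correlated tests is
selected, the raw p-value is anti-conservative; the Miller-Siegmund
approximation corrects it over the scanned quantile range
$(\varepsilon_1, \varepsilon_2)$:

$$p \approx \varphi(b)\,(b - b^{-1})\,
\log\frac{\varepsilon_2(1-\varepsilon_1)}{\varepsilon_1(1-\varepsilon_2)}
 + 4\,\varphi(b)/b, \qquad b = \sqrt{\chi^2_{max}},$$

floored at the raw p-value and capped at 1. A seeded permutation null is
available when the approximation's assumptions are doubtful. Only
two-group dichotomization is provided; three-group partitions are out of
scope. A caveat the simulations make visible: when the marker density near
the true change-point is low (here, the valley between the two mixture
modes), the argmax has appreciable sampling spread even when the log-rank
statistic itself is computed exactly — the median recovered threshold is
on target while individual replicates can land a few points away.

# Survival analysis

`kaplanMeier()` is the product-limit estimator with Greenwood standard
errors and plain 95% bands clipped to [0, 1]. `coxFit()` maximizes the Cox
partial likelihood by Newton-Raphson with step halving, Efron tie handling
by default (Breslow optional), convergence at gradient norm 1e-8, at most
100 iterations; Wald confidence intervals and p-values come from the
inverse information. Continuous event times take a fully vectorized
risk-set path; tied blocks fall back to a per-event-time loop with Efron's
fractional downweighting. Both the log-rank statistic and the Cox
coefficients are verified in the test suite against the survival package
(1e-8 / 1e-6) — the package implements them itself precisely so that this
cross-check is a genuine dual route.

`runTable2Models()` composes the standard prognostic table: univariate
fits for age (>= 70), sex, pT (3-4 vs 1-2), pN (2-3 vs 0-1), pM, pTNM
stage (III-IV vs II), lymphovascular invasion and dichotomized TILs
(reference: the low group), and a multivariate model over
{age, pT, pN, stage, LVI, TILs}. The multivariate set knowingly carries
pT/stage collinearity; a condition-number message is emitted rather than
silently dropping a term, because the composition mirrors common clinical
reporting practice. Missing covariates are handled complete-case per
model with a logged count; no imputation.

# Synthetic data

`simulateTile()` renders each nucleus as a rotated ellipse with radial
hematoxylin OD profile $\mathrm{peak}\cdot(1 - (r/R)^2)^{1.5}$ — zero at
the membrane with a soft shoulder, calibrated so that the detector's
thresholded area is an unbiased estimate of the true ellipse area — plus a
class-dependent eosin cytoplasm halo and a faint uniform eosin tissue
background, composed through the stain matrix and corrupted with additive
Gaussian intensity noise (sd 2 gray levels by default). Class phenotypes
are: immune nuclei 20-40 um^2, round, peak OD 0.8-1.1, scant cytoplasm;
tumor nuclei 60-150 um^2, pleomorphic, OD 0.45-0.7, moderate eosin;
stromal nuclei 30-80 um^2, elongated (eccentricity 0.80-0.95), OD
0.25-0.45, strong eosin. Placement is seeded dart-throwing with a 16 um
minimum separation. What the generator does *not* emulate: overlapping
and touching nuclei beyond the separation limit, texture within nuclei,
staining gradients across a slide, folds and pen marks — so passing
segmentation tests demonstrate correctness of the implementation under
clean conditions, not expected accuracy on clinical material.

`simulateCohort()` draws a TILs score from a two-component normal mixture
(defaults 0.5 N(8, 2^2) + 0.5 N(20, 4^2), truncated to [0, 100]),
dichotomizes it at the true change-point 13.2, and generates exponential
event times with hazard `baselineRate * hr^I(high) * exp(x'beta)` for
optional binary clinical confounders (age >= 70, stage III-IV, LVI).
The exponential baseline (0.04/month, a median survival of about 17
months, typical of muscle-invasive bladder cancer) permits closed-form
sanity checks. Censoring is an independent uniform time whose upper bound
is calibrated against the realized event times so the expected censored
fraction matches the request; clinical covariate marginals resemble a
bladder-cancer cohort (76% male, pT3-dominant staging). Hazard ratios
below 1 for the high-TILs group encode the better prognosis of
immune-infiltrated tumors.

`simulateFixture()` ties both generators together: each synthetic
patient's tile receives tumor/immune counts reproducing that patient's
eTILs% to within rounding, enabling pixel-to-hazard-ratio tests against
exact truth.

# Numerical choices and problem sizes

Degenerate inputs are first-class: fewer than 100 foreground pixels or a
rank-1 OD cloud abort stain estimation with named errors; constant
markers abort the cut-point scan; zero-variance covariates abort Cox fits
by name; empty ROIs and non-OD rasters are rejected at the detector
boundary. All generators are pure functions of their spec and seed and
restore the caller's RNG state.

The validation suites run at deliberately desk-sized scales: 100 cohorts
of n = 380 for cut-point recovery, one n = 2000 cohort plus 500 replicates
of n = 247 for hazard-ratio recovery and CI calibration, 200 confounded
cohorts of n = 500 for the multivariate model, a 400 um tile with 200
cells for segmentation fidelity, and a 12-patient fixture for the
end-to-end check. These sizes give Monte-Carlo standard errors comfortably
below the tolerances being checked while keeping the whole suite quick on
a single CPU.

# Known limitations

- Stromal vs intratumoral TILs are not separated; the score is a single
  regional aggregate.
- The watershed cannot resolve heavily overlapping nuclei; the synthetic
  generator's separation constraint sidesteps rather than solves this.
- The Miller-Siegmund correction assumes a continuous marker; heavily
  tied markers should use the permutation option.
- Maximally selected cut-points are noisy estimators when few subjects
  lie near the change-point; report the scan, not just the maximizer.
- The MLP classifier is only as good as its features; no texture or
  deep-learning embeddings are provided.
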