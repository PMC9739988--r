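# TILquant

Quantifying tumor-infiltrating lymphocytes (TILs) on H&E histology and
relating the score to patient survival.

Visual TILs assessment carries strong prognostic information in
muscle-invasive bladder cancer and other solid tumors, but inter-observer
variability limits its clinical use. TILquant implements a reproducible,
machine-readable alternative: cells are detected and classified on
hematoxylin-and-eosin images, TILs are expressed as simple count ratios,
and the resulting score is dichotomized and carried into standard survival
models. The package is aimed at computational-pathology and biostatistics
users who want every stage — image processing, classification, scoring and
inference — as plain, testable R functions.

## What it computes

**Stain deconvolution.** With per-stain unit optical-density vectors as
columns of `M`, transmitted light obeys Beer–Lambert,
`I = I0 * 10^-(M c)`; the package estimates `M` per image (plane fitting
with a 1%/99% extreme-angle rule on foreground OD pixels) and unmixes each
pixel by solving `OD = M c`.

**Watershed cell detection** on the hematoxylin OD channel at 0.5 µm/px,
with physical-unit parameters (background radius 8 µm, Gaussian sigma
1.5 µm, OD threshold 0.1, nucleus area 10–400 µm², maximum background
intensity 2, 5 µm non-overlapping cell expansion).

**Cell classification** into tumor / immune (lymphocyte) / stroma /
ignore with a seeded multilayer perceptron over per-cell intensity and
shape features plus their 25 µm / 50 µm Gaussian-smoothed neighborhood
variants.

**Four TILs variables** from classified counts `T` (TILs), `U` (tumor),
`S` (stroma) and analyzed area `A` (mm²):

    eTILs%  = 100 T / (T + U)        esTILs% = 100 T / (T + S)
    etTILs% = 100 T / (T + U + S)    eaTILs  = T / A   (per mm²)

**Survival analysis.** Maximally selected log-rank cut-point search with
Miller–Siegmund multiplicity correction, Kaplan–Meier estimation with
Greenwood intervals, and Cox proportional-hazards fits (Efron ties,
Newton–Raphson) for univariate and multivariate prognostic tables.

**Synthetic data.** Seeded generators for H&E-like tiles (Beer–Lambert
rendering of tumor/immune/stroma nuclei with exact ground truth) and for
proportional-hazards cohorts whose hazard depends on the dichotomized
TILs score — the basis of the package's validation suites.

## Worked example

From pixels to a hazard ratio on synthetic data:

```r
library(TILquant)

## a 250 µm tile with 40 tumor, 15 immune, 20 stromal cells
tile <- simulateTile(SceneSpec(tileSize = 250,
                               counts = c(TUMOR = 40L, IMMUNE = 15L,
                                          STROMA = 20L), seed = 7L))
od  <- rgbToOD(tile$image, background = 255, pixelSize = 0.5)
ch  <- deconvolveStains(od, estimateStainVectors(od))
det <- detectCells(ch[, , 1])
nrow(det)
#> [1] 75

## label detections from ground truth and score the region
roi <- cbind(c(0, 250, 250, 0), c(0, 0, 250, 250))
ca  <- countAndArea(det, roi)   # after labelling det$class from truth
computeTILsReport(c(IMMUNE = 15, TUMOR = 40, STROMA = 20), ca$area_mm2)
#> TILsReport: 15 TILs, 40 tumor, 20 stroma, 0 ignore in 0.062 mm^2
#>   eTILs%=27.27  esTILs%=42.86  etTILs%=20.00  eaTILs=240.0/mm^2
```

All 75 rendered nuclei are recovered, and the report reads: 27.3% of
epithelial-compartment cells are lymphocytes (eTILs%), 20% of all cells
are lymphocytes (etTILs%), at a density of 240 lymphocytes per mm² of
analyzed tumor (eaTILs).

```r
## a 380-patient cohort whose true prognostic change-point is eTILs = 13.2%
coh <- simulateCohort(CohortSpec(n = 380, seed = 1L))
cp  <- findOptimalCutpoint(coh$eTILs_pct, coh$time_months, coh$event)
cp
#> CutpointResult: threshold 14.44 (chi-square 69.192)
#>   p (raw) = 8.93e-17, p (corrected) = 1.38e-14; groups low/high = 187/193
#>   scan over 305 admissible candidates

coxFit(coh, "eTILs_pct",
       dichotomize = list(variable = "eTILs_pct", threshold = cp@threshold))
#> CoxResult (efron ties): n = 380, events = 237, loglik = -1203.718
#>            term          HR (95% CI)        p
#>  eTILs_pct_high 0.336 (0.257, 0.439) 1.61e-15
```

The scan recovers a threshold near the true 13.2% change-point, and the
high-TILs group shows the expected protective hazard ratio (truth 1/3 in
this generator).

`runPipeline()` chains all stages over a set of tiles and writes GeoJSON
detections, feature/report CSVs and a reproducibility manifest;
`inst/scripts/tilquant.R` exposes the same functions as shell
subcommands (`simulate-tile`, `segment`, `cutpoint`, `survival`, `run`).

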