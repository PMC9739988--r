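#' @import methods
NULL

# ---------------------------------------------------------------------------
# Stain model
# ---------------------------------------------------------------------------

#' H&E stain model
#'
#' Unit optical-density direction vectors for hematoxylin, eosin and a
#' residual stain, together with the per-channel background (white) intensity
#' of the slide. Columns of the implied 3x3 stain matrix are, in order,
#' hematoxylin, eosin, residual.
#'
#' @slot hematoxylin numeric(3), unit-norm OD direction of hematoxylin.
#' @slot eosin numeric(3), unit-norm OD direction of eosin.
#' @slot residual numeric(3), unit-norm OD direction orthogonal to both.
#' @slot background numeric(3), per-RGB-channel white level (intensity units).
#'
#' @export
setClass("StainModel",
  representation(
    hematoxylin = "numeric",
    eosin       = "numeric",
    residual    = "numeric",
    background  = "numeric"
  )
)

setValidity("StainModel", function(object) {
  msg <- character()
  for (nm in c("hematoxylin", "eosin", "residual")) {
    v <- slot(object, nm)
    if (length(v) != 3L || !all(is.finite(v)))
      msg <- c(msg, sprintf("'%s' must be a finite numeric vector of length 3", nm))
    else if (abs(sqrt(sum(v^2)) - 1) > 1e-9)
      msg <- c(msg, sprintf("'%s' must have Euclidean norm 1", nm))
  }
  if (!length(msg)) {
    h <- object@hematoxylin; e <- object@eosin; r <- object@residual
    ang <- acos(min(1, abs(sum(h * e)))) * 180 / pi
    if (ang <= 1)
      msg <- c(msg, "hematoxylin and eosin vectors are collinear (angle <= 1 degree)")
    if (abs(sum(r * h)) > 1e-6 || abs(sum(r * e)) > 1e-6)
      msg <- c(msg, "residual vector must be orthogonal to hematoxylin and eosin")
  }
  if (length(object@background) != 3L || any(!is.finite(object@background)) ||
      any(object@background <= 0))
    msg <- c(msg, "'background' must be 3 positive finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a stain model
#'
#' @param hematoxylin,eosin numeric(3) OD direction vectors (normalized
#'   internally).
#' @param residual optional numeric(3); defaults to the normalized cross
#'   product of the hematoxylin and eosin vectors.
#' @param background numeric(3) per-channel white level; default 255.
#' @return A [StainModel-class] object.
#' @examples
#' StainModel(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
#' @export
StainModel <- function(hematoxylin, eosin, residual = NULL,
                       background = c(255, 255, 255)) {
  nrm <- function(v) v / sqrt(sum(v^2))
  h <- nrm(as.numeric(hematoxylin))
  e <- nrm(as.numeric(eosin))
  if (is.null(residual)) {
    r <- c(h[2] * e[3] - h[3] * e[2],
           h[3] * e[1] - h[1] * e[3],
           h[1] * e[2] - h[2] * e[1])
    r <- nrm(r)
  } else r <- nrm(as.numeric(residual))
  new("StainModel", hematoxylin = h, eosin = e, residual = r,
      background = rep_len(as.numeric(background), 3L))
}

#' @describeIn StainModel 3x3 stain matrix with columns H, E, residual.
#' @param model A `StainModel`.
#' @export
stainMatrix <- function(model) {
  stopifnot(is(model, "StainModel"))
  m <- cbind(model@hematoxylin, model@eosin, model@residual)
  dimnames(m) <- list(c("R", "G", "B"), c("hematoxylin", "eosin", "residual"))
  m
}

setMethod("show", "StainModel", function(object) {
  m <- stainMatrix(object)
  cat("StainModel (unit OD vectors)\n")
  print(round(m, 4))
  cat("background intensity:", paste(round(object@background, 2), collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# Optical-density image
# ---------------------------------------------------------------------------

#' Per-pixel optical-density image
#'
#' A 3-channel raster of decadic optical densities with a known physical
#' pixel size. The array is indexed `[x, y, channel]` with 0-based pixel
#' coordinates at pixel centers; micron coordinates are `index * pixelSize`.
#'
#' @slot values numeric array `[nx, ny, 3]`, all values >= 0 and finite.
#' @slot pixelSize physical size of one pixel in micrometers.
#' @export
setClass("ODImage",
  representation(values = "array", pixelSize = "numeric"))

setValidity("ODImage", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L || dim(v)[3] != 3L)
    return("'values' must be an [nx, ny, 3] array")
  if (any(!is.finite(v))) return("OD values must be finite")
  if (any(v < 0)) return("OD values must be >= 0")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("'pixelSize' must be a single positive number")
  TRUE
})

setMethod("show", "ODImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("ODImage %d x %d px (%.3g um/px), OD range [%.3f, %.3f]\n",
              d[1], d[2], object@pixelSize, min(object@values), max(object@values)))
})

#' @describeIn ODImage-class physical pixel size in micrometers.
#' @param x An `ODImage`.
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn ODImage-class the raw OD array `[nx, ny, 3]`.
#' @export
odValues <- function(x) x@values

# ---------------------------------------------------------------------------
# Detection parameters
# ---------------------------------------------------------------------------

#' Watershed cell-detection parameters
#'
#' Physical-unit parameters of the watershed nucleus detector. Defaults are
#' the standard H&E settings: detection on the hematoxylin OD channel at a
#' working resolution of 0.5 um/px, 8 um background radius, no median filter,
#' 1.5 um Gaussian sigma, nucleus area within 10-400 um^2, OD threshold 0.1,
#' maximum background intensity 2 OD, and 5 um cell expansion.
#'
#' @slot requestedPixelSize working resolution in um/px.
#' @slot backgroundRadius radius (um) of the grayscale opening used to
#'   estimate slowly varying background.
#' @slot medianRadius median-filter radius in um; 0 skips the filter.
#' @slot sigma Gaussian smoothing sigma in um.
#' @slot minCellArea,maxCellArea nucleus area filter bounds in um^2.
#' @slot odThreshold foreground threshold on background-subtracted OD.
#' @slot maxBackgroundIntensity nuclei whose local background OD exceeds this
#'   are discarded as artifacts.
#' @slot cellExpansion distance (um) the nucleus is expanded to approximate
#'   the cell boundary, limited so neighboring cells never overlap.
#' @export
setClass("DetectionParams",
  representation(
    requestedPixelSize     = "numeric",
    backgroundRadius       = "numeric",
    medianRadius           = "numeric",
    sigma                  = "numeric",
    minCellArea            = "numeric",
    maxCellArea            = "numeric",
    odThreshold            = "numeric",
    maxBackgroundIntensity = "numeric",
    cellExpansion          = "numeric"
  ),
  prototype(
    requestedPixelSize = 0.5, backgroundRadius = 8, medianRadius = 0,
    sigma = 1.5, minCellArea = 10, maxCellArea = 400, odThreshold = 0.1,
    maxBackgroundIntensity = 2, cellExpansion = 5
  )
)

setValidity("DetectionParams", function(object) {
  msg <- character()
  sc <- function(x) length(x) == 1L && is.finite(x)
  for (nm in slotNames(object))
    if (!sc(slot(object, nm))) msg <- c(msg, sprintf("'%s' must be a single finite number", nm))
  if (!length(msg)) {
    if (object@requestedPixelSize <= 0) msg <- c(msg, "requestedPixelSize must be > 0")
    if (object@backgroundRadius < 0 || object@medianRadius < 0 ||
        object@sigma < 0 || object@cellExpansion < 0)
      msg <- c(msg, "radii and sigma must be >= 0")
    if (object@minCellArea < 0) msg <- c(msg, "minCellArea must be >= 0")
    if (object@minCellArea >= object@maxCellArea)
      msg <- c(msg, "minCellArea must be smaller than maxCellArea")
    if (object@odThreshold <= 0) msg <- c(msg, "odThreshold must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DetectionParams-class constructor; any slot can be overridden
#'   by name.
#' @param ... named slot overrides, e.g. `sigma = 2`.
#' @export
DetectionParams <- function(...) new("DetectionParams", ...)

setMethod("show", "DetectionParams", function(object) {
  cat("DetectionParams:\n")
  for (nm in slotNames(object))
    cat(sprintf("  %-24s %g\n", nm, slot(object, nm)))
})

# ---------------------------------------------------------------------------
# TILs report
# ---------------------------------------------------------------------------

#' Per-region TILs quantification report
#'
#' Class counts, analyzed tumor area and the four electronic TILs variables:
#' eTILs% = 100 T/(T+tumor), esTILs% = 100 T/(T+stroma),
#' etTILs% = 100 T/(T+tumor+stroma), eaTILs = T/area (per mm^2), where T is
#' the lymphocyte count.
#'
#' @slot nTILs,nTumor,nStroma,nIgnore non-negative integer class counts.
#' @slot areaMm2 analyzed tumor area in mm^2 (> 0).
#' @slot eTILs,esTILs,etTILs percentages in [0, 100].
#' @slot eaTILs lymphocyte density per mm^2.
#' @slot qcFlags character vector of quality-control flags (e.g.
#'   "zero_denominator_eTILs").
#' @export
setClass("TILsReport",
  representation(
    nTILs = "integer", nTumor = "integer", nStroma = "integer",
    nIgnore = "integer", areaMm2 = "numeric",
    eTILs = "numeric", esTILs = "numeric", etTILs = "numeric",
    eaTILs = "numeric", qcFlags = "character"
  )
)

setValidity("TILsReport", function(object) {
  msg <- character()
  cnt <- c(object@nTILs, object@nTumor, object@nStroma, object@nIgnore)
  if (any(is.na(cnt)) || any(cnt < 0L)) msg <- c(msg, "counts must be non-negative integers")
  if (object@areaMm2 <= 0) msg <- c(msg, "areaMm2 must be > 0")
  pct <- c(object@eTILs, object@esTILs, object@etTILs)
  if (any(pct < 0 | pct > 100)) msg <- c(msg, "percentages must lie in [0, 100]")
  if (object@eaTILs < 0) msg <- c(msg, "eaTILs must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TILsReport", function(object) {
  cat(sprintf("TILsReport: %d TILs, %d tumor, %d stroma, %d ignore in %.3f mm^2\n",
              object@nTILs, object@nTumor, object@nStroma, object@nIgnore,
              object@areaMm2))
  cat(sprintf("  eTILs%%=%.2f  esTILs%%=%.2f  etTILs%%=%.2f  eaTILs=%.1f/mm^2\n",
              object@eTILs, object@esTILs, object@etTILs, object@eaTILs))
  if (length(object@qcFlags)) cat("  QC:", paste(object@qcFlags, collapse = ", "), "\n")
})

#' Extract the four TILs variables as a named numeric vector
#' @param report A [TILsReport-class].
#' @return Named numeric: `eTILs_pct`, `esTILs_pct`, `etTILs_pct`,
#'   `eaTILs_per_mm2`.
#' @export
tilsVariables <- function(report) {
  stopifnot(is(report, "TILsReport"))
  c(eTILs_pct = report@eTILs, esTILs_pct = report@esTILs,
    etTILs_pct = report@etTILs, eaTILs_per_mm2 = report@eaTILs)
}

# ---------------------------------------------------------------------------
# Cut-point result
# ---------------------------------------------------------------------------

#' Maximally selected log-rank cut-point result
#'
#' @slot threshold selected dichotomization threshold (subjects with value >=
#'   threshold form the "high" group).
#' @slot chiSquare log-rank chi-square at the threshold (maximum of the scan).
#' @slot pRaw uncorrected chi-square(1 df) p-value at the maximum.
#' @slot pCorrected multiplicity-corrected p-value (Miller-Siegmund or
#'   permutation).
#' @slot nLow,nHigh group sizes at the selected threshold.
#' @slot scan data.frame of all admissible candidates and their chi-squares.
#' @export
setClass("CutpointResult",
  representation(
    threshold = "numeric", chiSquare = "numeric",
    pRaw = "numeric", pCorrected = "numeric",
    nLow = "integer", nHigh = "integer", scan = "data.frame"
  )
)

setValidity("CutpointResult", function(object) {
  msg <- character()
  if (object@nLow + object@nHigh <= 0L) msg <- c(msg, "empty cohort")
  if (nrow(object@scan) &&
      abs(object@chiSquare - max(object@scan$chi_square)) > 1e-8)
    msg <- c(msg, "chiSquare must equal the maximum of the scan")
  if (object@pCorrected < object@pRaw - 1e-12)
    msg <- c(msg, "pCorrected must be >= pRaw")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CutpointResult", function(object) {
  cat(sprintf("CutpointResult: threshold %.4g (chi-square %.3f)\n",
              object@threshold, object@chiSquare))
  cat(sprintf("  p (raw) = %.3g, p (corrected) = %.3g; groups low/high = %d/%d\n",
              object@pRaw, object@pCorrected, object@nLow, object@nHigh))
  cat(sprintf("  scan over %d admissible candidates\n", nrow(object@scan)))
})

# ---------------------------------------------------------------------------
# Cox model result
# ---------------------------------------------------------------------------

#' Cox proportional-hazards fit summary
#'
#' @slot table data.frame with one row per covariate (level): `term`, `coef`,
#'   `se`, `hr`, `lower`, `upper` (Wald 95% CI), `z`, `p`.
#' @slot loglik numeric(2): null and fitted partial log-likelihood.
#' @slot n number of subjects used; @slot nEvents number of events.
#' @slot ties tie-handling method ("efron" or "breslow").
#' @export
setClass("CoxResult",
  representation(table = "data.frame", loglik = "numeric",
                 n = "integer", nEvents = "integer", ties = "character"))

setValidity("CoxResult", function(object) {
  tb <- object@table
  need <- c("term", "coef", "se", "hr", "lower", "upper", "z", "p")
  if (!all(need %in% names(tb))) return("missing columns in coefficient table")
  if (any(tb$hr <= 0)) return("hazard ratios must be positive")
  if (any(tb$lower > tb$hr + 1e-12 | tb$upper < tb$hr - 1e-12))
    return("confidence bounds must bracket the hazard ratio")
  TRUE
})

setMethod("show", "CoxResult", function(object) {
  cat(sprintf("CoxResult (%s ties): n = %d, events = %d, loglik = %.3f\n",
              object@ties, object@n, object@nEvents, object@loglik[2]))
  tb <- object@table
  tb$`HR (95% CI)` <- sprintf("%.3f (%.3f, %.3f)", tb$hr, tb$lower, tb$upper)
  print(tb[, c("term", "HR (95% CI)", "p")], row.names = FALSE, digits = 3)
})

#' @describeIn CoxResult-class coefficient table accessor.
#' @param object A `CoxResult`.
#' @export
coefTable <- function(object) {
  stopifnot(is(object, "CoxResult"))
  object@table
}

#' @describeIn CoxResult-class named vector of hazard ratios.
#' @export
hazardRatios <- function(object) {
  stopifnot(is(object, "CoxResult"))
  stats::setNames(object@table$hr, object@table$term)
}

# ---------------------------------------------------------------------------
# Synthetic scene / cohort specs
# ---------------------------------------------------------------------------

#' Synthetic H&E tile specification
#'
#' Describes a tile of tumor/immune/stroma nuclei rendered through a
#' Beer-Lambert stain model. Morphology defaults: immune nuclei are small
#' (20-40 um^2), round, with high hematoxylin peak OD; tumor nuclei large
#' (60-150 um^2), pleomorphic, moderate OD; stromal nuclei intermediate
#' (30-80 um^2), elongated, low OD.
#'
#' @slot tileSize tile side length in um (square tiles).
#' @slot pixelSize rendering resolution in um/px.
#' @slot counts named integer vector of cells per class
#'   (`TUMOR`, `IMMUNE`, `STROMA`).
#' @slot morphology named list per class with elements `area` (um^2 range),
#'   `eccentricity` (range) and `peakOD` (hematoxylin peak OD range).
#' @slot stainModel [StainModel-class] used for rendering.
#' @slot noiseSd additive Gaussian intensity noise standard deviation.
#' @slot minSeparation minimum center-to-center nucleus distance in um.
#' @slot seed RNG seed; generation is a pure function of spec + seed.
#' @export
setClass("SceneSpec",
  representation(
    tileSize = "numeric", pixelSize = "numeric", counts = "integer",
    morphology = "list", stainModel = "StainModel", noiseSd = "numeric",
    minSeparation = "numeric", seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@tileSize <= 0 || object@pixelSize <= 0)
    msg <- c(msg, "tileSize and pixelSize must be > 0")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be >= 0")
  if (!all(names(object@counts) %in% c("TUMOR", "IMMUNE", "STROMA")))
    msg <- c(msg, "counts must be named with TUMOR/IMMUNE/STROMA")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@minSeparation < 0) msg <- c(msg, "minSeparation must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SceneSpec-class constructor with field defaults.
#' @param tileSize,pixelSize,counts,morphology,stainModel,noiseSd,minSeparation,seed
#'   see slots.
#' @export
SceneSpec <- function(tileSize = 250, pixelSize = 0.5,
                      counts = c(TUMOR = 30L, IMMUNE = 15L, STROMA = 15L),
                      morphology = defaultMorphology(),
                      stainModel = defaultStainModel(),
                      noiseSd = 2, minSeparation = 16, seed = 1L) {
  cnt <- as.integer(counts)
  names(cnt) <- names(counts)
  new("SceneSpec", tileSize = tileSize, pixelSize = pixelSize, counts = cnt,
      morphology = morphology, stainModel = stainModel, noiseSd = noiseSd,
      minSeparation = minSeparation, seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %g um tile at %g um/px, noise sd %g, seed %d\n",
              object@tileSize, object@pixelSize, object@noiseSd, object@seed))
  print(object@counts)
})

#' Default per-class nucleus morphology ranges
#'
#' @return Named list with `area` (um^2), `eccentricity` and `peakOD` ranges
#'   per class.
#' @export
defaultMorphology <- function() {
  list(
    IMMUNE = list(area = c(20, 40),  eccentricity = c(0.0, 0.3),   peakOD = c(0.8, 1.1),
                  cytoOD = c(0.05, 0.15)),
    TUMOR  = list(area = c(60, 150), eccentricity = c(0.3, 0.7),   peakOD = c(0.45, 0.7),
                  cytoOD = c(0.20, 0.35)),
    STROMA = list(area = c(30, 80),  eccentricity = c(0.80, 0.95), peakOD = c(0.25, 0.45),
                  cytoOD = c(0.30, 0.50))
  )
}

#' Default H&E stain model (standard Ruifrok-Johnston H&E OD vectors)
#' @param background per-channel white level, default 255.
#' @export
defaultStainModel <- function(background = c(255, 255, 255)) {
  StainModel(hematoxylin = c(0.65, 0.70, 0.29),
             eosin = c(0.07, 0.99, 0.11),
             background = background)
}

#' Synthetic survival cohort specification
#'
#' Patients carry a continuous TILs score drawn from a two-component normal
#' mixture; the score dichotomized at `cutpoint` drives an exponential
#' proportional-hazards survival time (hazard ratio `hr` for the high group,
#' so `hr < 1` means longer survival above the cut-point), with independent
#' uniform censoring calibrated to the requested censoring fraction.
#' Optional binary clinical covariates (age >= 70, stage III-IV,
#' lymphovascular invasion) can carry their own log-hazard effects.
#'
#' @slot n number of patients (>= 20).
#' @slot mixtureMeans,mixtureSds,mixtureWeights two-component mixture of the
#'   TILs score (percent scale), truncated to [0, 100].
#' @slot cutpoint true prognostic change-point of the score.
#' @slot hr true hazard ratio, high vs low group (> 0).
#' @slot baselineRate exponential baseline hazard, events per month.
#' @slot censoringRate target fraction of censored patients, in [0, 1).
#' @slot covariateLogHR named numeric of log-hazard effects for the binary
#'   covariates `age70`, `stage34`, `lvi` (0 = no effect).
#' @slot seed RNG seed.
#' @export
setClass("CohortSpec",
  representation(
    n = "integer", mixtureMeans = "numeric", mixtureSds = "numeric",
    mixtureWeights = "numeric", cutpoint = "numeric", hr = "numeric",
    baselineRate = "numeric", censoringRate = "numeric",
    covariateLogHR = "numeric", seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@n < 20L) msg <- c(msg, "n must be >= 20")
  if (object@hr <= 0) msg <- c(msg, "hr must be > 0")
  if (object@baselineRate <= 0) msg <- c(msg, "baselineRate must be > 0")
  if (object@censoringRate < 0 || object@censoringRate >= 1)
    msg <- c(msg, "censoringRate must be in [0, 1)")
  if (length(object@mixtureMeans) != 2L || length(object@mixtureSds) != 2L ||
      length(object@mixtureWeights) != 2L)
    msg <- c(msg, "mixture must have exactly two components")
  else if (abs(sum(object@mixtureWeights) - 1) > 1e-9)
    msg <- c(msg, "mixture weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortSpec-class constructor with field defaults matching a
#'   bladder-cancer-like cohort: score mixture 0.5 N(8, 2^2) + 0.5 N(20, 4^2),
#'   change-point 13.2, high-group hazard ratio 1/3, baseline hazard
#'   0.04/month, 40% censoring.
#' @param n,mixtureMeans,mixtureSds,mixtureWeights,cutpoint,hr,baselineRate,censoringRate,covariateLogHR,seed
#'   see slots.
#' @export
CohortSpec <- function(n = 380, mixtureMeans = c(8, 20), mixtureSds = c(2, 4),
                       mixtureWeights = c(0.5, 0.5), cutpoint = 13.2,
                       hr = 1 / 3, baselineRate = 0.04, censoringRate = 0.4,
                       covariateLogHR = c(age70 = 0, stage34 = 0, lvi = 0),
                       seed = 1L) {
  new("CohortSpec", n = as.integer(n), mixtureMeans = mixtureMeans,
      mixtureSds = mixtureSds, mixtureWeights = mixtureWeights,
      cutpoint = cutpoint, hr = hr, baselineRate = baselineRate,
      censoringRate = censoringRate, covariateLogHR = covariateLogHR,
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: n=%d, cutpoint=%.3g, HR(high vs low)=%.3g, %.0f%% censoring, seed %d\n",
    object@n, object@cutpoint, object@hr, 100 * object@censoringRate,
    object@seed))
})

# ---------------------------------------------------------------------------
# Cell classifier
# ---------------------------------------------------------------------------

#' Multilayer-perceptron cell-classifier configuration
#'
#' @slot hidden integer vector of hidden-layer widths (non-empty). The
#'   default is a single layer of 8 units; `hidden = rep(8L, 8L)` gives the
#'   alternative deep preset of eight hidden layers.
#' @slot maxIterations maximum gradient-descent iterations (default 1000).
#' @slot learningRate gradient-descent step size.
#' @slot tolerance stop when the loss improvement falls below this.
#' @slot classes class label vocabulary (>= 2 entries).
#' @slot seed RNG seed for weight initialization and the stratified split.
#' @export
setClass("ClassifierConfig",
  representation(hidden = "integer", maxIterations = "integer",
                 learningRate = "numeric", tolerance = "numeric",
                 classes = "character", seed = "integer"))

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (!length(object@hidden) || any(object@hidden < 1L))
    msg <- c(msg, "hidden must be a non-empty vector of positive widths")
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
  if (length(object@classes) < 2L) msg <- c(msg, "need at least 2 classes")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClassifierConfig-class constructor.
#' @param hidden,maxIterations,learningRate,tolerance,classes,seed see slots.
#' @export
ClassifierConfig <- function(hidden = 8L, maxIterations = 1000L,
                             learningRate = 0.01, tolerance = 1e-5,
                             classes = c("TUMOR", "IMMUNE", "STROMA", "IGNORE"),
                             seed = 1L) {
  new("ClassifierConfig", hidden = as.integer(hidden),
      maxIterations = as.integer(maxIterations), learningRate = learningRate,
      tolerance = tolerance, classes = classes, seed = as.integer(seed))
}

#' Trained cell classifier
#'
#' @slot weights list of layer weight matrices; @slot biases matching bias
#'   vectors; layer shapes chain from the feature count to the class count.
#' @slot config the [ClassifierConfig-class] used for training.
#' @slot featureNames feature columns the network expects, in order.
#' @slot center,scale z-standardization statistics from the training rows.
#' @slot classCounts training examples per class.
#' @slot confusion held-out confusion matrix (rows = truth).
#' @export
setClass("CellClassifier",
  representation(weights = "list", biases = "list", config = "ClassifierConfig",
                 featureNames = "character", center = "numeric",
                 scale = "numeric", classCounts = "integer",
                 confusion = "matrix"))

setValidity("CellClassifier", function(object) {
  p <- length(object@featureNames)
  dims <- c(p, object@config@hidden, length(object@config@classes))
  if (length(object@weights) != length(dims) - 1L)
    return("wrong number of weight layers")
  for (i in seq_along(object@weights)) {
    if (!all(dim(object@weights[[i]]) == c(dims[i], dims[i + 1L])))
      return(sprintf("layer %d weight shape does not chain", i))
    if (length(object@biases[[i]]) != dims[i + 1L])
      return(sprintf("layer %d bias length does not chain", i))
  }
  TRUE
})

setMethod("show", "CellClassifier", function(object) {
  cat(sprintf("CellClassifier: %d features -> [%s] -> %d classes (%s)\n",
              length(object@featureNames),
              paste(object@config@hidden, collapse = ", "),
              length(object@config@classes),
              paste(object@config@classes, collapse = "/")))
  cat("training examples per class:\n")
  print(object@classCounts)
  if (all(dim(object@confusion) > 0)) {
    acc <- sum(diag(object@confusion)) / sum(object@confusion)
    cat(sprintf("held-out accuracy: %.3f\n", acc))
  }
})
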