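# Synthetic H&E tiles with exact ground truth, and proportional-hazards
# survival cohorts tied to a dichotomized TILs score. Every generator is a
# pure function of its spec (including the spec's seed).

#' Generate a synthetic H&E tile with ground truth
#'
#' Nuclei are placed by seeded dart-throwing honoring the minimum
#' center-to-center separation, rendered as rotated ellipses with a
#' parabolic radial hematoxylin OD profile plus a faint uniform eosin
#' tissue background, composed through the spec's stain matrix
#' (Beer-Lambert), converted to transmitted intensity
#' `I = I0 * 10^-OD` and corrupted with additive Gaussian intensity noise.
#' The returned truth table is exact.
#'
#' @param spec A [SceneSpec-class].
#' @return List with `image` (RGB intensity array `[nx, ny, 3]`), `truth`
#'   (data.frame: `id`, `class`, `centroid_x_um`, `centroid_y_um`,
#'   `area_um2`, `peak_od`, list column `polygon`), `od` (noise-free
#'   [ODImage-class]) and `spec`.
#' @examples
#' tile <- simulateTile(SceneSpec(tileSize = 60,
#'   counts = c(TUMOR = 2L, IMMUNE = 1L, STROMA = 1L), seed = 3L))
#' @export
simulateTile <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    px <- spec@pixelSize
    n <- max(1L, round(spec@tileSize / px))
    total <- sum(spec@counts)
    cls <- rep(names(spec@counts), spec@counts)

    # dart-throwing with rejection
    margin <- 8
    centers <- matrix(0, 0, 2)
    rejections <- 0L
    while (nrow(centers) < total) {
      cand <- stats::runif(2, margin, spec@tileSize - margin)
      ok <- !nrow(centers) ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
              spec@minSeparation^2)
      if (ok) centers <- rbind(centers, cand)
      else {
        rejections <- rejections + 1L
        if (rejections > 1e4L)
          stop("packing error: requested cell counts unachievable at ",
               "minimum separation ", spec@minSeparation, " um", call. = FALSE)
      }
    }

    hema <- matrix(0, n, n)
    eos <- matrix(0, n, n)
    gx <- (seq_len(n) - 1) * px
    polys <- vector("list", total)
    area <- peak <- numeric(total)
    theta <- seq(0, 2 * pi, length.out = 33L)[-33L]
    for (i in seq_len(total)) {
      mo <- spec@morphology[[cls[i]]]
      A <- stats::runif(1, mo$area[1], mo$area[2])
      ecc <- stats::runif(1, mo$eccentricity[1], mo$eccentricity[2])
      pOD <- stats::runif(1, mo$peakOD[1], mo$peakOD[2])
      cyt <- if (is.null(mo$cytoOD)) 0 else stats::runif(1, mo$cytoOD[1], mo$cytoOD[2])
      ratio <- sqrt(1 - ecc^2)              # b / a
      a <- sqrt(A / (pi * ratio)); b <- a * ratio
      rot <- stats::runif(1, 0, pi)
      area[i] <- A; peak[i] <- pOD
      ca <- cos(rot); sa <- sin(rot)
      cx <- centers[i, 1]; cy <- centers[i, 2]
      polys[[i]] <- cbind(
        x_um = cx + a * cos(theta) * ca - b * sin(theta) * sa,
        y_um = cy + a * cos(theta) * sa + b * sin(theta) * ca)
      # render on a local window (cytoplasm halo reaches 2x the nucleus)
      ext <- ceiling(2 * a / px) + 2L
      i0 <- max(1L, round(cx / px) + 1L - ext); i1 <- min(n, round(cx / px) + 1L + ext)
      j0 <- max(1L, round(cy / px) + 1L - ext); j1 <- min(n, round(cy / px) + 1L + ext)
      if (i0 > i1 || j0 > j1) next
      X <- matrix(gx[i0:i1] - cx, i1 - i0 + 1L, j1 - j0 + 1L)
      Y <- matrix(gx[j0:j1] - cy, i1 - i0 + 1L, j1 - j0 + 1L, byrow = TRUE)
      u <- (X * ca + Y * sa) / a
      v <- (-X * sa + Y * ca) / b
      r2 <- u^2 + v^2
      # radial chromatin density (1 - r^2)^1.5: zero at the membrane with a
      # soft shoulder, so the thresholded area of the smoothed OD matches
      # the true ellipse area closely
      prof <- pOD * pmax(1 - r2, 0)^1.5
      hema[i0:i1, j0:j1] <- pmax(hema[i0:i1, j0:j1], prof)
      halo <- cyt * pmax(1 - r2 / 4, 0) * (r2 <= 4)
      eos[i0:i1, j0:j1] <- pmax(eos[i0:i1, j0:j1], halo)
    }

    conc <- array(0, c(n, n, 3))
    conc[, , 1] <- hema
    conc[, , 2] <- eos + 0.06                # faint eosin tissue background
    od <- composeStains(conc, spec@stainModel, pixelSize = px)
    img <- odToRGB(od, spec@stainModel@background)
    if (spec@noiseSd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec@noiseSd), dim(img))
      for (k in 1:3)
        img[, , k] <- pmin(pmax(img[, , k], 0), spec@stainModel@background[k])
    }

    truth <- data.frame(id = seq_len(total), class = cls,
                        centroid_x_um = centers[, 1],
                        centroid_y_um = centers[, 2],
                        area_um2 = area, peak_od = peak,
                        stringsAsFactors = FALSE)
    truth$polygon <- polys
    ord <- order(truth$centroid_y_um, truth$centroid_x_um)
    truth <- truth[ord, , drop = FALSE]
    truth$id <- seq_len(total)
    rownames(truth) <- NULL
    list(image = img, truth = truth, od = od, spec = spec)
  })
}

#' Generate a synthetic proportional-hazards survival cohort
#'
#' TILs scores are drawn from the spec's two-component normal mixture
#' (truncated to [0, 100]); patients at or above the spec's change-point
#' form the high group; event times are exponential with hazard
#' `baselineRate * hr^I(high) * exp(x' covariateLogHR)`; censoring is an
#' independent uniform time calibrated so the realized censored fraction
#' matches the requested rate in expectation. Clinical covariates (age,
#' sex, pT/pN/pM/pTNM stage, lymphovascular invasion) are drawn from
#' bladder-cancer-like marginals.
#'
#' @param spec A [CohortSpec-class].
#' @return A data.frame (one row per patient): `id`, `time_months`, `event`,
#'   `eTILs_pct`, `tils_high`, `age_years`, `age70`, `sex`, `pT`, `pN`,
#'   `pM`, `pTNM`, `stage34`, `lvi`.
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    n <- spec@n
    comp <- sample.int(2L, n, replace = TRUE, prob = spec@mixtureWeights)
    val <- stats::rnorm(n, spec@mixtureMeans[comp], spec@mixtureSds[comp])
    val <- pmin(pmax(val, 0), 100)
    high <- as.integer(val >= spec@cutpoint)

    age <- round(pmin(pmax(stats::rnorm(n, 68, 10), 30), 95))
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.76, 0.24))
    pT <- sample(c("pT2", "pT3", "pT4"), n, replace = TRUE,
                 prob = c(0.30, 0.53, 0.17))
    pN <- sample(c("pN0", "pN1", "pN2", "pN3"), n, replace = TRUE,
                 prob = c(0.59, 0.12, 0.24, 0.05))
    pM <- sample(c("pM0", "pM1"), n, replace = TRUE, prob = c(0.95, 0.05))
    pTNM <- ifelse(pM == "pM1", "IV",
                   ifelse(pN != "pN0", "III-IV",
                          ifelse(pT == "pT2", "II", "III-IV")))
    pTNM[pTNM == "IV"] <- "III-IV"
    lvi <- stats::rbinom(n, 1L, 0.4)

    eff <- spec@covariateLogHR
    lp <- log(spec@hr) * high +
      .effOr0(eff, "age70") * (age >= 70) +
      .effOr0(eff, "stage34") * (pTNM == "III-IV") +
      .effOr0(eff, "lvi") * lvi
    rate <- spec@baselineRate * exp(lp)
    tEvent <- stats::rexp(n, rate)

    if (spec@censoringRate > 0) {
      cmax <- .calibrateUniformCensoring(tEvent, spec@censoringRate)
      cens <- stats::runif(n, 0, cmax)
      time <- pmin(tEvent, cens)
      event <- as.integer(tEvent <= cens)
    } else {
      time <- tEvent
      event <- rep(1L, n)
    }

    data.frame(id = seq_len(n), time_months = time, event = event,
               eTILs_pct = val, tils_high = high,
               age_years = age, age70 = as.integer(age >= 70), sex = sex,
               pT = pT, pN = pN, pM = pM, pTNM = pTNM,
               stage34 = as.integer(pTNM == "III-IV"), lvi = lvi,
               stringsAsFactors = FALSE)
  })
}

.effOr0 <- function(eff, nm) if (nm %in% names(eff)) eff[[nm]] else 0

# Choose cmax so that, given the realized event times, a U(0, cmax)
# censoring time censors the requested fraction: mean(min(T/cmax, 1)) = q.
.calibrateUniformCensoring <- function(tEvent, q) {
  f <- function(cmax) mean(pmin(tEvent / cmax, 1)) - q
  hi <- max(tEvent) / q + 1
  stats::uniroot(f, c(1e-9, hi), tol = 1e-10)$root
}

#' Generate a paired image + survival fixture for end-to-end tests
#'
#' For every patient of a synthetic cohort, a tile is generated whose true
#' tumor/immune counts reproduce that patient's eTILs% to within rounding
#' (±1 percentage point for 100+ epithelial cells), so the full pipeline
#' from pixels to hazard ratios can be checked against exact ground truth.
#'
#' @param cohortSpec A [CohortSpec-class].
#' @param sceneTemplate A [SceneSpec-class] whose total epithelial count
#'   (TUMOR + IMMUNE) and STROMA count set the per-tile cell budget.
#' @param patients indices of cohort rows to build tiles for (tiles are the
#'   expensive part; default all).
#' @param outDir optional directory; when given, tiles are written as PNG,
#'   truth tables and the cohort as CSV.
#' @return List with `cohort` (data.frame), `tiles` (list of
#'   [simulateTile()] results with an extra `patient` element), and
#'   `paths` when `outDir` was given.
#' @export
simulateFixture <- function(cohortSpec, sceneTemplate = SceneSpec(),
                            patients = seq_len(cohortSpec@n),
                            outDir = NULL) {
  cohort <- simulateCohort(cohortSpec)
  nEpi <- sum(sceneTemplate@counts[c("TUMOR", "IMMUNE")])
  nStroma <- sceneTemplate@counts[["STROMA"]]
  tiles <- vector("list", length(patients))
  for (k in seq_along(patients)) {
    i <- patients[k]
    nImm <- as.integer(round(cohort$eTILs_pct[i] / 100 * nEpi))
    counts <- c(TUMOR = nEpi - nImm, IMMUNE = nImm, STROMA = nStroma)
    sp <- sceneTemplate
    sp@counts <- stats::setNames(as.integer(counts), names(counts))
    sp@seed <- cohortSpec@seed + 1000L + as.integer(i)
    tile <- simulateTile(sp)
    tile$patient <- i
    tile$true_eTILs_pct <- 100 * nImm / nEpi
    tiles[[k]] <- tile
  }
  out <- list(cohort = cohort, tiles = tiles)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    for (tile in tiles) {
      base <- file.path(outDir, sprintf("patient_%03d", tile$patient))
      png::writePNG(.toPNGArray(tile$image, tile$spec@stainModel@background),
                    paste0(base, "_tile.png"))
      tt <- tile$truth[, c("id", "class", "centroid_x_um", "centroid_y_um",
                           "area_um2", "peak_od")]
      utils::write.csv(tt, paste0(base, "_truth.csv"), row.names = FALSE)
      paths <- c(paths, paste0(base, "_tile.png"), paste0(base, "_truth.csv"))
    }
    cohortPath <- file.path(outDir, "cohort.csv")
    utils::write.csv(cohort, cohortPath, row.names = FALSE)
    out$paths <- c(paths, cohortPath)
  }
  out
}

# [nx, ny, 3] intensity array -> [ny, nx, 3] array in [0,1] for writePNG
.toPNGArray <- function(img, background) {
  out <- array(0, c(dim(img)[2], dim(img)[1], 3))
  for (k in 1:3) out[, , k] <- t(img[, , k]) / background[k]
  pmin(pmax(out, 0), 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, making generators pure
#' functions of spec + seed.
#' @param seed integer seed. @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
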