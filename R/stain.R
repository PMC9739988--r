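# H&E stain estimation and color deconvolution in optical-density space.
#
# Transmitted intensity I relates to stain concentrations c through
# Beer-Lambert: I = I0 * 10^-(M c), with M the 3x3 matrix of unit stain OD
# vectors. All stain arithmetic therefore happens on OD = -log10(I / I0).

#' Convert an RGB intensity image to optical density
#'
#' Computes the decadic optical density `OD = -log10(max(I, 1) / I0)` per
#' channel. The intensity is clamped at 1 before the log so fully opaque
#' pixels map to a large finite OD rather than infinity; negative OD (pixels
#' brighter than the background estimate) is clipped to 0.
#'
#' @param image numeric array `[nx, ny, 3]` of RGB intensities in
#'   `[0, background]`.
#' @param background per-channel white level; a single value is recycled.
#'   When `NULL`, the per-channel 99.9th-percentile intensity is used as a
#'   robust white estimate.
#' @param pixelSize physical pixel size in micrometers.
#' @return An [ODImage-class].
#' @examples
#' img <- array(128, c(4, 4, 3))
#' od <- rgbToOD(img, background = 255, pixelSize = 0.5)
#' @export
rgbToOD <- function(image, background = NULL, pixelSize = 0.5) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (is.null(background)) {
    background <- vapply(1:3, function(k)
      as.numeric(stats::quantile(image[, , k], 0.999, names = FALSE)), 0)
  }
  background <- rep_len(as.numeric(background), 3L)
  if (any(!is.finite(background)) || any(background <= 0))
    stop("background intensity must be positive", call. = FALSE)
  od <- array(0, dim(image))
  for (k in 1:3)
    od[, , k] <- pmax(-log10(pmax(image[, , k], 1) / background[k]), 0)
  new("ODImage", values = od, pixelSize = pixelSize)
}

#' Estimate H&E stain vectors from an image
#'
#' Automatic stain estimation by plane fitting: foreground pixels (total OD
#' above `odMin`) are projected onto the plane of the two leading singular
#' vectors of the OD cloud; the extreme directions at the `anglePercentile`
#' and `1 - anglePercentile` quantiles of the in-plane angle are taken as the
#' two stain vectors. Hematoxylin is identified as the vector with the larger
#' blue-channel OD component; the residual direction is the normalized cross
#' product.
#'
#' @param od An [ODImage-class].
#' @param odMin foreground threshold on the total (summed) OD; default 0.15.
#' @param anglePercentile extreme-angle quantile; default 0.01 (the 1%/99%
#'   rule).
#' @param background per-channel white level recorded in the returned model.
#' @return A [StainModel-class].
#' @examples
#' mod <- defaultStainModel()
#' conc <- array(stats::runif(3 * 600, 0.1, 1), c(600, 1, 3))
#' conc[, , 3] <- 0
#' od <- composeStains(conc, mod)
#' fit <- estimateStainVectors(od)
#' @export
estimateStainVectors <- function(od, odMin = 0.15, anglePercentile = 0.01,
                                 background = c(255, 255, 255)) {
  stopifnot(is(od, "ODImage"))
  v <- od@values
  px <- cbind(as.vector(v[, , 1]), as.vector(v[, , 2]), as.vector(v[, , 3]))
  fg <- px[rowSums(px) > odMin, , drop = FALSE]
  if (nrow(fg) < 100L)
    stop("degenerate input: fewer than 100 foreground pixels above OD ",
         odMin, call. = FALSE)
  sv <- svd(fg, nu = 0, nv = 3)
  if (sv$d[2] < 1e-6 * sv$d[1])
    stop("degenerate input: OD cloud is rank 1 (single stain); ",
         "second singular value collapsed", call. = FALSE)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  # orient the plane basis so projections are positive along e1
  if (sum(fg %*% e1) < 0) e1 <- -e1
  proj1 <- fg %*% e1
  proj2 <- fg %*% e2
  ang <- atan2(proj2, proj1)
  qa <- stats::quantile(ang, c(anglePercentile, 1 - anglePercentile),
                        names = FALSE)
  mk <- function(a) {
    w <- cos(a) * e1 + sin(a) * e2
    if (sum(w) < 0) w <- -w          # OD vectors have non-negative total
    w / sqrt(sum(w^2))
  }
  v1 <- mk(qa[1]); v2 <- mk(qa[2])
  if (acos(min(1, abs(sum(v1 * v2)))) * 180 / pi <= 1)
    stop("degenerate input: extreme-angle directions collapsed ",
         "(single stain)", call. = FALSE)
  # hematoxylin carries the larger blue-channel OD component
  if (v1[3] >= v2[3]) StainModel(v1, v2, background = background)
  else StainModel(v2, v1, background = background)
}

#' Unmix an OD image into per-stain concentration channels
#'
#' Solves the 3x3 linear system `OD = M c` for every pixel, where the columns
#' of `M` are the model's hematoxylin, eosin and residual vectors. Negative
#' concentrations are clipped to 0.
#'
#' @param od An [ODImage-class].
#' @param model A [StainModel-class].
#' @return Numeric array `[nx, ny, 3]` with channels hematoxylin, eosin,
#'   residual; carries a `pixelSize` attribute.
#' @export
deconvolveStains <- function(od, model) {
  stopifnot(is(od, "ODImage"), is(model, "StainModel"))
  validObject(model)
  M <- stainMatrix(model)
  if (abs(det(M)) < 1e-12)
    stop("singular stain matrix", call. = FALSE)
  v <- od@values
  d <- dim(v)
  px <- rbind(as.vector(v[, , 1]), as.vector(v[, , 2]), as.vector(v[, , 3]))
  conc <- solve(M, px)
  conc[conc < 0] <- 0
  out <- array(0, d)
  for (k in 1:3) out[, , k] <- conc[k, ]
  dimnames(out) <- list(NULL, NULL, c("hematoxylin", "eosin", "residual"))
  attr(out, "pixelSize") <- od@pixelSize
  out
}

#' Compose stain concentrations into an OD image (forward Beer-Lambert)
#'
#' The inverse of [deconvolveStains()]: `OD = M c` per pixel. Useful for
#' rendering synthetic data and round-trip checks.
#'
#' @param conc numeric array `[nx, ny, 3]` of non-negative concentrations
#'   (hematoxylin, eosin, residual).
#' @param model A [StainModel-class].
#' @param pixelSize physical pixel size in micrometers.
#' @return An [ODImage-class].
#' @export
composeStains <- function(conc, model, pixelSize = 0.5) {
  stopifnot(length(dim(conc)) == 3L, dim(conc)[3] == 3L,
            is(model, "StainModel"))
  M <- stainMatrix(model)
  d <- dim(conc)
  cc <- rbind(as.vector(conc[, , 1]), as.vector(conc[, , 2]),
              as.vector(conc[, , 3]))
  od <- M %*% cc
  out <- array(0, d)
  for (k in 1:3) out[, , k] <- pmax(od[k, ], 0)
  new("ODImage", values = out, pixelSize = pixelSize)
}

#' Render an OD image to RGB transmitted intensity
#'
#' `I = I0 * 10^-OD` per channel, the camera-side counterpart of
#' [rgbToOD()].
#'
#' @param od An [ODImage-class].
#' @param background per-channel white level.
#' @return Numeric array `[nx, ny, 3]` of intensities.
#' @export
odToRGB <- function(od, background = c(255, 255, 255)) {
  stopifnot(is(od, "ODImage"))
  background <- rep_len(as.numeric(background), 3L)
  out <- array(0, dim(od@values))
  for (k in 1:3) out[, , k] <- background[k] * 10^(-od@values[, , k])
  out
}

#' Angular distance between two direction vectors, in degrees
#' @param a,b numeric vectors of equal length.
#' @keywords internal
angleBetween <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

#' Write a stain model to a small structured text file
#'
#' Serialized as JSON: one entry per stain name with its 3 OD components,
#' plus the background triplet.
#'
#' @param model A [StainModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStainModel <- function(model, path) {
  stopifnot(is(model, "StainModel"))
  obj <- list(hematoxylin = model@hematoxylin, eosin = model@eosin,
              residual = model@residual, background = model@background)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeStainModel
#' @export
readStainModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  StainModel(obj$hematoxylin, obj$eosin, residual = obj$residual,
             background = obj$background)
}
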