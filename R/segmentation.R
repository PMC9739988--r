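# Watershed nucleus detection on the hematoxylin OD channel.
#
# Image convention throughout: matrices are indexed [x, y] (EBImage layout);
# pixel (i, j) sits at micron coordinates ((i-1) * pixelSize,
# (j-1) * pixelSize), origin at the image top-left, x rightward, y downward.

#' Area-weighted resampling to a working resolution
#'
#' Resamples a raster from its source pixel size to the requested working
#' resolution (0.5 um/px for the standard detector) by exact area-overlap
#' averaging, which is anti-aliased and mean-preserving. The physical extent
#' is preserved to within one output pixel. Upsampling by more than a factor
#' of 4 triggers a warning, since information cannot be created.
#'
#' @param image numeric matrix `[nx, ny]` or array `[nx, ny, k]`.
#' @param sourcePixelSize,requestedPixelSize pixel sizes in um (> 0).
#' @return The resampled raster (same number of channels).
#' @export
resampleToWorkingResolution <- function(image, sourcePixelSize,
                                        requestedPixelSize) {
  stopifnot(sourcePixelSize > 0, requestedPixelSize > 0)
  if (sourcePixelSize == requestedPixelSize) return(image)
  if (requestedPixelSize < sourcePixelSize / 4)
    warning("upsampling by more than 4x: information cannot be created",
            call. = FALSE)
  f <- function(m) {
    Wx <- .overlapWeights(nrow(m), sourcePixelSize, requestedPixelSize)
    Wy <- .overlapWeights(ncol(m), sourcePixelSize, requestedPixelSize)
    Wx %*% m %*% t(Wy)
  }
  if (length(dim(image)) == 3L) {
    ch <- lapply(seq_len(dim(image)[3]), function(k) f(image[, , k]))
    out <- array(0, c(dim(ch[[1]]), length(ch)))
    for (k in seq_along(ch)) out[, , k] <- ch[[k]]
    out
  } else f(image)
}

# Row-stochastic matrix of interval-overlap weights for 1-D area resampling.
.overlapWeights <- function(nIn, srcPx, dstPx) {
  nOut <- max(1L, as.integer(round(nIn * srcPx / dstPx)))
  W <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    lo <- (i - 1) * dstPx; hi <- i * dstPx
    j0 <- max(1L, floor(lo / srcPx) + 1L)
    j1 <- min(nIn, ceiling(hi / srcPx))
    j <- j0:j1
    ov <- pmin(hi, j * srcPx) - pmax(lo, (j - 1) * srcPx)
    ov[ov < 0] <- 0
    W[i, j] <- ov
  }
  W / rowSums(W)
}

#' Grayscale morphological opening with an approximately circular element
#'
#' Erosion followed by dilation with an octagonal structuring element that
#' approximates a disc of the given radius (maximum radial error about 8%).
#' Used to estimate the slowly varying background of the hematoxylin OD
#' image. Edges are handled by replication.
#'
#' @param m numeric matrix.
#' @param radiusPx element radius in pixels (>= 1).
#' @return Matrix of the same shape.
#' @export
grayOpening <- function(m, radiusPx) {
  er <- .octagonFilter(m, radiusPx, pmin)
  .octagonFilter(er, radiusPx, pmax)
}

# Min/max filter over an octagon: composition of line elements along the
# horizontal, vertical and both diagonals (Minkowski decomposition).
.octagonFilter <- function(m, r, op) {
  a <- max(1L, round(0.414 * r))   # half-length of axis-aligned lines
  b <- max(1L, round(0.293 * r))   # half-length of diagonal lines
  m <- .lineFilter(m, a, 1L, 0L, op)
  m <- .lineFilter(m, a, 0L, 1L, op)
  m <- .lineFilter(m, b, 1L, 1L, op)
  .lineFilter(m, b, 1L, -1L, op)
}

.lineFilter <- function(m, halfLen, dx, dy, op) {
  nx <- nrow(m); ny <- ncol(m)
  out <- m
  for (s in seq_len(halfLen)) {
    for (sg in c(-1L, 1L)) {
      ix <- pmin(pmax(seq_len(nx) + sg * s * dx, 1L), nx)
      iy <- pmin(pmax(seq_len(ny) + sg * s * dy, 1L), ny)
      out <- op(out, m[ix, iy, drop = FALSE])
    }
  }
  out
}

#' Signed polygon area (shoelace), absolute value in square input units
#' @param poly two-column matrix of vertices (closed implicitly).
#' @export
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Rasterize a polygon over pixel centers
#'
#' Even-odd point-in-polygon test evaluated at every pixel center of an
#' `nx` by `ny` grid with the given pixel size.
#'
#' @param poly two-column matrix of vertices in um.
#' @param nx,ny grid dimensions; @param pixelSize um per pixel.
#' @return Logical matrix `[nx, ny]`.
#' @export
rasterizePolygon <- function(poly, nx, ny, pixelSize) {
  px <- (seq_len(nx) - 1) * pixelSize
  py <- (seq_len(ny) - 1) * pixelSize
  X <- matrix(px, nx, ny)
  Y <- matrix(py, nx, ny, byrow = TRUE)
  inside <- matrix(FALSE, nx, ny)
  n <- nrow(poly)
  jprev <- n
  for (j in seq_len(n)) {
    x1 <- poly[jprev, 1]; y1 <- poly[jprev, 2]
    x2 <- poly[j, 1];     y2 <- poly[j, 2]
    crosses <- ((y1 > Y) != (y2 > Y))
    if (any(crosses)) {
      xi <- x1 + (Y - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (X < xi))
    }
    jprev <- j
  }
  inside
}

#' Detect and segment cells by watershed on the hematoxylin OD channel
#'
#' Implements the standard watershed cell-detection pipeline on a
#' hematoxylin OD raster at the working resolution: optional median filter
#' (skipped when the radius is 0), Gaussian smoothing, background estimation
#' by grayscale opening and subtraction, thresholding of the
#' background-corrected OD, hole filling, distance-transform watershed to
#' split touching nuclei, an area filter on the nucleus, rejection of nuclei
#' sitting on background brighter than `maxBackgroundIntensity`, and cell
#' boundary construction by distance-limited Voronoi expansion of the
#' nucleus so neighboring cells never overlap. Detections are confined to
#' the region of interest and ordered by (y, x) of their centroid.
#'
#' @param hemaOD numeric matrix `[nx, ny]` of hematoxylin OD at
#'   `params@requestedPixelSize` (all values >= 0).
#' @param params A [DetectionParams-class].
#' @param roi two-column matrix of ROI polygon vertices in um; `NULL` uses
#'   the full image.
#' @return A data.frame with one row per detected cell: `id`, `class`
#'   (initially `"UNCLASSIFIED"`), `centroid_x_um`, `centroid_y_um`,
#'   `nucleus_area_um2`, `cell_area_um2`, and list columns
#'   `nucleus_polygon`, `cell_polygon` (two-column um matrices). Label masks
#'   are attached as attributes `nucleusLabels` and `cellLabels`, the pixel
#'   size as `pixelSize`.
#' @export
detectCells <- function(hemaOD, params = DetectionParams(), roi = NULL) {
  stopifnot(is.matrix(hemaOD))
  validObject(params)
  if (any(hemaOD < 0))
    stop("input raster is not in OD units (negative values present)",
         call. = FALSE)
  px <- params@requestedPixelSize
  nx <- nrow(hemaOD); ny <- ncol(hemaOD)
  if (is.null(roi)) {
    roi <- cbind(c(0, nx, nx, 0), c(0, 0, ny, ny)) * px
  }
  if (nrow(roi) < 3L || polygonArea(roi) <= 0)
    stop("empty roi", call. = FALSE)
  roiMask <- rasterizePolygon(roi, nx, ny, px)
  if (!any(roiMask)) stop("empty roi", call. = FALSE)

  img <- hemaOD
  if (params@medianRadius > 0) {
    sz <- max(1L, round(params@medianRadius / px))
    top <- max(img, 1e-6)
    img <- EBImage::medianFilter(img / top, sz) * top
  }
  if (params@sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = params@sigma / px))
  if (params@backgroundRadius > 0) {
    bg <- grayOpening(img, max(1L, round(params@backgroundRadius / px)))
  } else bg <- matrix(0, nx, ny)
  sub <- pmax(img - bg, 0)

  fg <- (sub > params@odThreshold) & roiMask
  fg <- EBImage::fillHull(fg)
  if (!any(fg)) return(.emptyDetections(nx, ny, px))

  dm <- EBImage::distmap(fg)
  seedSepPx <- max(1L, round(2 / px))          # 2 um minimum seed separation
  lab <- EBImage::watershed(dm, tolerance = 1, ext = seedSepPx)
  lab <- EBImage::fillHull(lab)
  lab <- matrix(as.integer(lab), nx, ny)
  nObj <- max(lab)
  if (nObj == 0L) return(.emptyDetections(nx, ny, px))

  idx <- which(lab > 0L)
  ij <- arrayInd(idx, dim(lab))
  labv <- lab[idx]
  cnt <- tabulate(labv, nObj)
  # rowsum orders by sorted unique label; labels are 1..nObj with possible gaps
  present <- sort(unique(labv))
  cxs <- rep(NA_real_, nObj); cys <- rep(NA_real_, nObj)
  cxs[present] <- rowsum((ij[, 1] - 1) * px, labv)[, 1] / cnt[present]
  cys[present] <- rowsum((ij[, 2] - 1) * px, labv)[, 1] / cnt[present]
  areas <- cnt * px^2

  keep <- which(!is.na(cxs) &
                areas >= params@minCellArea & areas <= params@maxCellArea)
  if (length(keep)) {
    ci <- pmin(pmax(round(cxs[keep] / px) + 1, 1), nx)
    cj <- pmin(pmax(round(cys[keep] / px) + 1, 1), ny)
    bgAtC <- bg[cbind(ci, cj)]
    keep <- keep[bgAtC <= params@maxBackgroundIntensity]
  }
  if (!length(keep)) return(.emptyDetections(nx, ny, px))

  keep <- keep[order(cys[keep], cxs[keep])]
  nucLab <- matrix(0L, nx, ny)
  for (newId in seq_along(keep)) nucLab[lab == keep[newId]] <- newId
  n <- length(keep)

  # distance-limited Voronoi expansion of nuclei into cell territories
  expPx <- params@cellExpansion / px
  distToNuc <- EBImage::distmap(nucLab == 0L)
  cellRegion <- (distToNuc <= expPx) & roiMask
  cellRegion[nucLab > 0L] <- TRUE
  cellLab <- EBImage::propagate(matrix(0, nx, ny), seeds = nucLab,
                                mask = cellRegion, lambda = 1e10)
  cellLab <- matrix(as.integer(cellLab), nx, ny)

  nucPoly <- .labelContours(nucLab, n, px)
  cellPoly <- .labelContours(cellLab, n, px)
  cellCnt <- tabulate(cellLab[cellLab > 0L], n)

  out <- data.frame(
    id = seq_len(n),
    class = rep("UNCLASSIFIED", n),
    centroid_x_um = cxs[keep],
    centroid_y_um = cys[keep],
    nucleus_area_um2 = areas[keep],
    cell_area_um2 = cellCnt * px^2,
    stringsAsFactors = FALSE
  )
  out$nucleus_polygon <- nucPoly
  out$cell_polygon <- cellPoly
  attr(out, "nucleusLabels") <- nucLab
  attr(out, "cellLabels") <- cellLab
  attr(out, "pixelSize") <- px
  out
}

.emptyDetections <- function(nx, ny, px) {
  out <- data.frame(id = integer(), class = character(),
                    centroid_x_um = numeric(), centroid_y_um = numeric(),
                    nucleus_area_um2 = numeric(), cell_area_um2 = numeric(),
                    stringsAsFactors = FALSE)
  out$nucleus_polygon <- list()
  out$cell_polygon <- list()
  attr(out, "nucleusLabels") <- matrix(0L, nx, ny)
  attr(out, "cellLabels") <- matrix(0L, nx, ny)
  attr(out, "pixelSize") <- px
  out
}

# Outer contours of labelled objects, as micron polygons at pixel centers.
.labelContours <- function(lab, n, px) {
  oc <- EBImage::ocontour(lab)
  lapply(seq_len(n), function(i) {
    p <- oc[[i]]
    m <- cbind(x_um = p[, 1] * px, y_um = p[, 2] * px)
    m
  })
}

#' Per-class counts and analyzed area
#'
#' @param detections detection data.frame (see [detectCells()]); the `class`
#'   column may contain `UNCLASSIFIED`.
#' @param roi two-column polygon matrix in um.
#' @return List with `counts` (named integer over TUMOR, IMMUNE, STROMA,
#'   IGNORE, UNCLASSIFIED) and `area_mm2` (ROI polygon area / 1e6).
#' @examples
#' roi <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' det <- data.frame(class = c("TUMOR", "TUMOR", "IMMUNE"))
#' countAndArea(det, roi)
#' @export
countAndArea <- function(detections, roi) {
  classes <- c("TUMOR", "IMMUNE", "STROMA", "IGNORE", "UNCLASSIFIED")
  cl <- factor(detections$class, levels = classes)
  counts <- table(cl)
  list(counts = stats::setNames(as.integer(counts), classes),
       area_mm2 = polygonArea(roi) / 1e6)
}
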