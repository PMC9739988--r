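# Per-cell intensity and shape measurements, plus Gaussian neighborhood
# smoothing of every base feature at configurable radii (25 and 50 um by
# default) to give each cell context from its surroundings.

#' Compute per-cell intensity and shape features
#'
#' For every detected cell, intensity statistics (mean, sd, min, max) of the
#' hematoxylin and eosin OD are computed over three compartments — nucleus,
#' whole cell, and cytoplasm (cell minus nucleus) — together with nucleus
#' shape descriptors (area, perimeter, circularity, eccentricity, max/min
#' caliper), the cell area, and the nucleus/cell area ratio. A cell whose
#' cytoplasm ring is empty falls back to the cell statistics and is flagged
#' in the `qc_cytoplasm_fallback` column. Column order is deterministic;
#' names follow `<compartment>_<stain>_<stat>`.
#'
#' @param detections detection data.frame from [detectCells()] (must carry
#'   the `nucleusLabels`/`cellLabels` mask attributes).
#' @param hemaChannel,eosinChannel numeric matrices at the working
#'   resolution.
#' @return data.frame keyed by `id` with one row per cell; carries a
#'   `pixelSize` attribute.
#' @export
computeCellFeatures <- function(detections, hemaChannel, eosinChannel) {
  nucLab <- attr(detections, "nucleusLabels")
  cellLab <- attr(detections, "cellLabels")
  px <- attr(detections, "pixelSize")
  if (is.null(nucLab) || is.null(cellLab) || is.null(px))
    stop("detections must carry nucleusLabels/cellLabels/pixelSize attributes",
         call. = FALSE)
  n <- nrow(detections)
  stains <- list(hema = hemaChannel, eosin = eosinChannel)
  stat4 <- function(v) c(mean = mean(v), std = stats::sd(v),
                         min = min(v), max = max(v))
  empty4 <- c(mean = NA_real_, std = NA_real_, min = NA_real_, max = NA_real_)

  nzN <- which(nucLab > 0L)
  nucIdxBy <- split(nzN, nucLab[nzN])
  nzC <- which(cellLab > 0L)
  cellIdxBy <- split(nzC, cellLab[nzC])
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nucIdx <- nucIdxBy[[as.character(i)]]
    cellIdx <- cellIdxBy[[as.character(i)]]
    if (is.null(nucIdx)) nucIdx <- integer()
    if (is.null(cellIdx)) cellIdx <- integer()
    cytoIdx <- setdiff(cellIdx, nucIdx)
    fallback <- length(cytoIdx) == 0L
    rec <- list(id = detections$id[i])
    for (sn in names(stains)) {
      ch <- stains[[sn]]
      sN <- if (length(nucIdx)) stat4(ch[nucIdx]) else empty4
      sC <- if (length(cellIdx)) stat4(ch[cellIdx]) else empty4
      sY <- if (fallback) sC else stat4(ch[cytoIdx])
      for (st in names(sN)) {
        rec[[paste("nucleus", sn, st, sep = "_")]] <- unname(sN[st])
        rec[[paste("cell", sn, st, sep = "_")]] <- unname(sC[st])
        rec[[paste("cytoplasm", sn, st, sep = "_")]] <- unname(sY[st])
      }
    }
    shp <- shapeDescriptors(detections$nucleus_polygon[[i]])
    # area from the pixel mask, perimeter from the contour chain with the
    # Vossepoel-Smeulders staircase correction: polygon formulas alone
    # overestimate the perimeter and underestimate the area of rasterized
    # shapes, biasing circularity low
    areaUm2 <- detections$nucleus_area_um2[i]
    perim <- chainPerimeter(detections$nucleus_polygon[[i]], px)
    rec$nucleus_area <- areaUm2
    rec$nucleus_perimeter <- perim
    rec$nucleus_circularity <- min(4 * pi * areaUm2 / max(perim^2, 1e-12), 1)
    rec$nucleus_eccentricity <- shp[["eccentricity"]]
    rec$nucleus_max_caliper <- shp[["max_caliper"]]
    rec$nucleus_min_caliper <- shp[["min_caliper"]]
    rec$cell_area <- detections$cell_area_um2[i]
    rec$nucleus_cell_area_ratio <-
      detections$nucleus_area_um2[i] / max(detections$cell_area_um2[i], 1e-9)
    rec$qc_cytoplasm_fallback <- as.integer(fallback)
    rows[[i]] <- as.data.frame(rec)
  }
  out <- if (n) do.call(rbind, rows) else
    stop("no detections to measure", call. = FALSE)
  # single-pixel compartments have undefined sd; report 0 spread
  out[is.na(out)] <- 0
  rownames(out) <- NULL
  attr(out, "pixelSize") <- px
  out
}

#' Shape descriptors of a polygon
#'
#' Area and perimeter by the shoelace/edge-length formulas, circularity
#' `4 pi A / P^2` (1 for a circle), eccentricity from the second moments of
#' the vertex set, and max/min caliper (Feret) diameters over the edge
#' normal directions.
#'
#' @param poly two-column vertex matrix in um.
#' @return Named numeric vector.
#' @export
shapeDescriptors <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  jn <- c(2:n, 1L)
  perim <- sum(sqrt((x[jn] - x)^2 + (y[jn] - y)^2))
  A <- polygonArea(poly)
  circ <- min(4 * pi * A / max(perim^2, 1e-12), 1)
  # eccentricity from area-weighted central second moments of the polygon
  cx <- mean(x); cy <- mean(y)
  u <- x - cx; v <- y - cy
  cr <- u * v[jn] - u[jn] * v
  m20 <- sum(cr * (u^2 + u * u[jn] + u[jn]^2)) / 12
  m02 <- sum(cr * (v^2 + v * v[jn] + v[jn]^2)) / 12
  m11 <- sum(cr * (u * v[jn] + 2 * u * v + 2 * u[jn] * v[jn] + u[jn] * v)) / 24
  sgn <- sign(sum(cr) / 2)
  m20 <- m20 * sgn; m02 <- m02 * sgn; m11 <- m11 * sgn
  tr <- m20 + m02
  dt <- sqrt(max((m20 - m02)^2 / 4 + m11^2, 0))
  l1 <- tr / 2 + dt; l2 <- max(tr / 2 - dt, 1e-12)
  ecc <- sqrt(max(1 - l2 / l1, 0))
  # caliper widths over candidate directions (edge angles + fine sweep)
  ang <- seq(0, pi, length.out = 64L)[-64L]
  widths <- vapply(ang, function(a) {
    p <- x * cos(a) + y * sin(a)
    max(p) - min(p)
  }, 0)
  c(area = A, perimeter = perim, circularity = circ, eccentricity = ecc,
    max_caliper = max(widths), min_caliper = min(widths))
}

#' Perimeter of a pixel-chain contour with staircase correction
#'
#' Counts axial and diagonal chain steps of an 8-connected contour polygon
#' (vertices at pixel centers) and applies the Vossepoel-Smeulders weights
#' (0.948 per axial, 1.340 per diagonal step), which estimate the true
#' boundary length of digitized smooth shapes to within a few percent.
#'
#' @param poly two-column contour vertex matrix in um.
#' @param pixelSize um per pixel.
#' @return Perimeter in um.
#' @export
chainPerimeter <- function(poly, pixelSize) {
  n <- nrow(poly)
  if (n < 2L) return(0)
  jn <- c(2:n, 1L)
  dx <- round(abs(poly[jn, 1] - poly[, 1]) / pixelSize)
  dy <- round(abs(poly[jn, 2] - poly[, 2]) / pixelSize)
  steps <- pmax(dx, dy)
  diag <- pmin(dx, dy)
  axial <- steps - diag
  sum(0.948 * axial + 1.340 * diag) * pixelSize
}

#' Add Gaussian-smoothed neighborhood features
#'
#' For each cell i and base feature f, the smoothed value is the
#' Gaussian-weighted average `sum_j w_ij f_j / sum_j w_ij` with
#' `w_ij = exp(-d_ij^2 / (2 sigma^2))`, `sigma = radius/2`, summed over all
#' cells within `2 * radius` of cell i (including cell i itself). Radius 0
#' returns the base values unchanged. New columns are named
#' `smoothed_<radius>um_<base>`.
#'
#' @param table feature data.frame from [computeCellFeatures()].
#' @param centroids two-column matrix of cell centroids in um (same row
#'   order as `table`).
#' @param radii numeric vector of smoothing radii in um (default
#'   `c(25, 50)`).
#' @param baseColumns columns to smooth; defaults to every numeric column
#'   except `id` and QC flags.
#' @return `table` with the smoothed columns appended.
#' @export
smoothFeatures <- function(table, centroids, radii = c(25, 50),
                           baseColumns = NULL) {
  if (any(radii < 0)) stop("negative smoothing radius", call. = FALSE)
  if (is.null(baseColumns)) {
    num <- vapply(table, is.numeric, TRUE)
    baseColumns <- setdiff(names(table)[num],
                           c("id", "qc_cytoplasm_fallback"))
    baseColumns <- baseColumns[!grepl("^smoothed_", baseColumns)]
  }
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == nrow(table))
  d2 <- as.matrix(stats::dist(centroids))^2
  for (r in radii) {
    if (r == 0) {
      W <- diag(nrow(table))
    } else {
      sigma <- r / 2
      W <- exp(-d2 / (2 * sigma^2))
      W[d2 > (2 * r)^2] <- 0
    }
    sw <- rowSums(W)
    for (cn in baseColumns) {
      table[[sprintf("smoothed_%gum_%s", r, cn)]] <-
        as.vector(W %*% table[[cn]]) / sw
    }
  }
  table
}

#' Write / read a feature table as CSV with a stable header
#' @param table feature data.frame. @param path file path.
#' @return `path` / the table.
#' @export
writeFeatureCSV <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
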