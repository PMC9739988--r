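# Per-cell measurements and Gaussian neighborhood smoothing.

# Build a minimal detection object by hand: one circular nucleus mask of
# uniform OD inside a slightly larger cell territory.
diskDetection <- function(odValue = 0.5, rPx = 10L, n = 40L, px = 0.5) {
  g <- seq_len(n) - n / 2
  X <- matrix(g, n, n); Y <- matrix(g, n, n, byrow = TRUE)
  nuc <- matrix(0L, n, n); nuc[X^2 + Y^2 <= rPx^2] <- 1L
  cell <- matrix(0L, n, n); cell[X^2 + Y^2 <= (rPx + 4)^2] <- 1L
  oc <- EBImage::ocontour(nuc)
  poly <- cbind(x_um = oc[[1]][, 1] * px, y_um = oc[[1]][, 2] * px)
  det <- data.frame(id = 1L, class = "UNCLASSIFIED",
                    centroid_x_um = (n / 2 - 1) * px,
                    centroid_y_um = (n / 2 - 1) * px,
                    nucleus_area_um2 = sum(nuc) * px^2,
                    cell_area_um2 = sum(cell) * px^2)
  det$nucleus_polygon <- list(poly)
  det$cell_polygon <- list(poly)
  attr(det, "nucleusLabels") <- nuc
  attr(det, "cellLabels") <- cell
  attr(det, "pixelSize") <- px
  list(det = det, hema = matrix(odValue, n, n), eosin = matrix(0.1, n, n))
}

test_that("a uniform disk yields exact intensity stats and high circularity", {
  d <- diskDetection(odValue = 0.5)
  ft <- computeCellFeatures(d$det, d$hema, d$eosin)
  expect_equal(ft$nucleus_hema_mean, 0.5)
  expect_equal(ft$nucleus_hema_std, 0)
  expect_equal(ft$cytoplasm_eosin_mean, 0.1)
  expect_gte(ft$nucleus_circularity, 0.95)
  expect_equal(ft$qc_cytoplasm_fallback, 0L)
})

test_that("square polygons reproduce the closed-form shape descriptors", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  s <- shapeDescriptors(sq)
  expect_equal(s[["area"]], 100)
  expect_equal(s[["perimeter"]], 40)
  expect_equal(s[["circularity"]], 4 * pi * 100 / 1600, tolerance = 1e-12)
  expect_equal(s[["eccentricity"]], 0, tolerance = 1e-9)
  expect_equal(s[["min_caliper"]], 10, tolerance = 0.02)
  expect_equal(s[["max_caliper"]], 10 * sqrt(2), tolerance = 0.02)
})

test_that("feature computation is deterministic and order invariant", {
  tile <- simulateTile(smallScene(seed = 23L))
  ch <- deconvolveStains(rgbToOD(tile$image, 255), defaultStainModel())
  det <- detectCells(ch[, , 1])
  f1 <- computeCellFeatures(det, ch[, , 1], ch[, , 2])
  f2 <- computeCellFeatures(det, ch[, , 1], ch[, , 2])
  expect_identical(f1, f2)
  expect_false(any(is.na(as.matrix(f1[vapply(f1, is.numeric, TRUE)]))))
})

test_that("neighborhood smoothing follows the two-point Gaussian formula", {
  tb <- data.frame(id = 1:2, f = c(0, 1))
  ctr <- rbind(c(0, 0), c(25, 0))
  out <- smoothFeatures(tb, ctr, radii = 25, baseColumns = "f")
  w <- exp(-2)                    # d = 25, sigma = 12.5 -> exp(-d^2/(2 s^2))
  expect_equal(out$smoothed_25um_f[1], w / (1 + w), tolerance = 1e-12)
  expect_equal(out$smoothed_25um_f[1], 0.1192, tolerance = 1e-4)
  # radius 0 is the identity
  out0 <- smoothFeatures(tb, ctr, radii = 0, baseColumns = "f")
  expect_equal(out0$smoothed_0um_f, tb$f)
  # constant fields are fixed points
  tbc <- data.frame(id = 1:5, f = rep(2.5, 5))
  ctrc <- cbind(runif(5, 0, 40), runif(5, 0, 40))
  outc <- smoothFeatures(tbc, ctrc, radii = 25, baseColumns = "f")
  expect_equal(outc$smoothed_25um_f, rep(2.5, 5))
  expect_error(smoothFeatures(tb, ctr, radii = -1), "negative")
})

test_that("smoothing is a convex combination and commutes with shifts", {
  set.seed(42)
  n <- 40
  tb <- data.frame(id = 1:n, f = rnorm(n))
  ctr <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  out <- smoothFeatures(tb, ctr, radii = c(25, 50), baseColumns = "f")
  for (cn in c("smoothed_25um_f", "smoothed_50um_f")) {
    expect_true(all(out[[cn]] >= min(tb$f) - 1e-12))
    expect_true(all(out[[cn]] <= max(tb$f) + 1e-12))
  }
  tb2 <- tb; tb2$f <- tb$f + 7
  out2 <- smoothFeatures(tb2, ctr, radii = 25, baseColumns = "f")
  expect_equal(out2$smoothed_25um_f, out$smoothed_25um_f + 7,
               tolerance = 1e-12)
})

test_that("feature tables round-trip through CSV", {
  tile <- simulateTile(smallScene(seed = 29L))
  ch <- deconvolveStains(rgbToOD(tile$image, 255), defaultStainModel())
  det <- detectCells(ch[, , 1])
  ft <- smoothFeatures(computeCellFeatures(det, ch[, , 1], ch[, , 2]),
                       cbind(det$centroid_x_um, det$centroid_y_um))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeFeatureCSV(ft, f)
  back <- readFeatureCSV(f)
  expect_identical(names(back), names(ft))
  num <- vapply(ft, is.numeric, TRUE)
  expect_equal(as.matrix(back[num]), as.matrix(ft[num]), tolerance = 1e-9,
               ignore_attr = TRUE)
})
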