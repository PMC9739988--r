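# Resampling geometry and watershed cell detection on synthetic tiles.

test_that("area-weighted resampling preserves geometry and means", {
  img <- matrix(runif(1000 * 1000), 1000, 1000)
  half <- resampleToWorkingResolution(img, 0.25, 0.5)
  expect_equal(dim(half), c(500, 500))
  expect_equal(mean(half), mean(img), tolerance = 1e-12)
  # identity when pixel sizes agree
  expect_identical(resampleToWorkingResolution(img, 0.5, 0.5), img)
  # constant image stays constant at any resampling factor
  const <- matrix(3.25, 130, 70)
  out <- resampleToWorkingResolution(const, 0.4, 0.5)
  expect_equal(dim(out), c(104, 56))
  expect_equal(range(out), c(3.25, 3.25), tolerance = 1e-12)
  expect_warning(resampleToWorkingResolution(const, 2, 0.25), "upsampling")
})

test_that("nuclei are detected with accurate centroids and areas", {
  mono <- lapply(defaultMorphology(), function(m) {
    m$area <- c(45, 55); m$peakOD <- c(0.8, 0.8); m
  })
  spec <- SceneSpec(tileSize = 200, morphology = mono,
                    counts = c(TUMOR = 7L, IMMUNE = 7L, STROMA = 6L),
                    seed = 21L)
  tile <- simulateTile(spec)
  ch <- deconvolveStains(rgbToOD(tile$image, 255), defaultStainModel())
  det <- detectCells(ch[, , 1])
  expect_equal(nrow(det), 20)
  m <- matchDetections(det, tile$truth, maxDist = 5)
  expect_equal(m$recall, 1)
  expect_true(all(m$dist < 1))
  relErr <- abs(det$nucleus_area_um2[m$matchedDet] -
                  tile$truth$area_um2[m$matchedTruth]) /
    tile$truth$area_um2[m$matchedTruth]
  expect_true(all(relErr <= 0.2))
})

test_that("the nucleus area filter rejects blobs outside 10-400 um^2", {
  mkBlob <- function(areaUm2, n = 160, px = 0.5) {
    r <- sqrt(areaUm2 / pi)
    g <- ((seq_len(n) - 1) - n / 2) * px
    X <- matrix(g, n, n); Y <- matrix(g, n, n, byrow = TRUE)
    r2 <- (X^2 + Y^2) / r^2
    0.8 * pmax(1 - r2, 0)
  }
  # flat background: probe the area filter in isolation with a light blur
  p <- DetectionParams(backgroundRadius = 0, sigma = 0.5)
  expect_equal(nrow(detectCells(mkBlob(5), p)), 0)     # below minimum area
  expect_equal(nrow(detectCells(mkBlob(500), p)), 0)   # above maximum area
  expect_equal(nrow(detectCells(mkBlob(50), p)), 1)    # sanity: in range
  # and no detection ever falls outside the configured range
  tile <- simulateTile(smallScene(seed = 31L))
  ch <- deconvolveStains(rgbToOD(tile$image, 255), defaultStainModel())
  det <- detectCells(ch[, , 1])
  expect_true(all(det$nucleus_area_um2 >= 10 & det$nucleus_area_um2 <= 400))
})

test_that("detection is translation equivariant", {
  tile <- simulateTile(smallScene(seed = 13L))
  ch <- deconvolveStains(rgbToOD(tile$image, 255), defaultStainModel())
  hema <- ch[, , 1]
  dx <- 6L; dy <- 4L                                # pixels
  shifted <- matrix(0, nrow(hema), ncol(hema))
  shifted[(dx + 1):nrow(hema), (dy + 1):ncol(hema)] <-
    hema[1:(nrow(hema) - dx), 1:(ncol(hema) - dy)]
  d1 <- detectCells(hema)
  d2 <- detectCells(shifted)
  expect_equal(nrow(d1), nrow(d2))
  px <- 0.5
  m <- matchDetections(
    d2, data.frame(centroid_x_um = d1$centroid_x_um + dx * px,
                   centroid_y_um = d1$centroid_y_um + dy * px))
  expect_equal(m$recall, 1)
  expect_true(all(m$dist <= px))
})

test_that("cell territories never overlap and stay near their nuclei", {
  tile <- simulateTile(smallScene(seed = 17L))
  ch <- deconvolveStains(rgbToOD(tile$image, 255), defaultStainModel())
  det <- detectCells(ch[, , 1])
  cellLab <- attr(det, "cellLabels")
  nucLab <- attr(det, "nucleusLabels")
  # every nucleus pixel belongs to the same cell label (nucleus within cell)
  nz <- which(nucLab > 0L)
  expect_true(all(cellLab[nz] == nucLab[nz]))
  expect_true(all(det$cell_area_um2 >= det$nucleus_area_um2))
  # expansion is bounded by the configured 5 um
  d <- EBImage::distmap(nucLab == 0L)
  expect_true(all(d[cellLab > 0L] <= 5 / 0.5 + 1))
})

test_that("detections are confined to the region of interest", {
  tile <- simulateTile(smallScene(seed = 19L))
  ch <- deconvolveStains(rgbToOD(tile$image, 255), defaultStainModel())
  roi <- cbind(c(0, 60, 60, 0), c(0, 0, 120, 120))  # left half, um
  det <- detectCells(ch[, , 1], roi = roi)
  full <- detectCells(ch[, , 1])
  expect_lt(nrow(det), nrow(full))
  expect_true(all(det$centroid_x_um <= 61))
  expect_error(detectCells(ch[, , 1], roi = cbind(0, 0)), "roi")
  neg <- ch[, , 1]; neg[1, 1] <- -0.2
  expect_error(detectCells(neg), "OD units")
})

test_that("counts and areas aggregate correctly", {
  roi <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  det <- data.frame(class = c("TUMOR", "TUMOR", "TUMOR", "IMMUNE", "IMMUNE"))
  ca <- countAndArea(det, roi)
  expect_equal(ca$counts[["TUMOR"]], 3L)
  expect_equal(ca$counts[["IMMUNE"]], 2L)
  expect_equal(ca$area_mm2, 1.0)
  empty <- countAndArea(data.frame(class = character()), roi)
  expect_true(all(empty$counts == 0L))
  expect_equal(empty$area_mm2, 1.0)
})
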