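# Optical-density conversion, stain-vector estimation and deconvolution.

test_that("rgbToOD follows the clamped Beer-Lambert identities", {
  mk <- function(val) array(val, c(2, 2, 3))
  # background intensity gives zero absorbance
  expect_equal(max(abs(odValues(rgbToOD(mk(255), 255)))), 0)
  # one decade of attenuation gives OD 1
  expect_equal(odValues(rgbToOD(mk(25.5), 255))[1, 1, 1], 1.0)
  # fully opaque pixels hit the I >= 1 clamp
  expect_equal(odValues(rgbToOD(mk(0), 255))[1, 1, 1], log10(255),
               tolerance = 1e-12)
  expect_error(rgbToOD(mk(10), background = 0), "positive")
})

test_that("OD is monotonically decreasing in intensity per channel", {
  vals <- seq(0, 255, length.out = 64)
  img <- array(rep(vals, 3), c(64, 1, 3))
  od <- odValues(rgbToOD(img, 255))
  for (k in 1:3) expect_true(all(diff(od[, 1, k]) <= 0))
})

test_that("deconvolution is exact on pure stains and round-trips", {
  mod <- defaultStainModel()
  # pure hematoxylin pixel
  od <- new("ODImage", values = array(0.7 * mod@hematoxylin, c(1, 1, 3)),
            pixelSize = 0.5)
  ch <- deconvolveStains(od, mod)
  expect_equal(as.numeric(ch[1, 1, ]), c(0.7, 0, 0), tolerance = 1e-9)
  # zero OD pixel
  od0 <- new("ODImage", values = array(0, c(1, 1, 3)), pixelSize = 0.5)
  expect_equal(as.numeric(deconvolveStains(od0, mod)[1, 1, ]), c(0, 0, 0))
  # random non-negative H/E concentrations round-trip through compose
  # (the residual direction has negative OD components, so only the
  # physical H+E subspace composes to a valid absorbance image)
  set.seed(11)
  for (rep in 1:5) {
    conc <- array(runif(3 * 60, 0, 1.5), c(10, 2, 3))
    conc[, , 3] <- 0
    rt <- deconvolveStains(composeStains(conc, mod), mod)
    expect_equal(as.vector(rt), as.vector(conc), tolerance = 1e-6)
    # full 3-channel unmixing identity, checked at the matrix level
    M <- stainMatrix(mod)
    cc <- matrix(runif(30, 0, 1), 3, 10)
    expect_equal(solve(M, M %*% cc), cc, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("stain vectors are recovered from rendered mixtures", {
  mod <- defaultStainModel()
  set.seed(1)
  conc <- array(0, c(40, 40, 3))
  conc[, , 1] <- runif(1600, 0, 1)
  conc[, , 2] <- runif(1600, 0, 1)
  img <- odToRGB(composeStains(conc, mod))
  # noise-free render: within 2 degrees
  fit <- estimateStainVectors(rgbToOD(img, 255))
  expect_lt(angleBetween(fit@hematoxylin, mod@hematoxylin), 2)
  expect_lt(angleBetween(fit@eosin, mod@eosin), 2)
  # Gaussian intensity noise sigma = 2: within 5 degrees
  imgN <- img + array(rnorm(length(img), 0, 2), dim(img))
  imgN <- pmin(pmax(imgN, 0), 255)
  fitN <- estimateStainVectors(rgbToOD(imgN, 255))
  expect_lt(angleBetween(fitN@hematoxylin, mod@hematoxylin), 5)
  expect_lt(angleBetween(fitN@eosin, mod@eosin), 5)
})

test_that("degenerate inputs are rejected with informative errors", {
  # uniform background: no foreground pixels
  blank <- rgbToOD(array(255, c(30, 30, 3)), 255)
  expect_error(estimateStainVectors(blank), "foreground")
  # rank-1 cloud: a single stain everywhere
  mod <- defaultStainModel()
  conc <- array(0, c(30, 30, 3))
  conc[, , 1] <- runif(900, 0.3, 1)
  odr1 <- composeStains(conc, mod)
  expect_error(estimateStainVectors(odr1), "single stain|rank")
})

test_that("estimated directions are scale invariant", {
  mod <- defaultStainModel()
  set.seed(5)
  conc <- array(runif(3 * 500, 0, 1), c(25, 20, 3))
  conc[, , 3] <- 0
  od1 <- composeStains(conc, mod)
  od2 <- new("ODImage", values = od1@values * 3.7, pixelSize = 0.5)
  f1 <- estimateStainVectors(od1, odMin = 0.05)
  f2 <- estimateStainVectors(od2, odMin = 0.05 * 3.7)
  expect_lt(angleBetween(f1@hematoxylin, f2@hematoxylin) * pi / 180, 1e-6)
  expect_lt(angleBetween(f1@eosin, f2@eosin) * pi / 180, 1e-6)
})

test_that("stain models enforce their invariants and serialize losslessly", {
  expect_error(new("StainModel", hematoxylin = c(1, 0, 0), eosin = c(1, 0, 0),
                   residual = c(0, 0, 1), background = rep(255, 3)),
               "collinear")
  mod <- defaultStainModel()
  expect_equal(sum(mod@residual * mod@hematoxylin), 0, tolerance = 1e-9)
  f <- withr::local_tempfile(fileext = ".json")
  writeStainModel(mod, f)
  back <- readStainModel(f)
  expect_equal(back@hematoxylin, mod@hematoxylin, tolerance = 1e-12)
  expect_equal(back@eosin, mod@eosin, tolerance = 1e-12)
  expect_equal(back@background, mod@background)
})
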