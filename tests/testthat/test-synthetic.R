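# Synthetic tile and cohort generators: determinism, conservation and
# statistical calibration.

test_that("tile generation is a pure function of spec and seed", {
  spec <- smallScene(seed = 41L)
  t1 <- simulateTile(spec)
  t2 <- simulateTile(spec)
  expect_identical(t1$image, t2$image)
  expect_identical(t1$truth, t2$truth)
  # a different seed changes the scene
  t3 <- simulateTile(smallScene(seed = 42L))
  expect_false(identical(t1$image, t3$image))
  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulateTile(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("truth tables conserve requested counts and morphology ranges", {
  spec <- smallScene(seed = 43L)
  tile <- simulateTile(spec)
  tab <- table(tile$truth$class)
  for (cl in names(spec@counts))
    expect_equal(unname(tab[[cl]]), unname(spec@counts[[cl]]))
  mo <- spec@morphology
  for (i in seq_len(nrow(tile$truth))) {
    cl <- tile$truth$class[i]
    expect_gte(tile$truth$area_um2[i], mo[[cl]]$area[1])
    expect_lte(tile$truth$area_um2[i], mo[[cl]]$area[2])
    # the stored polygon is consistent with the analytic ellipse area
    expect_equal(polygonArea(tile$truth$polygon[[i]]),
                 tile$truth$area_um2[i], tolerance = 0.05)
  }
  # minimum separation is honored
  d <- as.matrix(dist(cbind(tile$truth$centroid_x_um,
                            tile$truth$centroid_y_um)))
  diag(d) <- Inf
  expect_gte(min(d), spec@minSeparation)
})

test_that("an empty scene renders pure background", {
  spec <- smallScene(counts = c(TUMOR = 0L, IMMUNE = 0L, STROMA = 0L),
                     noiseSd = 0)
  tile <- simulateTile(spec)
  expect_equal(nrow(tile$truth), 0)
  # only the faint uniform eosin background remains
  expect_equal(max(odValues(tile$od)[, , 1]) -
                 min(odValues(tile$od)[, , 1]), 0, tolerance = 1e-12)
})

test_that("impossible packing is reported", {
  spec <- smallScene(counts = c(TUMOR = 200L, IMMUNE = 0L, STROMA = 0L),
                     tileSize = 60, minSeparation = 16)
  expect_error(simulateTile(spec), "packing")
})

test_that("cohort generation hits the requested censoring rate", {
  coh <- simulateCohort(CohortSpec(n = 5000, censoringRate = 0.4,
                                   seed = 11L))
  expect_equal(mean(coh$event), 0.6, tolerance = 0.03)
  cohNC <- simulateCohort(CohortSpec(n = 500, censoringRate = 0,
                                     seed = 11L))
  expect_true(all(cohNC$event == 1L))
})

test_that("the TILs score marginal matches the specified mixture", {
  spec <- CohortSpec(n = 2000, seed = 13L)
  coh <- simulateCohort(spec)
  mixCDF <- function(q) 0.5 * pnorm(q, 8, 2) + 0.5 * pnorm(q, 20, 4)
  ks <- suppressWarnings(ks.test(coh$eTILs_pct, mixCDF))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(coh$eTILs_pct >= 0 & coh$eTILs_pct <= 100))
})

test_that("a null hazard ratio produces a null log-rank distribution", {
  pvals <- vapply(1:40, function(i) {
    coh <- simulateCohort(CohortSpec(n = 200, hr = 1, censoringRate = 0.3,
                                     seed = 600L + i))
    hi <- coh$tils_high == 1L
    logrankTest(coh$time_months[hi], coh$event[hi],
                coh$time_months[!hi], coh$event[!hi])$p_value
  }, 0)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("fixture tiles reproduce each patient's TILs value", {
  fx <- simulateFixture(
    CohortSpec(n = 20, seed = 5L),
    sceneTemplate = SceneSpec(tileSize = 150,
                              counts = c(TUMOR = 12L, IMMUNE = 4L,
                                         STROMA = 6L)),
    patients = 1:4)
  expect_equal(nrow(fx$cohort), 20)
  expect_length(fx$tiles, 4)
  for (tile in fx$tiles) {
    cohortVal <- fx$cohort$eTILs_pct[tile$patient]
    tab <- table(factor(tile$truth$class,
                        levels = c("TUMOR", "IMMUNE", "STROMA")))
    tileVal <- 100 * tab[["IMMUNE"]] / (tab[["IMMUNE"]] + tab[["TUMOR"]])
    expect_equal(tileVal, tile$true_eTILs_pct)
    # rounding to 16 epithelial cells bounds the discrepancy
    expect_lte(abs(tileVal - cohortVal), 100 / 16 / 2 + 1e-9)
  }
  # regeneration with identical specs is bit-identical
  fx2 <- simulateFixture(
    CohortSpec(n = 20, seed = 5L),
    sceneTemplate = SceneSpec(tileSize = 150,
                              counts = c(TUMOR = 12L, IMMUNE = 4L,
                                         STROMA = 6L)),
    patients = 1:4)
  expect_identical(fx$tiles[[2]]$image, fx2$tiles[[2]]$image)
  expect_identical(fx$cohort, fx2$cohort)
})

test_that("fixture export writes readable plain-text artifacts", {
  dir <- tempfile("fixture_")
  on.exit(unlink(dir, recursive = TRUE))
  fx <- simulateFixture(CohortSpec(n = 20, seed = 6L),
                        sceneTemplate = smallScene(),
                        patients = 1L, outDir = dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "patient_001_tile.png")))
  img <- readTileImage(file.path(dir, "patient_001_tile.png"))
  expect_equal(dim(img), dim(fx$tiles[[1]]$image))
  # 8-bit PNG quantization: intensities agree to half a gray level
  expect_lt(max(abs(img - fx$tiles[[1]]$image)), 0.51)
})
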