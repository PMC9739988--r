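# Kaplan-Meier estimation and the Cox partial-likelihood fitter.

test_that("Kaplan-Meier reproduces textbook product-limit tables", {
  km <- kaplanMeier(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(0.5, 0))
  # all censored: estimate stays at 1 (no event rows)
  expect_equal(nrow(kaplanMeier(c(3, 5, 7), c(0, 0, 0))), 0)
  # hand-computed 5-subject mixed-censoring table:
  # t=1 event (n=5), t=2 censored, t=3 event (n=3), t=4 event (n=2),
  # t=5 censored
  km5 <- kaplanMeier(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  expect_equal(km5$time, c(1, 3, 4))
  expect_equal(km5$n_risk, c(5, 3, 2))
  expect_equal(km5$survival, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2),
               tolerance = 1e-12)
  expect_true(all(diff(km5$survival) <= 0))
  expect_true(all(km5$lower <= km5$survival & km5$survival <= km5$upper))
})

test_that("without censoring the KM estimate is the empirical survivor", {
  set.seed(31)
  t <- sort(sample(1:50, 25, replace = FALSE))
  km <- kaplanMeier(t, rep(1, 25))
  emp <- vapply(km$time, function(t0) mean(t > t0), 0)
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("Cox coefficients match the survival package with and without ties", {
  skip_if_not_installed("survival")
  set.seed(99)
  for (i in 1:20) {
    n <- 150
    tm <- rexp(n, 0.05)
    if (i %% 2) tm <- round(tm) + 0.5          # tied event times
    e <- rbinom(n, 1, 0.7)
    df <- data.frame(time_months = tm, event = e,
                     a = rnorm(n), b = rbinom(n, 1, 0.4))
    mine <- coxFit(df, c("a", "b"))
    ref <- survival::coxph(survival::Surv(time_months, event) ~ a + b, df,
                           ties = "efron")
    expect_equal(unname(mine@table$coef), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(mine@table$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(mine@loglik[2], ref$loglik[2], tolerance = 1e-6)
    # Breslow tie handling agrees too
    mineB <- coxFit(df, c("a", "b"), ties = "breslow")
    refB <- survival::coxph(survival::Surv(time_months, event) ~ a + b, df,
                            ties = "breslow")
    expect_equal(unname(mineB@table$coef), unname(coef(refB)),
                 tolerance = 1e-6)
  }
})

test_that("a large two-group cohort recovers its true hazard ratio", {
  coh <- simulateCohort(CohortSpec(n = 2000, hr = 0.333,
                                   censoringRate = 0.4, seed = 77L))
  fit <- coxFit(coh, "tils_high")
  expect_gte(fit@table$hr, 0.28)
  expect_lte(fit@table$hr, 0.40)
  expect_lte(fit@table$lower, fit@table$hr)
  expect_gte(fit@table$upper, fit@table$hr)
})

test_that("degenerate covariates are rejected by name", {
  coh <- simulateCohort(CohortSpec(n = 100, seed = 3L))
  coh$flat <- 1
  expect_error(coxFit(coh, "flat"), "zero-variance.*flat")
  expect_error(coxFit(coh, "nope"), "not found")
})

test_that("Cox estimates are centering invariant and scaling equivariant", {
  coh <- simulateCohort(CohortSpec(n = 300, seed = 9L))
  coh$x <- rnorm(300) + 0.1 * coh$tils_high
  f0 <- coxFit(coh, "x")
  cohC <- coh; cohC$x <- coh$x - 5
  fC <- coxFit(cohC, "x")
  expect_equal(fC@table$coef, f0@table$coef, tolerance = 1e-7)
  cohS <- coh; cohS$x <- coh$x * 4
  fS <- coxFit(cohS, "x")
  expect_equal(fS@table$coef, f0@table$coef / 4, tolerance = 1e-7)
})

test_that("dichotomization inside coxFit matches manual preprocessing", {
  coh <- simulateCohort(CohortSpec(n = 400, seed = 15L))
  fit <- coxFit(coh, "eTILs_pct",
                dichotomize = list(variable = "eTILs_pct", threshold = 13.2))
  manual <- coh
  manual$grp <- as.integer(coh$eTILs_pct >= 13.2)
  ref <- coxFit(manual, "grp")
  expect_equal(fit@table$coef, ref@table$coef, tolerance = 1e-10)
})

test_that("the prognostic-table models are composed correctly", {
  coh <- simulateCohort(CohortSpec(n = 400, hr = 0.345, censoringRate = 0.35,
                                   covariateLogHR = c(age70 = 0.59,
                                                      stage34 = 0.34,
                                                      lvi = 0.31),
                                   seed = 19L))
  res <- suppressMessages(runTable2Models(coh))
  expect_named(res, c("univariate", "multivariate"))
  # one univariate fit per prognostic factor present in the cohort
  expect_setequal(names(res$univariate),
                  c("age:>=70", "sex:male", "pT:3-4", "pN:2-3", "pM:1",
                    "stage:III-IV", "lvi:yes", "tils:high"))
  # the univariate TILs fit equals coxFit called directly
  direct <- coxFit(coh, "eTILs_pct",
                   dichotomize = list(variable = "eTILs_pct",
                                      threshold = 13.2))
  expect_equal(res$univariate$`tils:high`@table$coef, direct@table$coef,
               tolerance = 1e-10)
  # multivariate model covers the adjusted factor set, one row each
  expect_setequal(res$multivariate@table$term,
                  c("age:>=70", "pT:3-4", "pN:2-3", "stage:III-IV",
                    "lvi:yes", "tils:high"))
  # the TILs effect survives adjustment in this TILs-driven cohort
  tb <- res$multivariate@table
  expect_lt(tb$p[tb$term == "tils:high"], 0.05)
})

test_that("complete-case handling drops rows with missing LVI", {
  coh <- simulateCohort(CohortSpec(n = 300, seed = 23L))
  coh$lvi[1:60] <- NA
  expect_message(fit <- coxFit(coh, "lvi"), "60 rows dropped")
  expect_equal(fit@n, 240L)
})
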