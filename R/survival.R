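# Kaplan-Meier estimation and Cox proportional-hazards regression.
#
# The Cox fitter maximizes the partial likelihood by Newton-Raphson with
# Efron's tie correction (Breslow available), iterating until the gradient
# norm drops below 1e-8.

#' Kaplan-Meier product-limit estimate with Greenwood 95% CIs
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (0 = right-censored).
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `survival`, `se` (Greenwood), `lower`, `upper`.
#'   Survival starts at 1 and is non-increasing. With no events the
#'   estimate is 1 everywhere (empty frame).
#' @examples
#' kaplanMeier(c(1, 2), c(1, 1))
#' @export
kaplanMeier <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  ord <- order(times)
  t <- times[ord]; e <- events[ord] != 0
  ut <- unique(t[e])
  if (!length(ut))
    return(data.frame(time = numeric(), n_risk = numeric(),
                      n_event = numeric(), survival = numeric(),
                      se = numeric(), lower = numeric(), upper = numeric()))
  nRisk <- vapply(ut, function(t0) sum(t >= t0), 0)
  nEvent <- vapply(ut, function(t0) sum(e & t == t0), 0)
  surv <- cumprod(1 - nEvent / nRisk)
  gw <- cumsum(nEvent / (nRisk * pmax(nRisk - nEvent, 1e-12)))
  se <- surv * sqrt(gw)
  data.frame(time = ut, n_risk = nRisk, n_event = nEvent, survival = surv,
             se = se,
             lower = pmax(surv - 1.96 * se, 0),
             upper = pmin(surv + 1.96 * se, 1))
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximization by Newton-Raphson (Efron tie handling by
#' default, Breslow optional) with Wald confidence intervals and p-values.
#' Character/factor covariates are expanded against their first (reference)
#' level; rows with missing values in any used column are dropped
#' complete-case with a message (no imputation).
#'
#' @param data data.frame holding the survival columns and covariates.
#' @param covariates character vector of covariate column names.
#' @param time,event names of the follow-up time (months) and 0/1 event
#'   columns.
#' @param dichotomize optional `list(variable = <column>, threshold = <x>)`:
#'   the named continuous column is replaced by its [applyCutpoint()]
#'   dichotomization (high vs low) before fitting.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A [CoxResult-class].
#' @export
coxFit <- function(data, covariates, time = "time_months", event = "event",
                   dichotomize = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(time %in% names(data), event %in% names(data))
  missingCov <- setdiff(covariates, names(data))
  if (length(missingCov))
    stop("covariate column not found: ", paste(missingCov, collapse = ", "),
         call. = FALSE)
  df <- data
  if (!is.null(dichotomize)) {
    v <- dichotomize$variable
    stopifnot(v %in% names(df))
    nm <- paste0(v, "_high")
    df[[nm]] <- as.integer(applyCutpoint(df[[v]],
                                         dichotomize$threshold) == "high")
    covariates <- c(setdiff(covariates, v), nm)
  }
  used <- c(time, event, covariates)
  cc <- stats::complete.cases(df[, used, drop = FALSE])
  if (any(!cc))
    message(sum(!cc), " rows dropped for missing covariate values")
  df <- df[cc, , drop = FALSE]
  X <- .coxModelMatrix(df, covariates)
  tvec <- df[[time]]; evec <- as.integer(df[[event]] != 0)
  if (any(tvec <= 0)) stop("times must be > 0", call. = FALSE)
  if (sum(evec) < 10L)
    stop("fewer than 10 events", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12))
    stop("zero-variance covariate: ",
         paste(colnames(X)[sds < 1e-12], collapse = ", "), call. = FALSE)
  fit <- .coxNewton(tvec, evec, X, ties)
  se <- sqrt(diag(fit$var))
  z <- fit$coef / se
  tab <- data.frame(term = colnames(X), coef = fit$coef, se = se,
                    hr = exp(fit$coef),
                    lower = exp(fit$coef - 1.96 * se),
                    upper = exp(fit$coef + 1.96 * se),
                    z = z, p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("CoxResult", table = tab, loglik = fit$loglik,
      n = nrow(X), nEvents = sum(evec), ties = ties)
}

.coxModelMatrix <- function(df, covariates) {
  cols <- list()
  for (cv in covariates) {
    x <- df[[cv]]
    if (is.numeric(x)) {
      cols[[cv]] <- as.numeric(x)
    } else {
      f <- if (is.factor(x)) x else factor(x)
      for (lv in levels(f)[-1])
        cols[[paste0(cv, ":", lv)]] <- as.numeric(f == lv)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# Newton-Raphson maximization of the Cox partial likelihood. Risk-set sums
# are reverse cumulative sums over the ascending time sort; tied event
# blocks get Efron's fractional downweighting of the tied subjects.
.coxNewton <- function(time, event, X, ties = "efron", maxIter = 100L,
                       tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  r <- rle(time)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nBlocks <- length(starts)
  beta <- numeric(p)

  hasTiedEvents <- any(vapply(seq_len(nBlocks), function(k)
    sum(event[starts[k]:ends[k]]) > 1L, TRUE))
  evIdx <- which(event == 1L)

  evalAt <- function(beta) {
    eta <- as.vector(X %*% beta)
    w <- exp(eta)
    wX <- X * w
    rs0 <- rev(cumsum(rev(w)))
    rs1 <- apply(wX, 2, function(cl) rev(cumsum(rev(cl))))
    if (p == 1L) rs1 <- matrix(rs1, ncol = 1L)
    pairIdx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    rs2f <- apply(pairIdx, 1, function(ab)
      rev(cumsum(rev(wX[, ab[1]] * X[, ab[2]]))))
    if (nrow(pairIdx) == 1L) rs2f <- matrix(rs2f, ncol = 1L)
    getS2 <- function(i) {
      S2 <- matrix(0, p, p)
      S2[pairIdx] <- rs2f[i, ]
      S2[pairIdx[, c(2, 1), drop = FALSE]] <- rs2f[i, ]
      S2
    }
    if (!hasTiedEvents) {
      # untied fast path (Efron == Breslow): fully vectorized over events
      S0 <- rs0[evIdx]
      S1 <- rs1[evIdx, , drop = FALSE]
      psi <- S1 / S0
      ll <- sum(eta[evIdx]) - sum(log(S0))
      U <- colSums(X[evIdx, , drop = FALSE]) - colSums(psi)
      I <- matrix(0, p, p)
      sumS2 <- colSums(rs2f[evIdx, , drop = FALSE] / S0)
      I[pairIdx] <- sumS2
      I[pairIdx[, c(2, 1), drop = FALSE]] <- sumS2
      I <- I - crossprod(psi)
      return(list(ll = ll, U = U, I = I))
    }
    ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
    for (k in seq_len(nBlocks)) {
      bl <- starts[k]:ends[k]
      dIdx <- bl[event[bl] == 1L]
      d <- length(dIdx)
      if (!d) next
      f <- starts[k]
      S0 <- rs0[f]; S1 <- rs1[f, ]; S2 <- getS2(f)
      wD <- w[dIdx]
      s0D <- sum(wD)
      s1D <- colSums(X[dIdx, , drop = FALSE] * wD)
      XD <- X[dIdx, , drop = FALSE]
      s2D <- crossprod(XD * wD, XD)
      ll <- ll + sum(eta[dIdx])
      U <- U + colSums(XD)
      fr <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
      for (l in seq_len(d)) {
        phi <- S0 - fr[l] * s0D
        psi <- (S1 - fr[l] * s1D) / phi
        Sig <- (S2 - fr[l] * s2D) / phi
        ll <- ll - log(phi)
        U <- U - psi
        I <- I + Sig - outer(psi, psi)
      }
    }
    list(ll = ll, U = U, I = I)
  }

  ev <- evalAt(beta)
  ll0 <- ev$ll
  for (it in seq_len(maxIter)) {
    if (sqrt(sum(ev$U^2)) < tol)
      return(list(coef = stats::setNames(beta, colnames(X)),
                  var = solve(ev$I), loglik = c(ll0, ev$ll),
                  iter = it - 1L, info = ev$I))
    step <- solve(ev$I, ev$U)
    # step halving to guarantee ascent
    for (h in 0:20) {
      cand <- beta + step / 2^h
      evC <- evalAt(cand)
      if (evC$ll >= ev$ll - 1e-12) break
    }
    beta <- cand; ev <- evC
  }
  stop("Cox fit did not converge in ", maxIter, " iterations", call. = FALSE)
}

#' Univariate and multivariate Cox models for the standard prognostic table
#'
#' Fits one univariate Cox model per available prognostic factor — age
#' (>= 70 vs < 70), sex (male vs female), pT (pT3-4 vs pT1-2), pN (pN2-3 vs
#' pN0-1), pM (pM1 vs pM0), pTNM stage (III-IV vs II), lymphovascular
#' invasion (yes vs no) and the dichotomized TILs variable (high vs low) —
#' and one multivariate model over the subset {age, pT, pN, pTNM stage,
#' LVI, TILs} of factors present in the cohort. Rows with missing values
#' are dropped complete-case per model. A message is emitted when the
#' multivariate information matrix is ill-conditioned (collinear stage
#' covariates).
#'
#' @param cohort data.frame with `time_months`, `event` and any of the
#'   columns `age_years` (or binary `age70`), `sex`, `pT`, `pN`, `pM`,
#'   `pTNM` (or binary `stage34`), `lvi`, and the TILs column.
#' @param tilsVariable continuous TILs column name (default `eTILs_pct`).
#' @param threshold TILs dichotomization cut-point (default 13.2).
#' @param ties tie handling, see [coxFit()].
#' @param univariate set `FALSE` to fit only the multivariate model.
#' @return List with `univariate` (named list of [CoxResult-class]) and
#'   `multivariate` (one [CoxResult-class]).
#' @export
runTable2Models <- function(cohort, tilsVariable = "eTILs_pct",
                            threshold = 13.2, ties = "efron",
                            univariate = TRUE) {
  df <- cohort
  der <- character()
  if ("age70" %in% names(df)) {
    df$`age:>=70` <- as.numeric(df$age70); der <- c(der, "age:>=70")
  } else if ("age_years" %in% names(df)) {
    df$`age:>=70` <- as.numeric(df$age_years >= 70); der <- c(der, "age:>=70")
  }
  if ("sex" %in% names(df)) {
    df$`sex:male` <- as.numeric(df$sex == "male"); der <- c(der, "sex:male")
  }
  if ("pT" %in% names(df)) {
    df$`pT:3-4` <- as.numeric(df$pT %in% c("pT3", "pT4"))
    der <- c(der, "pT:3-4")
  }
  if ("pN" %in% names(df)) {
    df$`pN:2-3` <- as.numeric(df$pN %in% c("pN2", "pN3"))
    der <- c(der, "pN:2-3")
  }
  if ("pM" %in% names(df)) {
    df$`pM:1` <- as.numeric(df$pM == "pM1"); der <- c(der, "pM:1")
  }
  if ("stage34" %in% names(df)) {
    df$`stage:III-IV` <- as.numeric(df$stage34); der <- c(der, "stage:III-IV")
  } else if ("pTNM" %in% names(df)) {
    df$`stage:III-IV` <- as.numeric(df$pTNM %in% c("III-IV", "III", "IV"))
    der <- c(der, "stage:III-IV")
  }
  if ("lvi" %in% names(df)) {
    df$`lvi:yes` <- as.numeric(df$lvi); der <- c(der, "lvi:yes")
  }
  stopifnot(tilsVariable %in% names(df))
  df$`tils:high` <- as.numeric(applyCutpoint(df[[tilsVariable]],
                                             threshold) == "high")
  der <- c(der, "tils:high")

  uni <- if (univariate) {
    u <- lapply(der, function(cv) coxFit(df, cv, ties = ties))
    names(u) <- der
    u
  } else list()
  multiSet <- intersect(c("age:>=70", "pT:3-4", "pN:2-3", "stage:III-IV",
                          "lvi:yes", "tils:high"), der)
  multi <- coxFit(df, multiSet, ties = ties)
  # collinearity diagnostic on the standardized covariates
  Xm <- as.matrix(df[stats::complete.cases(df[, multiSet, drop = FALSE]),
                     multiSet, drop = FALSE])
  kp <- kappa(stats::cor(Xm), exact = TRUE)
  if (is.finite(kp) && kp > 100)
    message(sprintf("multivariate covariates are ill-conditioned (condition number %.3g)", kp))
  list(univariate = uni, multivariate = multi)
}
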