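# Maximally selected log-rank dichotomization of a continuous TILs score:
# scan every admissible midpoint between consecutive sorted values, compute
# the two-group log-rank chi-square at each, keep the maximizer, and correct
# the selected p-value for the multiplicity of the scan (Miller-Siegmund
# approximation, or a seeded permutation null).

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time, the observed number of
#' events in group A minus its hypergeometric expectation given the risk
#' sets, with the variance summed across event times;
#' `chi-square = (sum(O - E))^2 / sum(V)`, referred to a chi-square
#' distribution with 1 df.
#'
#' @param timesA,timesB positive follow-up times of the two groups.
#' @param eventsA,eventsB 0/1 event indicators (1 = event, 0 = censored).
#' @return List with `chi_square`, `p_value`, `observed` and `expected`
#'   events in group A.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  stopifnot(length(timesA) == length(eventsA),
            length(timesB) == length(eventsB))
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB) != 0
  group <- rep(c(TRUE, FALSE), c(length(timesA), length(timesB)))
  if (!any(event))
    stop("log-rank statistic undefined: no events", call. = FALSE)
  if (any(time <= 0)) stop("times must be > 0", call. = FALSE)
  st <- .logrankStat(time, event, group)
  list(chi_square = st[["chi_square"]],
       p_value = stats::pchisq(st[["chi_square"]], 1, lower.tail = FALSE),
       observed = st[["observed"]], expected = st[["expected"]])
}

# Core statistic; `group` marks membership of group A. O(n) after the time
# sort: tied blocks of times are collapsed with cumulative sums.
.logrankStat <- function(time, event, group, sorted = FALSE) {
  if (!sorted) {
    ord <- order(time)
    time <- time[ord]; event <- event[ord]; group <- group[ord]
  }
  n <- length(time)
  r <- rle(time)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ce <- cumsum(as.numeric(event))
  cea <- cumsum(as.numeric(event & group))
  cgr <- cumsum(as.numeric(group))
  dTot <- ce[ends] - c(0, ce)[starts]       # events at each distinct time
  dA <- cea[ends] - c(0, cea)[starts]
  nTot <- n - starts + 1                    # at risk at each distinct time
  nA <- cgr[n] - c(0, cgr)[starts]
  keep <- dTot > 0
  dTot <- dTot[keep]; dA <- dA[keep]; nTot <- nTot[keep]; nA <- nA[keep]
  E <- dTot * nA / nTot
  V <- ifelse(nTot > 1,
              dTot * (nA / nTot) * (1 - nA / nTot) * (nTot - dTot) / (nTot - 1),
              0)
  OE <- sum(dA) - sum(E)
  Vs <- sum(V)
  chi <- if (Vs > 0) OE^2 / Vs else 0
  c(chi_square = chi, observed = sum(dA), expected = sum(E))
}

#' Find the optimal survival cut-point of a continuous variable
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' values; candidates that would leave either group smaller than
#' `minGroupFraction * n` are skipped. The log-rank chi-square is computed
#' at every admissible candidate and the maximizer returned (the smallest
#' threshold on ties). `pCorrected` accounts for the maximal selection,
#' either by the Miller-Siegmund approximation over the scanned quantile
#' range or by a seeded permutation null.
#'
#' @param values continuous marker values, one per subject.
#' @param times positive follow-up times. @param events 0/1 indicators.
#' @param minGroupFraction minimum group size as a fraction of the cohort,
#'   in (0, 0.5] (default 0.1).
#' @param correction `"miller-siegmund"` (default) or `"permutation"`.
#' @param nPermutations,permutationSeed permutation-null settings.
#' @return A [CutpointResult-class].
#' @export
findOptimalCutpoint <- function(values, times, events, minGroupFraction = 0.1,
                                correction = c("miller-siegmund",
                                               "permutation"),
                                nPermutations = 1000L,
                                permutationSeed = 1L) {
  correction <- match.arg(correction)
  n <- length(values)
  stopifnot(length(times) == n, length(events) == n)
  if (n < 20L) stop("need at least 20 subjects", call. = FALSE)
  if (minGroupFraction <= 0 || minGroupFraction > 0.5)
    stop("minGroupFraction must be in (0, 0.5]", call. = FALSE)
  if (!any(events != 0)) stop("no events", call. = FALSE)

  scan <- .cutpointScan(values, times, events, minGroupFraction)
  if (!nrow(scan))
    stop("no admissible cut-point (all values identical or groups below ",
         "the minimum fraction)", call. = FALSE)
  best <- which(scan$chi_square >= max(scan$chi_square) - 1e-12)[1]
  thr <- scan$candidate[best]
  chi <- scan$chi_square[best]
  nHigh <- sum(values >= thr)
  pRaw <- stats::pchisq(chi, 1, lower.tail = FALSE)

  if (correction == "miller-siegmund") {
    propHigh <- vapply(scan$candidate, function(ct) mean(values >= ct), 0)
    pCor <- .millerSiegmund(chi, 1 - max(propHigh), 1 - min(propHigh))
  } else {
    pCor <- withSeed(permutationSeed, {
      exceed <- 0L
      for (b in seq_len(nPermutations)) {
        vp <- sample(values)
        sp <- .cutpointScan(vp, times, events, minGroupFraction)
        if (nrow(sp) && max(sp$chi_square) >= chi - 1e-12)
          exceed <- exceed + 1L
      }
      (exceed + 1) / (nPermutations + 1)
    })
  }
  pCor <- min(max(pCor, pRaw), 1)
  new("CutpointResult", threshold = thr, chiSquare = chi, pRaw = pRaw,
      pCorrected = pCor, nLow = n - as.integer(nHigh),
      nHigh = as.integer(nHigh), scan = scan)
}

.cutpointScan <- function(values, times, events, minGroupFraction) {
  n <- length(values)
  sv <- sort(unique(values))
  if (length(sv) < 2L)
    return(data.frame(candidate = numeric(), chi_square = numeric()))
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  nHigh <- vapply(cand, function(ct) sum(values >= ct), 0)
  minN <- minGroupFraction * n
  cand <- cand[nHigh >= minN & (n - nHigh) >= minN]
  if (!length(cand))
    return(data.frame(candidate = numeric(), chi_square = numeric()))
  ord <- order(times)
  ts <- times[ord]; ev <- events[ord] != 0; vs <- values[ord]
  chi <- vapply(cand, function(ct)
    .logrankStat(ts, ev, vs >= ct, sorted = TRUE)[["chi_square"]], 0)
  data.frame(candidate = cand, chi_square = chi)
}

# Miller & Siegmund improved Bonferroni approximation for the maximally
# selected standardized statistic scanned over selection quantiles
# (epsLow, epsHigh):
#   p ~ phi(b) (b - 1/b) log(epsHigh (1-epsLow) / (epsLow (1-epsHigh)))
#       + 4 phi(b) / b,   b = sqrt(chi)
.millerSiegmund <- function(chi, epsLow, epsHigh) {
  b <- sqrt(max(chi, 1e-12))
  epsLow <- min(max(epsLow, 1e-6), 1 - 1e-6)
  epsHigh <- min(max(epsHigh, epsLow + 1e-9), 1 - 1e-6)
  lg <- log(epsHigh * (1 - epsLow) / (epsLow * (1 - epsHigh)))
  p <- stats::dnorm(b) * (b - 1 / b) * lg + 4 * stats::dnorm(b) / b
  min(max(p, 0), 1)
}

#' Dichotomize a variable at a threshold
#'
#' Subjects with `value >= threshold` are labelled `"high"`, the rest
#' `"low"` (the threshold itself belongs to the high group).
#'
#' @param values numeric vector. @param threshold finite cut-point.
#' @return Factor with levels `low`, `high`.
#' @examples
#' applyCutpoint(c(10, 13.2, 20), 13.2)
#' @export
applyCutpoint <- function(values, threshold) {
  stopifnot(is.finite(threshold))
  factor(ifelse(values >= threshold, "high", "low"), levels = c("low", "high"))
}
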