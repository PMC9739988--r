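# Shared fixtures: small synthetic scenes, detection/truth matching, and
# Gaussian feature clusters for the classifier tests.

smallScene <- function(seed = 7L, tileSize = 120,
                       counts = c(TUMOR = 8L, IMMUNE = 6L, STROMA = 6L),
                       ...) {
  SceneSpec(tileSize = tileSize, counts = counts, seed = seed, ...)
}

# Greedy nearest-centroid matching of detections to ground truth within
# `maxDist` um; returns per-match distances and precision/recall.
matchDetections <- function(det, truth, maxDist = 5) {
  if (!nrow(det) || !nrow(truth))
    return(list(dist = numeric(), precision = 0, recall = 0,
                matchedTruth = integer(0), matchedDet = integer(0)))
  D <- outer(det$centroid_x_um, truth$centroid_x_um, "-")^2 +
    outer(det$centroid_y_um, truth$centroid_y_um, "-")^2
  D <- sqrt(D)
  matchedDet <- integer(0); matchedTruth <- integer(0); dists <- numeric(0)
  Dw <- D
  repeat {
    m <- which.min(Dw)
    if (!length(m) || Dw[m] > maxDist) break
    i <- (m - 1) %% nrow(Dw) + 1
    j <- (m - 1) %/% nrow(Dw) + 1
    matchedDet <- c(matchedDet, i); matchedTruth <- c(matchedTruth, j)
    dists <- c(dists, Dw[m])
    Dw[i, ] <- Inf; Dw[, j] <- Inf
    if (length(matchedDet) == min(nrow(det), nrow(truth))) break
  }
  list(dist = dists,
       precision = length(matchedDet) / nrow(det),
       recall = length(matchedTruth) / nrow(truth),
       matchedTruth = matchedTruth, matchedDet = matchedDet)
}

# Four well-separated Gaussian clusters in feature space.
clusterData <- function(separation, nPerClass = 200, p = 6, seed = 3) {
  set.seed(seed)
  classes <- c("TUMOR", "IMMUNE", "STROMA", "IGNORE")
  ctr <- matrix(rnorm(length(classes) * p), length(classes), p)
  ctr <- ctr / sqrt(rowSums(ctr^2)) * separation
  X <- do.call(rbind, lapply(seq_along(classes), function(k)
    sweep(matrix(rnorm(nPerClass * p), nPerClass, p), 2, ctr[k, ], "+")))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(p))
  centersDF <- as.data.frame(ctr)
  names(centersDF) <- names(df)
  list(features = df, labels = rep(classes, each = nPerClass),
       centers = centersDF, classes = classes)
}

# Brute-force log-rank chi-square from an explicit risk-set table.
bruteLogrank <- function(tA, eA, tB, eB) {
  t <- c(tA, tB); e <- c(eA, eB) != 0
  g <- rep(c(1, 0), c(length(tA), length(tB)))
  OE <- 0; V <- 0
  for (t0 in sort(unique(t[e]))) {
    atRisk <- t >= t0
    n <- sum(atRisk); nA <- sum(atRisk & g == 1)
    d <- sum(e & t == t0); dA <- sum(e & t == t0 & g == 1)
    OE <- OE + dA - d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}
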