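# Multilayer-perceptron cell classifier over TUMOR/IMMUNE/STROMA/IGNORE.
#
# Deliberately self-contained: seeded initialization, full-batch gradient
# descent with momentum, tanh hidden units and a softmax output, so that
# training is bit-reproducible given the config seed and supports an
# arbitrary stack of hidden layers (the single-layer default and a deep
# eight-layer preset).

#' Train the cell classifier
#'
#' Features are z-standardized with statistics computed from the training
#' rows only; zero-variance columns are dropped with a warning. A seeded
#' stratified 80/20 split reserves held-out rows for the reported confusion
#' matrix; the network is then trained on the 80% split by full-batch
#' gradient descent (momentum 0.9) on the softmax cross-entropy, for up to
#' `maxIterations` iterations or until the loss improvement falls below the
#' config tolerance.
#'
#' @param table feature data.frame (numeric feature columns; `id` and
#'   `qc_*` columns are ignored).
#' @param labels character vector of class labels, one per row, each from
#'   the config class list, with at least 10 examples per class.
#' @param config A [ClassifierConfig-class].
#' @return A [CellClassifier-class].
#' @export
trainCellClassifier <- function(table, labels, config = ClassifierConfig()) {
  validObject(config)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(table))
  bad <- setdiff(unique(labels), config@classes)
  if (length(bad))
    stop("labels outside the class list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training error: all labels identical (single class)", call. = FALSE)
  tooFew <- names(which(base::table(labels) < 10L))
  if (length(tooFew))
    stop("training error: fewer than 10 examples for class ",
         paste(tooFew, collapse = ", "), call. = FALSE)

  X <- .featureMatrix(table)
  withSeed(config@seed, {
    # stratified 80/20 split; the 20% never touches the standardization
    # statistics or the gradients
    holdout <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      k <- max(1L, floor(length(ix) * 0.2))
      sample(ix, k)
    }), use.names = FALSE)
    trainIdx <- setdiff(seq_along(labels), holdout)

    ctr <- colMeans(X[trainIdx, , drop = FALSE])
    scl <- apply(X[trainIdx, , drop = FALSE], 2, stats::sd)
    zeroVar <- scl < 1e-12
    if (any(zeroVar)) {
      warning("dropping zero-variance feature columns: ",
              paste(colnames(X)[zeroVar], collapse = ", "), call. = FALSE)
      X <- X[, !zeroVar, drop = FALSE]
      ctr <- ctr[!zeroVar]; scl <- scl[!zeroVar]
    }
    if (!ncol(X)) stop("no usable feature columns", call. = FALSE)
    Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

    classes <- config@classes
    y <- match(labels, classes)
    K <- length(classes)
    dims <- c(ncol(Z), config@hidden, K)
    nl <- length(dims) - 1L
    W <- B <- vector("list", nl)
    for (l in seq_len(nl)) {
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -0.5, 0.5) /
                         sqrt(dims[l]), dims[l], dims[l + 1L])
      B[[l]] <- numeric(dims[l + 1L])
    }

    Zt <- Z[trainIdx, , drop = FALSE]
    Yt <- matrix(0, length(trainIdx), K)
    Yt[cbind(seq_along(trainIdx), y[trainIdx])] <- 1
    m <- nrow(Zt)
    vW <- lapply(W, function(w) w * 0); vB <- lapply(B, function(b) b * 0)
    lastLoss <- Inf
    for (it in seq_len(config@maxIterations)) {
      acts <- .mlpForward(Zt, W, B)
      P <- acts$prob
      loss <- -sum(Yt * log(pmax(P, 1e-12))) / m
      delta <- (P - Yt) / m
      gW <- vector("list", nl); gB <- vector("list", nl)
      for (l in rev(seq_len(nl))) {
        Ain <- if (l == 1L) Zt else acts$hidden[[l - 1L]]
        gW[[l]] <- crossprod(Ain, delta)
        gB[[l]] <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * (1 - acts$hidden[[l - 1L]]^2)
      }
      for (l in seq_len(nl)) {
        vW[[l]] <- 0.9 * vW[[l]] - config@learningRate * gW[[l]]
        vB[[l]] <- 0.9 * vB[[l]] - config@learningRate * gB[[l]]
        W[[l]] <- W[[l]] + vW[[l]]
        B[[l]] <- B[[l]] + vB[[l]]
      }
      if (abs(lastLoss - loss) < config@tolerance) break
      lastLoss <- loss
    }

    clf <- new("CellClassifier", weights = W, biases = B, config = config,
               featureNames = colnames(Z), center = ctr, scale = scl,
               classCounts = stats::setNames(
                 as.integer(base::table(factor(labels, levels = classes))), classes),
               confusion = matrix(0L, K, K,
                                  dimnames = list(truth = classes,
                                                  prediction = classes)))
    # held-out confusion matrix
    pred <- classifyCells(clf, table[holdout, , drop = FALSE])$class
    cm <- base::table(factor(labels[holdout], levels = classes),
                factor(pred, levels = classes))
    clf@confusion <- matrix(as.integer(cm), K, K,
                            dimnames = list(truth = classes,
                                            prediction = classes))
    clf
  })
}

.featureMatrix <- function(table, featureNames = NULL) {
  num <- vapply(table, is.numeric, TRUE)
  keep <- setdiff(names(table)[num], c("id", "qc_cytoplasm_fallback"))
  X <- as.matrix(table[, keep, drop = FALSE])
  if (!is.null(featureNames)) {
    missing <- setdiff(featureNames, colnames(X))
    if (length(missing))
      stop("missing feature column: ", paste(missing, collapse = ", "),
           call. = FALSE)
    X <- X[, featureNames, drop = FALSE]
  }
  X
}

.mlpForward <- function(Z, W, B) {
  nl <- length(W)
  hidden <- vector("list", nl - 1L)
  A <- Z
  for (l in seq_len(nl)) {
    A <- sweep(A %*% W[[l]], 2, B[[l]], "+")
    if (l < nl) {
      A <- tanh(A)
      hidden[[l]] <- A
    }
  }
  A <- A - apply(A, 1, max)
  E <- exp(A)
  list(prob = E / rowSums(E), hidden = hidden)
}

#' Classify cells with a trained classifier
#'
#' Features are standardized with the training statistics; the predicted
#' class is the softmax argmax, with ties broken by class-list order.
#'
#' @param classifier A [CellClassifier-class].
#' @param table feature data.frame containing every training feature column.
#' @return List with `class` (character vector) and `prob` (matrix, one row
#'   per cell, columns named by class; rows sum to 1).
#' @export
classifyCells <- function(classifier, table) {
  stopifnot(is(classifier, "CellClassifier"))
  X <- .featureMatrix(table, classifier@featureNames)
  Z <- sweep(sweep(X, 2, classifier@center), 2, classifier@scale, "/")
  P <- .mlpForward(Z, classifier@weights, classifier@biases)$prob
  colnames(P) <- classifier@config@classes
  cls <- classifier@config@classes[apply(P, 1, which.max)]
  list(class = cls, prob = P)
}

#' Evaluate a classifier against known labels
#'
#' @param classifier A [CellClassifier-class].
#' @param table feature data.frame. @param labels true class labels.
#' @return List with `confusion` (rows = truth, columns = prediction),
#'   `precision` and `recall` per class, and overall `accuracy`
#'   (trace / total).
#' @export
evaluateClassifier <- function(classifier, table, labels) {
  pred <- classifyCells(classifier, table)$class
  classes <- classifier@config@classes
  cm <- base::table(factor(labels, levels = classes),
              factor(pred, levels = classes))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(truth = classes, prediction = classes))
  prec <- diag(cm) / pmax(colSums(cm), 1L)
  rec <- diag(cm) / pmax(rowSums(cm), 1L)
  list(confusion = cm, precision = prec, recall = rec,
       accuracy = sum(diag(cm)) / sum(cm))
}

#' Serialize / restore a trained classifier
#'
#' Written as a single portable JSON file holding the config, the
#' standardization statistics and all layer weights at full precision.
#'
#' @param classifier A [CellClassifier-class]. @param path file path.
#' @return `path` / the restored classifier.
#' @export
writeClassifier <- function(classifier, path) {
  stopifnot(is(classifier, "CellClassifier"))
  cfg <- classifier@config
  obj <- list(
    config = list(hidden = cfg@hidden, maxIterations = cfg@maxIterations,
                  learningRate = cfg@learningRate, tolerance = cfg@tolerance,
                  classes = cfg@classes, seed = cfg@seed),
    featureNames = classifier@featureNames,
    center = classifier@center, scale = classifier@scale,
    classCounts = as.list(classifier@classCounts),
    confusion = classifier@confusion,
    weights = lapply(classifier@weights, function(w)
      list(dim = dim(w), data = as.vector(w))),
    biases = classifier@biases)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  co <- obj$config
  cfg <- ClassifierConfig(hidden = as.integer(unlist(co$hidden)),
                          maxIterations = as.integer(co$maxIterations[[1]]),
                          learningRate = as.numeric(co$learningRate[[1]]),
                          tolerance = as.numeric(co$tolerance[[1]]),
                          classes = as.character(unlist(co$classes)),
                          seed = as.integer(co$seed[[1]]))
  K <- length(cfg@classes)
  featureNames <- as.character(unlist(obj$featureNames))
  cm <- matrix(as.integer(unlist(obj$confusion)), K, K, byrow = TRUE,
               dimnames = list(truth = cfg@classes, prediction = cfg@classes))
  new("CellClassifier",
      weights = lapply(obj$weights, function(w) {
        dm <- as.integer(unlist(w$dim))
        matrix(as.numeric(unlist(w$data)), dm[1], dm[2])
      }),
      biases = lapply(obj$biases, function(b) as.numeric(unlist(b))),
      config = cfg, featureNames = featureNames,
      center = stats::setNames(as.numeric(unlist(obj$center)), featureNames),
      scale = stats::setNames(as.numeric(unlist(obj$scale)), featureNames),
      classCounts = stats::setNames(as.integer(unlist(obj$classCounts)),
                                    names(obj$classCounts)),
      confusion = cm)
}
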