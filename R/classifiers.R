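#' Five white-blood-cell type labels
#'
#' The classification target: lymphocyte, monocyte, basophil, eosinophil,
#' neutrophil.
#'
#' @return character vector of length 5
#' @export
wbcClassLabels <- function() {
  c("lymphocyte", "monocyte", "basophil", "eosinophil", "neutrophil")
}

prepareXY <- function(x, y) {
  if (is.data.frame(x)) {
    if ("label" %in% names(x)) {
      if (missing(y) || is.null(y)) y <- x$label
      x$label <- NULL
    }
    x <- as.matrix(x)
  }
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("feature matrix contains non-finite values", call. = FALSE)
  list(x = x, y = y)
}

zscoreFit <- function(x) {
  ctr <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(center = ctr, scale = sdv)
}

zscoreApply <- function(x, s) sweep(sweep(x, 2L, s$center), 2L, s$scale, "/")

reportAccuracy <- function(pred, y) {
  classes <- unique(y)
  perClass <- vapply(classes, function(cl) mean(pred[y == cl] == cl),
                     numeric(1))
  list(trainAccuracy = mean(pred == y),
       perClassTrainAccuracy = as.list(perClass))
}

# ---- multilayer perceptron -------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

mlpForward <- function(weights, x) {
  a1 <- sigmoid(x %*% weights$W1 + matrix(weights$b1, nrow(x),
                                          length(weights$b1), byrow = TRUE))
  a2 <- sigmoid(a1 %*% weights$W2 + matrix(weights$b2, nrow(x),
                                           length(weights$b2), byrow = TRUE))
  z3 <- a2 %*% weights$W3 + matrix(weights$b3, nrow(x),
                                   length(weights$b3), byrow = TRUE)
  list(a1 = a1, a2 = a2, p = softmaxRows(z3))
}

#' Train the multilayer perceptron classifier
#'
#' A fully connected network with the fixed architecture
#' `nFeatures x 12 x 10 x nClasses` (20 x 12 x 10 x 5 for the standard
#' feature vector): logistic hidden activations, softmax readout, trained
#' by full-batch backpropagation on the cross-entropy loss with momentum.
#' Inputs are z-scored with statistics fitted on the training data. The
#' run is deterministic given `seed` (weight initialisation is the only
#' source of randomness).
#'
#' @param x numeric feature matrix or data frame (a `label` column is used
#'   as `y` if present)
#' @param y class labels, one per row
#' @param seed integer seed for weight initialisation
#' @param epochs number of full-batch epochs (default 2000)
#' @param learningRate gradient-descent step size (default 0.3)
#' @param momentum momentum coefficient (default 0.9)
#' @param hidden sizes of the two hidden layers (default `c(12, 10)`)
#' @return an [MLPClassifier][WBCClassifier-class]
#' @export
mlpTrain <- function(x, y, seed = 1L, epochs = 2000L, learningRate = 0.3,
                     momentum = 0.9, hidden = c(12L, 10L)) {
  d <- prepareXY(x, y); x <- d$x; y <- d$y
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("training data must contain at least 2 classes", call. = FALSE)
  scal <- zscoreFit(x)
  xs <- zscoreApply(x, scal)
  n <- nrow(xs); nIn <- ncol(xs); nOut <- length(classes)
  tgt <- matrix(0, n, nOut)
  tgt[cbind(seq_len(n), match(y, classes))] <- 1
  sizes <- c(nIn, hidden, nOut)
  w <- withSeed(seed, {
    ini <- function(nr, nc) matrix(stats::runif(nr * nc, -0.5, 0.5) /
                                     sqrt(nr), nr, nc)
    list(W1 = ini(sizes[1], sizes[2]), b1 = numeric(sizes[2]),
         W2 = ini(sizes[2], sizes[3]), b2 = numeric(sizes[3]),
         W3 = ini(sizes[3], sizes[4]), b3 = numeric(sizes[4]))
  })
  vel <- lapply(w, function(p) p * 0)
  for (ep in seq_len(epochs)) {
    fw <- mlpForward(w, xs)
    d3 <- (fw$p - tgt) / n                               # softmax + CE
    d2 <- (d3 %*% t(w$W3)) * fw$a2 * (1 - fw$a2)
    d1 <- (d2 %*% t(w$W2)) * fw$a1 * (1 - fw$a1)
    grad <- list(W1 = t(xs) %*% d1, b1 = colSums(d1),
                 W2 = t(fw$a1) %*% d2, b2 = colSums(d2),
                 W3 = t(fw$a2) %*% d3, b3 = colSums(d3))
    for (nm in names(w)) {
      vel[[nm]] <- momentum * vel[[nm]] - learningRate * grad[[nm]]
      w[[nm]] <- w[[nm]] + vel[[nm]]
    }
  }
  fn <- colnames(x); if (is.null(fn)) fn <- paste0("x", seq_len(nIn))
  pred <- classes[max.col(mlpForward(w, xs)$p, ties.method = "first")]
  new("MLPClassifier", classes = classes, scaling = scal,
      featureNames = fn, weights = w, sizes = sizes,
      trainingReport = reportAccuracy(pred, y))
}

#' Number of trainable parameters of an MLP classifier
#'
#' Weights plus biases over all layers; 437 for the standard
#' 20 x 12 x 10 x 5 architecture.
#'
#' @param object an [MLPClassifier][WBCClassifier-class]
#' @return integer
#' @export
mlpParameterCount <- function(object) {
  stopifnot(is(object, "MLPClassifier"))
  sum(vapply(object@weights, length, integer(1)))
}

# ---- support vector machine ------------------------------------------------

#' Train the radial-basis-function support vector machine
#'
#' A C-classification SVM with the RBF kernel and one-vs-one multiclass
#' voting. The basis-function count and centres are set automatically by
#' the support vectors. Inputs are z-scored by the package (the fitted
#' transform is stored on the classifier).
#'
#' @inheritParams mlpTrain
#' @param gamma RBF kernel width parameter (default `1/nFeatures`)
#' @param cost soft-margin cost C (default 10)
#' @param seed seed for the underlying solver's internal randomisation
#' @return an [SVMClassifier][WBCClassifier-class]; the support-vector count
#'   is in `trainingReport$nSupportVectors`
#' @export
svmTrain <- function(x, y, gamma = NULL, cost = 10, seed = 1L) {
  d <- prepareXY(x, y); x <- d$x; y <- d$y
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("training data must contain at least 2 classes", call. = FALSE)
  scal <- zscoreFit(x)
  xs <- zscoreApply(x, scal)
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  fit <- withSeed(seed,
    e1071::svm(xs, factor(y, levels = classes), type = "C-classification",
               kernel = "radial", gamma = gamma, cost = cost, scale = FALSE))
  fn <- colnames(x); if (is.null(fn)) fn <- paste0("x", seq_len(ncol(x)))
  pred <- as.character(stats::predict(fit, xs))
  rpt <- reportAccuracy(pred, y)
  rpt$nSupportVectors <- nrow(fit$SV)
  new("SVMClassifier", classes = classes, scaling = scal,
      featureNames = fn, fit = fit, trainingReport = rpt)
}

# ---- HRCNN wrapper ---------------------------------------------------------

#' Train the hyperrectangular composite network classifier
#'
#' Wraps [hrcnnTrain()] in the common classifier interface (min-max scaling
#' lives inside the [HRCNNModel-class]). Training accuracy is 100% on any
#' consistently labelled data set by construction.
#'
#' @inheritParams mlpTrain
#' @param eta output threshold in (0,1)
#' @param seed optional seed to shuffle the covering order
#' @return an [HRCNNClassifier][WBCClassifier-class]
#' @export
hrcnnClassifier <- function(x, y, eta = 0.5, seed = NULL) {
  d <- prepareXY(x, y); x <- d$x; y <- d$y
  model <- hrcnnTrain(x, y, eta = eta, seed = seed)
  pred <- hrcnnPredict(model, x)
  new("HRCNNClassifier", classes = model@classes,
      scaling = model@scaling, featureNames = model@featureNames,
      model = model, trainingReport = reportAccuracy(pred, y))
}

# ---- prediction and evaluation --------------------------------------------

asFeatureMatrix <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    newdata$label <- NULL
    newdata <- as.matrix(newdata)
  }
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object@featureNames))
    stop("expected ", length(object@featureNames), " features, got ",
         ncol(newdata), call. = FALSE)
  if (!is.null(colnames(newdata)) &&
      all(object@featureNames %in% colnames(newdata)))
    newdata <- newdata[, object@featureNames, drop = FALSE]
  newdata
}

#' Predict cell types from feature vectors
#'
#' All three classifiers accept a feature matrix (or a single feature
#' vector) on the raw scale and return exactly one class label per row.
#'
#' @param object a trained classifier
#' @param newdata numeric matrix, data frame, or single feature vector
#' @return character vector of class labels
#' @rdname predict-classifiers
#' @export
setMethod("predict", "MLPClassifier", function(object, newdata) {
  xs <- zscoreApply(asFeatureMatrix(object, newdata), object@scaling)
  object@classes[max.col(mlpForward(object@weights, xs)$p,
                         ties.method = "first")]
})

#' @rdname predict-classifiers
#' @export
setMethod("predict", "SVMClassifier", function(object, newdata) {
  xs <- zscoreApply(asFeatureMatrix(object, newdata), object@scaling)
  as.character(stats::predict(object@fit, xs))
})

#' @rdname predict-classifiers
#' @export
setMethod("predict", "HRCNNClassifier", function(object, newdata) {
  hrcnnPredict(object@model, asFeatureMatrix(object, newdata))
})

#' Accuracy of a classifier on a labelled data set
#'
#' @param classifier a trained classifier
#' @param x feature matrix or data frame
#' @param y true labels
#' @return list with `overallAccuracy`, `perClassAccuracy` (named list) and
#'   the `confusion` table
#' @export
evaluateClassifier <- function(classifier, x, y) {
  d <- prepareXY(x, y)
  pred <- predict(classifier, d$x)
  classes <- unique(d$y)
  perClass <- lapply(stats::setNames(classes, classes),
                     function(cl) mean(pred[d$y == cl] == cl))
  list(overallAccuracy = mean(pred == d$y),
       perClassAccuracy = perClass,
       confusion = table(truth = d$y, predicted = pred))
}

#' Stratified train/test split
#'
#' Splits row indices per class so the training fraction is honoured within
#' every label (the canonical evaluation splits 450 cells into 299 training
#' and 151 testing rows, fraction 299/450).
#'
#' @param y class labels
#' @param trainFraction fraction of rows used for training
#' @param seed integer seed
#' @return list with integer index vectors `train` and `test`
#' @export
trainTestSplit <- function(y, trainFraction = 299 / 450, seed = 1L) {
  y <- as.character(y)
  withSeed(seed, {
    train <- integer(0)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      nTrain <- round(length(idx) * trainFraction)
      nTrain <- max(1L, min(length(idx), nTrain))
      train <- c(train, sample(idx, nTrain))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

# ---- model serialization ---------------------------------------------------

#' Save / load a trained classifier as JSON
#'
#' MLP weights and HRCNN boxes are stored as plain nested arrays at full
#' precision; the fitted SVM is embedded as a base64-encoded serialized
#' payload alongside its support-vector summary.
#'
#' @param classifier a trained classifier
#' @param path file path
#' @return `saveClassifier` returns `path` invisibly; `loadClassifier` the
#'   classifier
#' @export
saveClassifier <- function(classifier, path) {
  kind <- c(MLPClassifier = "mlp", SVMClassifier = "svm",
            HRCNNClassifier = "hrcnn")[[class(classifier)]]
  obj <- list(kind = kind, classes = classifier@classes,
              featureNames = classifier@featureNames,
              featureOrderVersion = featureOrderVersion(),
              scaling = classifier@scaling,
              trainingReport = classifier@trainingReport)
  if (kind == "mlp") {
    obj$sizes <- classifier@sizes
    obj$weights <- lapply(classifier@weights, function(w)
      if (is.matrix(w)) unclass(w) else as.numeric(w))
  } else if (kind == "hrcnn") {
    m <- classifier@model
    obj$eta <- m@eta
    obj$boxes <- lapply(m@boxes, function(bl)
      lapply(bl, function(b) list(m = as.numeric(b$m),
                                  M = as.numeric(b$M))))
  } else {
    obj$nSupportVectors <- nrow(classifier@fit$SV)
    obj$payload <- jsonlite::base64_enc(serialize(classifier@fit, NULL))
  }
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  scal <- lapply(obj$scaling, as.numeric)
  if (obj$kind == "mlp") {
    w <- obj$weights
    for (nm in c("W1", "W2", "W3")) w[[nm]] <- as.matrix(w[[nm]])
    for (nm in c("b1", "b2", "b3")) w[[nm]] <- as.numeric(w[[nm]])
    new("MLPClassifier", classes = obj$classes, scaling = scal,
        featureNames = obj$featureNames, weights = w,
        sizes = as.numeric(obj$sizes), trainingReport = obj$trainingReport)
  } else if (obj$kind == "hrcnn") {
    boxes <- lapply(obj$boxes, function(bl)
      lapply(bl, function(b) list(m = as.numeric(b$m), M = as.numeric(b$M))))
    model <- new("HRCNNModel", classes = obj$classes, boxes = boxes,
                 eta = obj$eta, scaling = scal,
                 featureNames = obj$featureNames)
    new("HRCNNClassifier", classes = obj$classes, scaling = scal,
        featureNames = obj$featureNames, model = model,
        trainingReport = obj$trainingReport)
  } else if (obj$kind == "svm") {
    fit <- unserialize(jsonlite::base64_dec(obj$payload))
    new("SVMClassifier", classes = obj$classes, scaling = scal,
        featureNames = obj$featureNames, fit = fit,
        trainingReport = obj$trainingReport)
  } else stop("unknown classifier kind: ", obj$kind, call. = FALSE)
}
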