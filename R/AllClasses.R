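#' @import methods
#' @importFrom stats cov quantile runif rnorm predict
NULL

#' Ellipsoidal discriminating region in HSI colour space
#'
#' Describes the tones of stained white-blood-cell pixels as a rotated
#' ellipsoid in hue-saturation-intensity space. A pixel with HSI triple
#' \eqn{x} is claimed to be a cell pixel when the quadratic membership value
#' \deqn{(H'-C_H)^2/r_H^2 + (S'-C_S)^2/r_S^2 + (I'-C_I)^2/r_I^2 \le 1}
#' with \eqn{(H',S',I')' = R x}, i.e. when the rotated triple falls inside
#' the axis-aligned ellipsoid with centre \eqn{(C_H,C_S,C_I)} and semi-axes
#' \eqn{(r_H,r_S,r_I)}.
#'
#' @slot rotation 3x3 numeric rotation matrix whose rows are the principal
#'   axes of the cell-tone cloud.
#' @slot center length-3 numeric, ellipsoid centre in rotated coordinates.
#' @slot semiAxes length-3 numeric, strictly positive semi-axis lengths.
#' @slot conventionTag free-text label of the HSI scaling convention the
#'   region was fitted under; regions fitted by [fitRegion()] carry
#'   `"gw-degrees"` (hue in degrees, S and I in \[0,1\]). The shipped presets
#'   carry `"published-unknown"` because their source scaling is not stated.
#'
#' @seealso [fitRegion()], [membership()], [presetRegion()]
#' @export
setClass("EllipsoidRegion",
  representation(
    rotation = "matrix",
    center = "numeric",
    semiAxes = "numeric",
    conventionTag = "character"
  )
)

setValidity("EllipsoidRegion", function(object) {
  msg <- character()
  if (!identical(dim(object@rotation), c(3L, 3L)))
    msg <- c(msg, "rotation must be a 3x3 matrix")
  if (length(object@center) != 3L)
    msg <- c(msg, "center must have length 3")
  if (length(object@semiAxes) != 3L || any(!is.finite(object@semiAxes)) ||
      any(object@semiAxes <= 0))
    msg <- c(msg, "semiAxes must be 3 strictly positive numbers")
  if (length(object@conventionTag) != 1L)
    msg <- c(msg, "conventionTag must be a single string")
  if (length(msg)) msg else TRUE
})

#' @describeIn EllipsoidRegion-class compact display of centre, semi-axes and
#'   convention tag.
#' @param object an `EllipsoidRegion`
#' @export
setMethod("show", "EllipsoidRegion", function(object) {
  cat("EllipsoidRegion (HSI discriminating region)\n")
  cat("  convention: ", object@conventionTag, "\n", sep = "")
  cat("  center    : ", paste(signif(object@center, 5), collapse = ", "), "\n", sep = "")
  cat("  semi-axes : ", paste(signif(object@semiAxes, 5), collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

#' Hyperrectangular composite neural network model
#'
#' A per-class collection of axis-aligned hyperrectangles (boxes). The
#' network output for class \eqn{c} is
#' \deqn{Out(x) = f\left(\sum_j Out_j(x) - \eta\right)}
#' with hidden nodes
#' \deqn{Out_j(x) = f(net_j(x)), \quad
#'       net_j(x) = \sum_{i=1}^n f\big((M_{ji}-x_i)(x_i-m_{ji})\big) - n}
#' and the hard threshold \eqn{f(y) = 1} iff \eqn{y \ge 0}. A hidden node
#' fires exactly when \eqn{m_{ji} \le x_i \le M_{ji}} for every feature
#' \eqn{i}, so each node is readable as a crisp If-Then interval rule.
#'
#' @slot classes character vector of class labels, in training order.
#' @slot boxes list (one element per class) of lists of boxes; each box is a
#'   `list(m = lower, M = upper)` pair of numeric vectors of the input
#'   dimension, in min-max-scaled feature units.
#' @slot eta small positive threshold \eqn{\eta \in (0,1)}; any value in
#'   that interval gives identical behaviour since hidden outputs are binary.
#' @slot scaling list with `min` and `range` vectors mapping raw features to
#'   \[0,1\] (`(x - min) / range`).
#' @slot featureNames character vector naming the input dimensions.
#'
#' @seealso [hrcnnTrain()], [hrcnnOutput()], [hrcnnRules()]
#' @export
setClass("HRCNNModel",
  representation(
    classes = "character",
    boxes = "list",
    eta = "numeric",
    scaling = "list",
    featureNames = "character"
  )
)

setValidity("HRCNNModel", function(object) {
  msg <- character()
  if (length(object@eta) != 1L || object@eta <= 0 || object@eta >= 1)
    msg <- c(msg, "eta must lie in (0,1)")
  if (length(object@boxes) != length(object@classes))
    msg <- c(msg, "boxes must have one element per class")
  for (cls in seq_along(object@boxes)) {
    for (b in object@boxes[[cls]]) {
      if (!all(b$m <= b$M)) {
        msg <- c(msg, "every box must satisfy m <= M")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HRCNNModel-class prints the number of rules per class.
#' @param object an `HRCNNModel`
#' @export
setMethod("show", "HRCNNModel", function(object) {
  cat("HRCNNModel:", length(object@classes), "classes,",
      sum(lengths(object@boxes)), "hyperrectangles\n")
  for (k in seq_along(object@classes))
    cat("  ", object@classes[k], ": ", length(object@boxes[[k]]),
        " box(es)\n", sep = "")
  invisible(NULL)
})

#' Trained white-blood-cell classifiers
#'
#' `WBCClassifier` is the virtual parent of the three trained classifier
#' types. All of them consume a 20-feature vector (see [extractFeatures()])
#' and emit exactly one of the five cell-type labels. Each subclass stores
#' the feature scaling fitted on its training split so raw feature rows can
#' be passed to [predict()] directly.
#'
#' @slot classes character vector of class labels.
#' @slot scaling list describing the fitted feature transform; z-score
#'   (`center`, `scale`) for the MLP and SVM, min-max (`min`, `range`) for
#'   the HRCNN.
#' @slot featureNames character, expected input column names (order matters).
#' @slot trainingReport list with at least `trainAccuracy` and
#'   `perClassTrainAccuracy`.
#' @export
setClass("WBCClassifier",
  representation(
    "VIRTUAL",
    classes = "character",
    scaling = "list",
    featureNames = "character",
    trainingReport = "list"
  )
)

#' @rdname WBCClassifier-class
#' @slot weights list of weight matrices and bias vectors of the multilayer
#'   perceptron, layer sizes 20, 12, 10, 5.
#' @slot sizes integer layer sizes.
#' @export
setClass("MLPClassifier",
  contains = "WBCClassifier",
  representation(weights = "list", sizes = "numeric")
)

#' @rdname WBCClassifier-class
#' @slot fit the underlying radial-basis-kernel support vector machine
#'   (one-vs-one multiclass); its support-vector count is reported in
#'   `trainingReport$nSupportVectors`.
#' @export
setClass("SVMClassifier",
  contains = "WBCClassifier",
  representation(fit = "ANY")
)

#' @rdname WBCClassifier-class
#' @slot model the underlying [HRCNNModel-class].
#' @export
setClass("HRCNNClassifier",
  contains = "WBCClassifier",
  representation(model = "HRCNNModel")
)

#' @describeIn WBCClassifier-class summary display.
#' @param object a classifier
#' @export
setMethod("show", "WBCClassifier", function(object) {
  cat(class(object), "over", length(object@classes), "classes;",
      "training accuracy",
      sprintf("%.4f", object@trainingReport$trainAccuracy), "\n")
  invisible(NULL)
})

#' Synthetic smear scene
#'
#' An RGB smear-like image together with the exact ground-truth cell mask
#' and the generating parameters, as produced by [generateScene()].
#'
#' @slot image H x W x 3 integer array, channels in \[0,255\].
#' @slot truth H x W logical matrix; `TRUE` on rasterised cell ellipses.
#' @slot spec the generating [sceneSpec()] list (including the seed), from
#'   which the scene is reproducible bit-exactly.
#' @export
setClass("SyntheticScene",
  representation(image = "array", truth = "matrix", spec = "list")
)

#' @describeIn SyntheticScene-class dimensions and cell count.
#' @param object a `SyntheticScene`
#' @export
setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene ", nrow(object@truth), "x", ncol(object@truth),
      ", ", length(object@spec$cells), " cell(s), ",
      sum(object@truth), " truth pixels, seed ", object@spec$seed, "\n",
      sep = "")
  invisible(NULL)
})
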