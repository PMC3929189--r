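#' Construct an EllipsoidRegion
#'
#' Low-level constructor; most users obtain regions from [fitRegion()] or
#' [presetRegion()].
#'
#' @param rotation 3x3 numeric matrix (rows = principal axes)
#' @param center length-3 numeric centre in rotated coordinates
#' @param semiAxes length-3 positive numeric semi-axis lengths
#' @param conventionTag HSI-scaling label (see [EllipsoidRegion-class])
#' @return an [EllipsoidRegion-class]
#' @export
EllipsoidRegion <- function(rotation, center, semiAxes,
                            conventionTag = "gw-degrees") {
  new("EllipsoidRegion", rotation = rotation, center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), conventionTag = conventionTag)
}

#' Ellipsoid membership value of HSI triples
#'
#' Evaluates the quadratic form of the discriminating region: the triple is
#' rotated by the region's matrix and the sum of squared, semi-axis-scaled
#' deviations from the centre is returned. A pixel is claimed to be a white
#' blood cell pixel when the value is at most 1; the pre-image of the centre
#' scores exactly 0.
#'
#' @param region an [EllipsoidRegion-class]
#' @param hsi a length-3 (H, S, I) triple or an N x 3 matrix of triples
#' @return non-negative numeric vector of membership values (length N)
#' @export
setGeneric("membership", function(region, hsi) standardGeneric("membership"))

#' @rdname membership
setMethod("membership", signature("EllipsoidRegion", "numeric"),
  function(region, hsi) {
    if (length(hsi) != 3L) stop("hsi triple must have length 3", call. = FALSE)
    membership(region, matrix(hsi, nrow = 1L))
  })

#' @rdname membership
setMethod("membership", signature("EllipsoidRegion", "matrix"),
  function(region, hsi) {
    if (ncol(hsi) != 3L) stop("hsi matrix must have 3 columns", call. = FALSE)
    rot <- hsi %*% t(region@rotation)
    dev <- sweep(rot, 2L, region@center)
    as.numeric(sweep(dev^2, 2L, region@semiAxes^2, "/") %*% rep(1, 3L))
  })

#' Fit a discriminating region to labelled cell-tone pixels
#'
#' Fits the rotated ellipsoid by principal component analysis: the rows of
#' the rotation matrix are the eigenvectors of the sample covariance (sorted
#' by descending eigenvalue, each row's sign fixed so that its
#' largest-magnitude entry is positive), the centre is the rotated sample
#' mean, and the semi-axes are set per axis to the
#' `coverage^(1/3)`-quantile of the absolute centred projections, then
#' rescaled by a single multiplicative factor (found by bisection) so that
#' the fraction of samples with membership value at most 1 matches
#' `coverage` to within 0.5%. Hue is treated as a linear scalar; sample the
#' tones so they do not straddle the 0/360 wrap.
#'
#' @param samples N x 3 numeric matrix of (H, S, I) rows, N >= 4, with a
#'   rank-3 covariance
#' @param coverage target fraction of samples inside the ellipsoid, in (0,1]
#' @param conventionTag HSI-scaling label recorded on the region
#' @return an [EllipsoidRegion-class]
#' @examples
#' set.seed(1)
#' pts <- cbind(H = rnorm(2000, 280, 20), S = rnorm(2000, 0.5, 0.08),
#'              I = rnorm(2000, 0.4, 0.05))
#' reg <- fitRegion(pts, coverage = 0.975)
#' mean(membership(reg, pts) <= 1)
#' @export
fitRegion <- function(samples, coverage = 0.975,
                      conventionTag = "gw-degrees") {
  if (!is.matrix(samples)) samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("samples must have 3 columns (H,S,I)",
                                call. = FALSE)
  if (nrow(samples) < 4L)
    stop("degenerate sample set: need at least 4 pixel samples", call. = FALSE)
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1]", call. = FALSE)
  cv <- stats::cov(samples)
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < max(eg$values) * 1e-10 || min(eg$values) <= 0)
    stop("degenerate sample set: covariance is not full rank", call. = FALSE)
  rot <- t(eg$vectors)                      # rows = principal axes
  for (k in 1:3) if (rot[k, which.max(abs(rot[k, ]))] < 0) rot[k, ] <- -rot[k, ]
  mu <- colMeans(samples)
  center <- as.numeric(rot %*% mu)
  proj <- samples %*% t(rot)
  dev <- abs(sweep(proj, 2L, center))
  q <- coverage^(1 / 3)
  r0 <- apply(dev, 2L, stats::quantile, probs = q, names = FALSE)
  r0[r0 <= 0] <- .Machine$double.eps
  covered <- function(scale) {
    reg <- EllipsoidRegion(rot, center, r0 * scale, conventionTag)
    mean(membership(reg, samples) <= 1)
  }
  lo <- 1e-3; hi <- 1
  while (covered(hi) < coverage && hi < 1e3) hi <- hi * 2
  scale <- hi
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    frac <- covered(mid)
    if (abs(frac - coverage) <= 0.005) { scale <- mid; break }
    if (frac < coverage) lo <- mid else hi <- mid
    scale <- hi
  }
  EllipsoidRegion(rot, center, r0 * scale, conventionTag)
}

#' Published discriminating regions for the two staining data sets
#'
#' Returns the discriminating region reported for one of two
#' differently stained smear-image collections: data set 1 and data set 2
#' (a more purple stain). The constants are stored verbatim; the HSI
#' scaling convention they were derived under is not documented, so the
#' regions carry `conventionTag = "published-unknown"` and are not assumed
#' compatible with [rgbToHSI()] output. The printed rotation matrices are
#' not orthonormal to printed precision and are deliberately not
#' re-orthogonalised.
#'
#' @param datasetId 1 or 2
#' @return an [EllipsoidRegion-class]
#' @export
presetRegion <- function(datasetId) {
  if (length(datasetId) != 1L || !datasetId %in% c(1, 2))
    stop("datasetId must be 1 or 2", call. = FALSE)
  if (datasetId == 1) {
    EllipsoidRegion(
      rotation = matrix(c(-0.6590, 0.3518, -0.7135,
                           0.7527, 0.5438,  0.3711,
                          -0.2574, 0.7620,  0.5943), 3L, 3L, byrow = TRUE),
      center = c(6.042, 2.916, 0.252),
      semiAxes = c(52.645, 17.274, 11.154),
      conventionTag = "published-unknown")
  } else {
    EllipsoidRegion(
      rotation = matrix(c(-0.3683, 0.5550, -0.7459,
                           0.8238, 0.5667,  0.0149,
                          -0.4309, 0.6090,  0.6659), 3L, 3L, byrow = TRUE),
      center = c(-16.433, -0.0512, -8.735),
      semiAxes = c(56.761, 40.027, 21.894),
      conventionTag = "published-unknown")
  }
}

#' Serialize a discriminating region to JSON
#'
#' Regions round-trip through a small JSON schema
#' (`rotation`, `center`, `semi_axes`, `convention_tag`) at full double
#' precision.
#'
#' @param region an [EllipsoidRegion-class]
#' @param path output / input file path
#' @return `saveRegion` returns `path` invisibly; `loadRegion` returns the
#'   region
#' @export
saveRegion <- function(region, path) {
  stopifnot(is(region, "EllipsoidRegion"))
  obj <- list(
    rotation = lapply(seq_len(3L), function(i) region@rotation[i, ]),
    center = region@center,
    semi_axes = region@semiAxes,
    convention_tag = region@conventionTag
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname saveRegion
#' @export
loadRegion <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse region file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  need <- c("rotation", "center", "semi_axes", "convention_tag")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("region file is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rot <- obj$rotation
  if (is.list(rot)) rot <- do.call(rbind, lapply(rot, as.numeric))
  rot <- matrix(as.numeric(rot), 3L, 3L)
  EllipsoidRegion(rot, as.numeric(obj$center), as.numeric(obj$semi_axes),
                  obj$convention_tag)
}
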