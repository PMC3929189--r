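#' Names and order of the 20 cell features
#'
#' The frozen feature order used everywhere (CSV columns, classifier
#' inputs): `Area`, `Length_var`, `Comp`, `Hue_var`, `Saturation_var`,
#' `Intensity_var`, then the 14 reduced-LDP bins `LDP_<code>`. The order is
#' versioned (`featureOrderVersion()`) so trained models stay portable.
#'
#' @param binList integer LDP bin codes (default [ldpDefaultBins()])
#' @return character vector of length `6 + length(binList)`
#' @export
featureNames <- function(binList = ldpDefaultBins()) {
  c("Area", "Length_var", "Comp", "Hue_var", "Saturation_var",
    "Intensity_var", paste0("LDP_", binList))
}

#' @rdname featureNames
#' @export
featureOrderVersion <- function() "wbc-features-v1"

#' Default reduced-LDP bins
#'
#' The 14 LDP codes whose average occurrence count across a 60-image
#' training corpus of the five cell types exceeded 400, i.e. the bins that
#' carry most of the texture mass. They are the default reduced-histogram
#' support; [selectProminentBins()] re-derives such a list from new data.
#'
#' @return integer vector of 14 LDP codes
#' @export
ldpDefaultBins <- function() {
  c(19L, 25L, 35L, 38L, 49L, 50L, 70L, 76L, 98L, 100L,
    137L, 140L, 145L, 196L)
}

emptyCellStop <- function() stop("empty cell: mask has no foreground pixels",
                                 call. = FALSE)

#' Area of a segmented cell
#'
#' Number of pixels in the mask.
#'
#' @param mask logical matrix (refined cell mask)
#' @return integer pixel count
#' @export
cellArea <- function(mask) {
  stopifnotMask(mask)
  a <- sum(mask)
  if (a == 0L) emptyCellStop()
  a
}

# Logical matrix of boundary pixels: foreground 4-adjacent to background or
# to the image edge. (4-adjacency keeps the perimeter estimator free of the
# diagonal-staircase double counting that would make digital disks score
# less compact than squares.)
boundaryPixelMask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  allNb <- matrix(TRUE, nr, nc)
  for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)))
    allNb <- allNb & pad[(2:(nr + 1L)) + s[1], (2:(nc + 1L)) + s[2]]
  mask & !allNb
}

#' Boundary-to-centroid distances
#'
#' Euclidean distances from every boundary pixel of the cell to the
#' foreground centroid. A boundary pixel is a foreground pixel 4-adjacent
#' to background or lying on the image edge.
#'
#' @param mask logical matrix
#' @return numeric vector, one length per boundary pixel
#' @export
boundaryLengths <- function(mask) {
  stopifnotMask(mask)
  if (!any(mask)) emptyCellStop()
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  b <- which(boundaryPixelMask(mask), arr.ind = TRUE)
  sqrt((b[, 1] - ctr[1])^2 + (b[, 2] - ctr[2])^2)
}

#' Variance of boundary-to-centroid lengths
#'
#' Population variance (divide by the number of boundary pixels
#' \eqn{N_b}) of [boundaryLengths()]:
#' \deqn{\mathrm{Length}_{var} = \frac{1}{N_b}\sum_{i=1}^{N_b}
#'   (\mathrm{length}_i - \overline{\mathrm{length}})^2.}
#' Near zero for disk-like cells, large for elongated or ragged ones.
#'
#' @inheritParams boundaryLengths
#' @return non-negative numeric scalar
#' @export
lengthVar <- function(mask) {
  len <- boundaryLengths(mask)
  mean((len - mean(len))^2)
}

#' Compactness of a cell
#'
#' Perimeter squared over area, with the perimeter estimated as the
#' boundary-pixel count (same boundary definition as
#' [boundaryLengths()]). Minimal for disk-like shapes.
#'
#' @inheritParams boundaryLengths
#' @return positive numeric scalar
#' @export
compactness <- function(mask) {
  stopifnotMask(mask)
  if (!any(mask)) emptyCellStop()
  sum(boundaryPixelMask(mask))^2 / sum(mask)
}

#' Colour variances over the cell pixels
#'
#' Population variances of the hue, saturation and intensity channels over
#' the masked pixels. Hue is treated as a linear quantity in degrees (no
#' circular statistics).
#'
#' @param hsi H x W x 3 HSI array (see [rgbToHSI()])
#' @param mask logical matrix of matching dimensions
#' @return named numeric vector `(Hue_var, Saturation_var, Intensity_var)`
#' @export
colorVariances <- function(hsi, mask) {
  stopifnotMask(mask)
  if (!any(mask)) emptyCellStop()
  if (!identical(dim(hsi)[1:2], dim(mask)))
    stop("hsi and mask dimensions differ", call. = FALSE)
  popvar <- function(x) mean((x - mean(x))^2)
  c(Hue_var = popvar(hsi[, , 1][mask]),
    Saturation_var = popvar(hsi[, , 2][mask]),
    Intensity_var = popvar(hsi[, , 3][mask]))
}

#' The eight Kirsch edge masks
#'
#' The canonical 3x3 directional edge kernels: rotations of
#' `rbind(c(-3,-3,5), c(-3,0,5), c(-3,-3,5))`, obtained by circularly
#' shifting the five -3 and three 5 entries around the outer ring. Mask
#' `k` (k = 0..7) responds most strongly to an edge in direction k, 45
#' degrees apart; entries of every mask sum to zero.
#'
#' @return list of eight 3x3 numeric matrices, named `M0` ... `M7`
#' @export
kirschMasks <- function() {
  # outer ring positions (row, col) in circular order
  ring <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3), c(3, 3),
                c(3, 2), c(3, 1), c(2, 1))
  base <- c(-3, -3, 5, 5, 5, -3, -3, -3)
  out <- vector("list", 8L)
  for (k in 0:7) {
    m <- matrix(0, 3L, 3L)
    vals <- base[((seq_len(8L) - 1L + k) %% 8L) + 1L]
    m[ring] <- vals
    out[[k + 1L]] <- m
  }
  names(out) <- paste0("M", 0:7)
  out
}

#' Kirsch edge responses of a gray image
#'
#' Applies the eight Kirsch masks to a grayscale image: the response of
#' mask \eqn{M} at pixel \eqn{(r,c)} is
#' \eqn{\sum_{u,v} M_{uv}\, g_{r+u-2,\,c+v-2}} (the mask laid over the 3x3
#' neighbourhood). Border pixels, whose neighbourhood leaves the image, are
#' `NA`.
#'
#' @param gray H x W numeric matrix, H, W >= 3
#' @return list of eight H x W response matrices, named `M0` ... `M7`
#' @export
kirschResponses <- function(gray) {
  if (!is.matrix(gray) || nrow(gray) < 3L || ncol(gray) < 3L)
    stop("gray image must be a matrix of at least 3 x 3", call. = FALSE)
  nr <- nrow(gray); nc <- ncol(gray)
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  masks <- kirschMasks()
  lapply(masks, function(m) {
    resp <- matrix(NA_real_, nr, nc)
    acc <- matrix(0, length(ri), length(ci))
    for (u in 1:3) for (v in 1:3) {
      if (m[u, v] == 0) next
      acc <- acc + m[u, v] * gray[ri + (u - 2L), ci + (v - 2L), drop = FALSE]
    }
    resp[ri, ci] <- acc
    resp
  })
}

#' Local directional pattern code from eight edge responses
#'
#' Sets the bits of the three directions with the largest absolute Kirsch
#' response (bit k for mask `Mk`). Ties are broken toward the lower
#' direction index, so the code is deterministic; every code has exactly
#' three set bits and lies in \[7, 224\].
#'
#' @param responses numeric vector of eight finite edge responses
#' @return integer LDP code
#' @export
ldpCode <- function(responses) {
  if (length(responses) != 8L || any(!is.finite(responses)))
    stop("need 8 finite responses", call. = FALSE)
  top <- order(-abs(responses), seq_len(8L))[1:3]
  sum(bitwShiftL(1L, top - 1L))
}

#' LDP-label a gray cell image
#'
#' Computes the LDP code at every pixel whose 3x3 neighbourhood lies fully
#' inside the image and (by default) which belongs to the cell mask, so
#' that the texture summary reflects the cell and not the background. All
#' other pixels are `NA`.
#'
#' @param gray H x W numeric matrix (cropped cell, see [rgbToGray()])
#' @param mask logical matrix of the same dimensions
#' @param maskOnly restrict codes to in-mask pixels (default `TRUE`); set
#'   `FALSE` for full-crop labelling
#' @return H x W integer matrix of codes, `NA` where excluded
#' @export
ldpLabelImage <- function(gray, mask, maskOnly = TRUE) {
  stopifnotMask(mask)
  if (!identical(dim(gray), dim(mask)))
    stop("gray and mask dimensions differ", call. = FALSE)
  if (!any(mask)) emptyCellStop()
  resp <- kirschResponses(gray)
  nr <- nrow(gray); nc <- ncol(gray)
  valid <- matrix(FALSE, nr, nc)
  valid[2:(nr - 1L), 2:(nc - 1L)] <- TRUE
  if (maskOnly) valid <- valid & mask
  codes <- matrix(NA_integer_, nr, nc)
  idx <- which(valid)
  if (length(idx)) {
    stack <- vapply(resp, function(m) m[idx], numeric(length(idx)))
    stack <- matrix(stack, ncol = 8L)
    codes[idx] <- apply(abs(stack), 1L, function(a) {
      top <- order(-a, seq_len(8L))[1:3]
      sum(bitwShiftL(1L, top - 1L))
    })
  }
  codes
}

#' LDP histogram of a labelled image
#'
#' Relative frequency of each LDP code over the valid (non-`NA`) pixels.
#' The full histogram spans the inclusive code range 7..224 (218 bins);
#' only the 56 codes with exactly three set bits can carry mass. The
#' reduced histogram reads the full one out at `binList`.
#'
#' @param labeled integer matrix from [ldpLabelImage()]
#' @param binList integer codes of the reduced histogram (default
#'   [ldpDefaultBins()])
#' @return list with `counts` (integer, named by code), `full` (218
#'   relative frequencies) and `reduced` (named, `length(binList)`)
#' @export
ldpHistogram <- function(labeled, binList = ldpDefaultBins()) {
  codes <- labeled[!is.na(labeled)]
  if (!length(codes)) emptyCellStop()
  counts <- tabulate(codes - 6L, nbins = 218L)   # bin 1 <-> code 7
  names(counts) <- as.character(7:224)
  full <- counts / sum(counts)
  reduced <- full[as.character(binList)]
  names(reduced) <- paste0("LDP_", binList)
  list(counts = counts, full = full, reduced = reduced)
}

#' Select prominent LDP bins from count histograms
#'
#' Averages raw count histograms across images and returns the codes whose
#' average count exceeds `threshold`, sorted ascending. Applied to a large
#' corpus with threshold 400 this is how the default 14-bin list was
#' derived. Set `perImage = TRUE` to require the threshold in every image
#' instead of on the average.
#'
#' @param histograms list of count vectors named by code (the `counts`
#'   element of [ldpHistogram()])
#' @param threshold minimum (average) count, exclusive
#' @param perImage apply the threshold per image rather than to the average
#' @return integer vector of codes, ascending (possibly empty)
#' @export
selectProminentBins <- function(histograms, threshold = 400,
                                perImage = FALSE) {
  if (!length(histograms)) stop("need at least one histogram", call. = FALSE)
  mat <- do.call(rbind, histograms)
  keep <- if (perImage) apply(mat > threshold, 2L, all)
          else colMeans(mat) > threshold
  sort(as.integer(colnames(mat)[keep]))
}

#' Extract the 20-feature vector of a segmented cell
#'
#' Assembles, in the frozen order of [featureNames()]: the three geometric
#' features ([cellArea()], [lengthVar()], [compactness()]), the three HSI
#' colour variances over the cell pixels, and the reduced LDP histogram of
#' the cell texture. The LDP part is computed on the luma of the image
#' cropped to the mask bounding box, restricted to in-mask pixels, which
#' makes all features invariant to translating the cell within the frame.
#'
#' @param img H x W x 3 RGB array in \[0,255\]
#' @param mask logical matrix of matching size (refined cell mask)
#' @param binList reduced-LDP bins (default [ldpDefaultBins()])
#' @return named numeric vector of length `6 + length(binList)`
#' @export
extractFeatures <- function(img, mask, binList = ldpDefaultBins()) {
  img <- validateRGBImage(img)
  stopifnotMask(mask)
  if (!identical(dim(img)[1:2], dim(mask)))
    stop("image and mask dimensions differ", call. = FALSE)
  if (!any(mask)) emptyCellStop()
  hsi <- rgbToHSI(img)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  cropGray <- rgbToGray(img[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE])
  cropMask <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  hist <- ldpHistogram(ldpLabelImage(cropGray, cropMask), binList = binList)
  out <- c(Area = as.numeric(cellArea(mask)),
           Length_var = lengthVar(mask),
           Comp = compactness(mask),
           colorVariances(hsi, mask),
           hist$reduced)
  names(out) <- featureNames(binList)
  out
}
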