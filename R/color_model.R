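#' Read an RGB smear image
#'
#' Reads a PNG, TIFF or BMP raster into an H x W x 3 integer array with
#' channel values in \[0,255\] (the `RGBImage` convention used throughout the
#' package). Grayscale rasters are replicated across the three channels; an
#' alpha channel, if present, is dropped.
#'
#' @param path path to an existing raster file
#' @return H x W x 3 integer array, channels in \[0,255\]
#' @seealso [writeRGBImage()], [rgbToHSI()]
#' @export
readRGBImage <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3L), dim = c(dim(dat), 3L))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]
  if (dim(dat)[3] != 3L)
    stop("expected an RGB (or grayscale) image, got ", dim(dat)[3],
         " channels", call. = FALSE)
  # EBImage stores x (width) first; internal convention is rows = height
  px <- aperm(dat, c(2L, 1L, 3L))
  storage.mode(px) <- "double"
  px <- round(px * 255)
  px[px < 0] <- 0; px[px > 255] <- 255
  storage.mode(px) <- "integer"
  validateRGBImage(px)
}

#' Write an RGB image or a binary mask
#'
#' `writeRGBImage()` writes an H x W x 3 \[0,255\] array as an 8-bit-per-channel
#' raster; `writeMask()` writes a logical mask as a 0/255 grayscale PNG.
#'
#' @param img H x W x 3 integer array, channels in \[0,255\]
#' @param path output path; format follows the file extension (png/tiff/bmp)
#' @return `path`, invisibly
#' @export
writeRGBImage <- function(img, path) {
  img <- validateRGBImage(img)
  dat <- aperm(img, c(2L, 1L, 3L)) / 255
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path,
                      bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeRGBImage
#' @param mask logical matrix
#' @export
writeMask <- function(mask, path) {
  stopifnotMask(mask)
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask from a raster file
#'
#' Pixels with value > 0.5 (on the \[0,1\] scale) become `TRUE`.
#'
#' @param path path to a raster mask
#' @param provenance provenance tag to attach (default `"truth"`)
#' @return logical matrix
#' @export
readMask <- function(path, provenance = "truth") {
  img <- readRGBImage(path)
  setProvenance(img[, , 1] > 127, provenance)
}

validateRGBImage <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("an RGBImage must be an H x W x 3 array", call. = FALSE)
  if (dim(img)[1] < 3L || dim(img)[2] < 3L)
    stop("image must be at least 3 x 3", call. = FALSE)
  if (min(img) < 0 || max(img) > 255)
    stop("channel values must lie in [0,255]", call. = FALSE)
  img
}

# Core scalar-vectorised conversion on an N x 3 matrix of [0,255] RGB rows.
rgbMatrixToHSI <- function(rgb) {
  r <- as.numeric(rgb[, 1]); g <- as.numeric(rgb[, 2]); b <- as.numeric(rgb[, 3])
  s3 <- r + g + b
  intensity <- s3 / (3 * 255)
  mn <- pmin(r, g, b)
  sat <- ifelse(s3 == 0, 0, 1 - 3 * mn / s3)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  ratio <- ifelse(den == 0, 1, num / den)
  ratio <- pmin(1, pmax(-1, ratio))
  theta <- acos(ratio) * 180 / pi
  hue <- ifelse(b > g, 360 - theta, theta)
  hue[sat == 0 | den == 0] <- 0     # achromatic convention
  hue <- hue %% 360
  cbind(H = hue, S = sat, I = intensity)
}

#' Convert RGB to HSI
#'
#' Converts \[0,255\] RGB to the arccos chromatic-angle HSI model: intensity
#' \eqn{I = (R+G+B)/(3 \cdot 255)}, saturation
#' \eqn{S = 1 - \min(R,G,B)/\mathrm{mean}(R,G,B)} (0 for black), and hue
#' \deqn{\theta = \arccos\frac{\tfrac12[(R-G)+(R-B)]}
#'   {\sqrt{(R-G)^2+(R-B)(G-B)}}}
#' in degrees, reflected to \eqn{360-\theta} when \eqn{B > G}. Achromatic
#' pixels (\eqn{S = 0} or an undefined chromatic angle) take hue 0 by
#' convention. Hue is in \[0,360), saturation and intensity in \[0,1\].
#'
#' @param img an H x W x 3 RGB array in \[0,255\], or an N x 3 matrix of RGB
#'   rows
#' @return an object of the same shape with channels (H, S, I)
#' @export
rgbToHSI <- function(img) {
  if (is.matrix(img)) return(rgbMatrixToHSI(img))
  img <- validateRGBImage(img)
  d <- dim(img)
  flat <- rgbMatrixToHSI(matrix(as.numeric(img), ncol = 3L))
  array(flat, dim = d)
}

#' Convert HSI back to RGB
#'
#' Inverse of [rgbToHSI()]: the standard sector-wise reconstruction (hue
#' sectors \[0,120), \[120,240), \[240,360) degrees). Used by the synthetic
#' scene generator to paint sampled HSI tones. Output channels are clamped
#' to \[0,255\] and rounded when `integer = TRUE`.
#'
#' @param hsi N x 3 matrix of (H degrees, S, I) rows or an H x W x 3 array
#' @param integer round to 8-bit integers (default `TRUE`)
#' @return RGB values in the same shape as the input
#' @export
hsiToRGB <- function(hsi, integer = TRUE) {
  arr <- !is.matrix(hsi)
  if (arr) { d <- dim(hsi); hsi <- matrix(as.numeric(hsi), ncol = 3L) }
  h <- hsi[, 1] %% 360; s <- hsi[, 2]; i <- hsi[, 3]
  sector <- ifelse(h < 120, 0L, ifelse(h < 240, 1L, 2L))
  hh <- (h - 120 * sector) * pi / 180
  a <- i * (1 - s)
  bpart <- i * (1 + s * cos(hh) / cos(pi / 3 - hh))
  cpart <- 3 * i - (a + bpart)
  r <- g <- b <- numeric(length(h))
  k0 <- sector == 0L; k1 <- sector == 1L; k2 <- sector == 2L
  b[k0] <- a[k0]; r[k0] <- bpart[k0]; g[k0] <- cpart[k0]
  r[k1] <- a[k1]; g[k1] <- bpart[k1]; b[k1] <- cpart[k1]
  g[k2] <- a[k2]; b[k2] <- bpart[k2]; r[k2] <- cpart[k2]
  out <- cbind(R = r, G = g, B = b) * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  if (integer) out <- round(out)
  if (arr) out <- array(out, dim = d)
  out
}

#' Grayscale (luma) of an RGB image
#'
#' ITU-R BT.601 luma, `0.299 R + 0.587 G + 0.114 B`, on the \[0,255\] scale.
#' This is the gray image the LDP texture operator works on.
#'
#' @param img H x W x 3 RGB array in \[0,255\]
#' @return H x W numeric matrix in \[0,255\]
#' @export
rgbToGray <- function(img) {
  img <- validateRGBImage(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
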