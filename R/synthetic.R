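#' Default cell-tone ellipsoid for synthetic smears
#'
#' An axis-aligned discriminating region in the package's HSI convention
#' emulating a purple nuclear stain: hue 280 +/- 35 degrees, saturation
#' 0.5 +/- 0.18, intensity 0.38 +/- 0.14. Pale smear backgrounds (high
#' intensity, near-zero saturation) score far outside it.
#'
#' @return an [EllipsoidRegion-class] with `conventionTag = "gw-degrees"`
#' @export
syntheticToneRegion <- function() {
  EllipsoidRegion(diag(3), center = c(280, 0.5, 0.38),
                  semiAxes = c(35, 0.18, 0.14),
                  conventionTag = "gw-degrees")
}

#' Specification of a synthetic smear scene
#'
#' Collects the generating parameters of one scene. The default emulates a
#' single stained leukocyte on a pale background: an ellipse of roughly
#' 2400 px, cell tones drawn from [syntheticToneRegion()] at membership at
#' most `toneQuantile`, light background jitter, and optional speckle noise
#' (isolated cell-tone pixels scattered over the frame) and red granules
#' (off-region disks inside the cell emulating basophil granulation).
#'
#' @param imageSize `c(height, width)` in pixels
#' @param cells list of ellipses, each `list(center = c(row, col),
#'   axes = c(a, b), rotation = radians)`
#' @param toneRegion [EllipsoidRegion-class] the cell tones are drawn from
#' @param toneQuantile membership bound for cell tones, in (0,1)
#' @param backgroundRGB mean background colour, \[0,255\]
#' @param backgroundJitter uniform per-channel jitter amplitude
#' @param speckleFraction fraction of image pixels replaced by cell-tone
#'   speckles, in \[0, 0.2\]
#' @param granuleDensity fraction of each cell's area covered by granule
#'   disks, in \[0, 1\]
#' @param granuleRadius granule disk radius in pixels
#' @param seed integer seed; fixes the scene bit-exactly
#' @return a named list of class-checked generating parameters
#' @export
sceneSpec <- function(imageSize = c(120L, 120L),
                      cells = list(list(center = c(60, 60),
                                        axes = c(30, 24),
                                        rotation = 0.4)),
                      toneRegion = syntheticToneRegion(),
                      toneQuantile = 0.7,
                      backgroundRGB = c(235, 230, 240),
                      backgroundJitter = 4,
                      speckleFraction = 0.01,
                      granuleDensity = 0,
                      granuleRadius = 2L,
                      seed = 1L) {
  if (toneQuantile <= 0 || toneQuantile >= 1)
    stop("toneQuantile must lie in (0,1)", call. = FALSE)
  if (speckleFraction < 0 || speckleFraction > 0.2)
    stop("speckleFraction must lie in [0, 0.2]", call. = FALSE)
  if (granuleDensity < 0 || granuleDensity > 1)
    stop("granuleDensity must lie in [0, 1]", call. = FALSE)
  list(imageSize = as.integer(imageSize), cells = cells,
       toneRegion = toneRegion, toneQuantile = toneQuantile,
       backgroundRGB = backgroundRGB, backgroundJitter = backgroundJitter,
       speckleFraction = speckleFraction, granuleDensity = granuleDensity,
       granuleRadius = as.integer(granuleRadius), seed = as.integer(seed))
}

# Rasterize one ellipse into a logical matrix.
rasterizeEllipse <- function(nr, nc, center, axes, rotation) {
  rr <- matrix(seq_len(nr), nr, nc) - center[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  u <- rr * cos(rotation) + cc * sin(rotation)
  v <- -rr * sin(rotation) + cc * cos(rotation)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

# Draw n HSI rows with membership <= bound: truncated Gaussian in the
# region's rotated coordinates (rejection sampling).
sampleToneHSI <- function(region, n, bound) {
  out <- matrix(NA_real_, 0L, 3L)
  sd <- sqrt(bound) / 2
  while (nrow(out) < n) {
    k <- max(64L, 2L * (n - nrow(out)))
    u <- matrix(stats::rnorm(3L * k, 0, sd), k, 3L)
    keep <- rowSums(u^2) <= bound
    v <- sweep(u[keep, , drop = FALSE], 2L, region@semiAxes, "*")
    v <- sweep(v, 2L, region@center, "+")
    out <- rbind(out, v %*% region@rotation)   # x = R^T v
  }
  out[seq_len(n), , drop = FALSE]
}

# Draw n 8-bit RGB rows whose HSI (after quantization) still has
# membership <= bound under the region.
sampleToneRGB <- function(region, n, bound) {
  out <- matrix(NA_integer_, 0L, 3L)
  guard <- 0L
  while (nrow(out) < n) {
    hsi <- sampleToneHSI(region, 2L * (n - nrow(out)) + 16L, bound)
    rgb <- hsiToRGB(hsi)
    keep <- membership(region, rgbToHSI(rgb)) <= bound
    out <- rbind(out, rgb[keep, , drop = FALSE])
    guard <- guard + 1L
    if (guard > 200L)
      stop("tone sampling failed: region too small for 8-bit quantization",
           call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic smear scene
#'
#' Deterministically (given the spec's seed) paints background, cells,
#' speckle noise and granules, and returns the image together with the
#' exact ground-truth mask (the rasterised cell ellipses). Every cell
#' pixel's colour is drawn - and re-checked after 8-bit quantization - to
#' have membership at most `toneQuantile` under the spec's tone region;
#' granule disks deliberately violate that bound.
#'
#' @param spec a [sceneSpec()] list
#' @return a [SyntheticScene-class]
#' @export
generateScene <- function(spec) {
  nr <- spec$imageSize[1]; nc <- spec$imageSize[2]
  for (cell in spec$cells) {
    if (any(cell$center - max(cell$axes) < 1) ||
        cell$center[1] + max(cell$axes) > nr ||
        cell$center[2] + max(cell$axes) > nc)
      stop("impossible scene: cell does not fit inside the image",
           call. = FALSE)
  }
  withSeed(spec$seed, {
    truth <- matrix(FALSE, nr, nc)
    for (cell in spec$cells)
      truth <- truth | rasterizeEllipse(nr, nc, cell$center, cell$axes,
                                        cell$rotation)
    img <- array(0, dim = c(nr, nc, 3L))
    for (ch in 1:3) {
      jit <- stats::runif(nr * nc, -spec$backgroundJitter,
                          spec$backgroundJitter)
      img[, , ch] <- pmin(255, pmax(0, round(spec$backgroundRGB[ch] + jit)))
    }
    cellIdx <- which(truth)
    if (length(cellIdx)) {
      tones <- sampleToneRGB(spec$toneRegion, length(cellIdx),
                             spec$toneQuantile)
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[cellIdx] <- tones[, ch]
        img[, , ch] <- plane
      }
    }
    nSpeckle <- floor(spec$speckleFraction * nr * nc)
    if (nSpeckle > 0) {
      sp <- sample.int(nr * nc, nSpeckle)
      tones <- sampleToneRGB(spec$toneRegion, nSpeckle, spec$toneQuantile)
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[sp] <- tones[, ch]
        img[, , ch] <- plane
      }
    }
    if (spec$granuleDensity > 0 && length(cellIdx)) {
      gr <- spec$granuleRadius
      nGran <- ceiling(spec$granuleDensity * length(cellIdx) /
                         (pi * gr^2))
      centers <- cellIdx[sample.int(length(cellIdx), min(nGran,
                                                         length(cellIdx)))]
      gmask <- matrix(FALSE, nr, nc)
      for (ci in centers) {
        r0 <- ((ci - 1L) %% nr) + 1L
        c0 <- ((ci - 1L) %/% nr) + 1L
        rs <- max(1L, r0 - gr):min(nr, r0 + gr)
        cs <- max(1L, c0 - gr):min(nc, c0 + gr)
        d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
        gmask[rs, cs] <- gmask[rs, cs] | (d2 <= gr^2)
      }
      gmask <- gmask & truth
      gIdx <- which(gmask)
      if (length(gIdx)) {
        # red granules: hue far from the purple tone ellipsoid
        for (ch in 1:3) {
          base <- c(185, 40, 60)[ch]
          plane <- img[, , ch]
          plane[gIdx] <- pmin(255, pmax(0, round(
            base + stats::runif(length(gIdx), -15, 15))))
          img[, , ch] <- plane
        }
      }
    }
    storage.mode(img) <- "integer"
    new("SyntheticScene", image = img,
        truth = setProvenance(truth, "truth"), spec = spec)
  })
}

#' Sample labelled HSI pixels from a discriminating region
#'
#' Emulates collecting cell-tone pixels from expert-segmented images: `n`
#' HSI triples with membership at most `quantile` under `region`, drawn by
#' truncated-Gaussian rejection sampling in the region's rotated
#' coordinates.
#'
#' @param region an [EllipsoidRegion-class]
#' @param n number of pixel samples (>= 4)
#' @param quantile membership bound in (0,1\]
#' @param seed integer seed
#' @param sourceLabel free-text provenance recorded on the sample set
#' @return N x 3 matrix with columns H, S, I and attribute `sourceLabel`
#' @export
sampleRegionPixels <- function(region, n, quantile = 0.9, seed = 1L,
                               sourceLabel = "synthetic") {
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  out <- withSeed(seed, sampleToneHSI(region, n, quantile))
  colnames(out) <- c("H", "S", "I")
  attr(out, "sourceLabel") <- sourceLabel
  out
}

#' Generate a labelled synthetic feature data set
#'
#' Five Gaussian clusters in the 20-feature space, one per cell type, with
#' centroids `separation` latent standard deviations apart (the five
#' centroids sit on orthogonal latent axes, so all pairwise distances are
#' equal). Latent coordinates are mapped affinely onto physically plausible
#' feature scales and clipped to valid ranges (area positive, LDP
#' frequencies in \[0,1\]). `separation = 0` makes the classes
#' indistinguishable.
#'
#' @param nPerClass rows per cell type (>= 1)
#' @param separation centroid separation in latent sigma units
#' @param seed integer seed
#' @return data frame with a `label` column and the 20 feature columns of
#'   [featureNames()]
#' @export
generateFeatureDataset <- function(nPerClass = 50L, separation = 5,
                                   seed = 1L) {
  if (nPerClass < 1L) stop("nPerClass must be >= 1", call. = FALSE)
  classes <- wbcClassLabels()
  p <- 20L
  mu <- c(3000, 6, 18, 60, 0.004, 0.003, rep(0.06, 14L))
  sd <- c(150, 0.8, 1.2, 8, 6e-4, 5e-4, rep(0.008, 14L))
  withSeed(seed, {
    lat <- matrix(stats::rnorm(5L * nPerClass * p), ncol = p)
    for (k in seq_along(classes)) {
      rows <- ((k - 1L) * nPerClass + 1L):(k * nPerClass)
      lat[rows, k] <- lat[rows, k] + separation / sqrt(2)
    }
    x <- sweep(sweep(lat, 2L, sd, "*"), 2L, mu, "+")
    x[, 1] <- pmax(x[, 1], 1)                      # area > 0
    x[, 2:6] <- pmax(x[, 2:6], 0)
    x[, 7:20] <- pmin(pmax(x[, 7:20], 0), 1)       # LDP in [0,1]
    colnames(x) <- featureNames()
    data.frame(label = rep(classes, each = nPerClass), x,
               check.names = FALSE)
  })
}
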