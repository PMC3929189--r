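#' Classify pixels by discriminating-region membership
#'
#' Marks a pixel as a white-blood-cell pixel exactly when its HSI triple has
#' membership value at most 1 under the region (see [membership()]). If the
#' image and region carry different HSI convention tags a warning is issued;
#' the classification still runs.
#'
#' @param hsi H x W x 3 HSI array (output of [rgbToHSI()])
#' @param region an [EllipsoidRegion-class]
#' @param conventionTag tag describing `hsi`'s scaling (default the
#'   package's `"gw-degrees"`)
#' @return logical H x W matrix with provenance `"raw"`
#' @export
classifyPixels <- function(hsi, region, conventionTag = "gw-degrees") {
  stopifnot(is(region, "EllipsoidRegion"))
  if (!identical(region@conventionTag, conventionTag))
    warning("region convention '", region@conventionTag,
            "' differs from image convention '", conventionTag, "'",
            call. = FALSE)
  d <- dim(hsi)
  m <- membership(region, matrix(as.numeric(hsi), ncol = 3L))
  setProvenance(matrix(m <= 1, d[1], d[2]), "raw")
}

# 8-connected component labelling of a logical matrix.
# EBImage::bwlabel is 4-connected, so adjacency is built explicitly and
# components taken from the pixel graph.
labelComponents8 <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  for (s in shifts) {
    r2 <- row + s[1]; c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j]
    edges[[length(edges) + 1L]] <- cbind(idx[ok][keep], j[keep])
  }
  edges <- do.call(rbind, edges)
  vid <- match(seq_len(nr * nc), idx)      # pixel index -> vertex id
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(vid[edges[, 1]], vid[edges[, 2]]))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Morphological refinement of a raw cell mask
#'
#' Cleans the broken, noisy mask produced by pixel classification. The
#' default pipeline applies, in order: 3x3 dilation, 3x3 closing, a 7x7
#' median filter, hole filling, and removal of all but the largest
#' 8-connected foreground component. Element sizes and the
#' hole-fill/median order are configurable. An all-background mask is
#' returned unchanged (apart from the provenance tag).
#'
#' @param mask logical matrix (raw classification mask)
#' @param dilateSize,closeSize odd box-element sizes in pixels (default 3)
#' @param medianSize odd median-filter window size in pixels (default 7)
#' @param fillHolesFirst fill holes before the median filter instead of
#'   after (default `FALSE`)
#' @return logical matrix with provenance `"refined"`, containing no
#'   interior holes and at most one foreground component
#' @export
refineMask <- function(mask, dilateSize = 3L, closeSize = 3L,
                       medianSize = 7L, fillHolesFirst = FALSE) {
  stopifnotMask(mask)
  m <- EBImage::Image(t(mask) * 1)
  m <- EBImage::dilate(m, EBImage::makeBrush(dilateSize, "box"))
  m <- EBImage::closing(m, EBImage::makeBrush(closeSize, "box"))
  if (fillHolesFirst) m <- EBImage::fillHull(m)
  m <- EBImage::medianFilter(m, (medianSize - 1L) %/% 2L)
  m <- EBImage::fillHull(m)
  out <- t(EBImage::imageData(m) > 0.5)
  lab <- labelComponents8(out)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    out <- lab == which.max(sizes)
    out <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(out) * 1))) > 0.5)
  }
  setProvenance(out, "refined")
}

#' Segment one white blood cell from a smear image
#'
#' Full segmentation: convert to HSI, classify pixels against the
#' discriminating region, refine the mask morphologically, and crop the
#' image to the bounding box of the detected cell. If nothing is detected
#' the mask is empty and the crop is the full image.
#'
#' @param img H x W x 3 RGB array in \[0,255\]
#' @param region an [EllipsoidRegion-class]
#' @param ... refinement options passed to [refineMask()]
#' @return list with elements `mask` (refined, full image size), `crop`
#'   (RGB array over the mask bounding box), `cropMask` (mask over the same
#'   box) and `bbox` (`c(rmin, rmax, cmin, cmax)` or `NULL`)
#' @export
segmentCell <- function(img, region, ...) {
  img <- validateRGBImage(img)
  raw <- classifyPixels(rgbToHSI(img), region,
                        conventionTag = region@conventionTag)
  refined <- refineMask(raw, ...)
  if (!any(refined))
    return(list(mask = refined, crop = img, cropMask = NULL, bbox = NULL))
  rows <- range(which(rowSums(refined) > 0))
  cols <- range(which(colSums(refined) > 0))
  list(mask = refined,
       crop = img[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
       cropMask = setProvenance(
         refined[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE], "refined"),
       bbox = c(rows, cols))
}

#' Pixel-level segmentation metrics
#'
#' Confusion counts of a predicted mask against ground truth, plus
#' sensitivity `tp / (tp + fn)` (ability to find cell pixels) and
#' specificity `tn / (tn + fp)` (ability to reject background). A rate with
#' a zero denominator is defined as 1: with no positives (negatives) to
#' find, the test is vacuously perfect.
#'
#' @param pred,truth logical matrices of equal dimensions
#' @return list with `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`
#' @export
evaluateSegmentation <- function(pred, truth) {
  stopifnotMask(pred); stopifnotMask(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical dimensions", call. = FALSE)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  sens <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  spec <- if (tn + fp == 0L) 1 else tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
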