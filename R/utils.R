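# Internal helpers shared across modules.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Number of set bits in each element of an integer vector (values 0..255).
popcount8 <- function(x) {
  n <- integer(length(x))
  for (b in 0:7) n <- n + bitwAnd(bitwShiftR(as.integer(x), b), 1L)
  n
}

stopifnotMask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  invisible(mask)
}

# Tag helper: masks carry a provenance attribute ("raw", "refined", "truth").
setProvenance <- function(mask, what) {
  attr(mask, "provenance") <- what
  mask
}

#' Provenance of a binary mask
#'
#' Masks produced by this package are plain logical matrices carrying a
#' `provenance` attribute: `"raw"` straight from pixel classification,
#' `"refined"` after morphological cleanup, `"truth"` for ground truth.
#'
#' @param mask logical matrix
#' @return character scalar or `NA` if untagged
#' @export
maskProvenance <- function(mask) {
  p <- attr(mask, "provenance")
  if (is.null(p)) NA_character_ else p
}
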