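# Shared fixtures, built in code at test time.

# Independent scalar HSI reference: the arccos chromatic-angle formula
# written as plainly as possible, one pixel at a time.
refHSIpixel <- function(r, g, b) {
  i <- (r + g + b) / (3 * 255)
  mu <- (r + g + b) / 3
  s <- if (mu == 0) 0 else 1 - min(r, g, b) / mu
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  if (s == 0 || den == 0) return(c(0, s, i))
  th <- acos(max(-1, min(1, 0.5 * ((r - g) + (r - b)) / den))) * 180 / pi
  h <- if (b > g) 360 - th else th
  c(h %% 360, s, i)
}

# Filled digital disk mask of radius r centred in a (2r+pad)x(2r+pad) frame.
diskMask <- function(r, pad = 6L) {
  n <- 2L * r + pad
  ctr <- r + pad %/% 2L + 1L       # integer lattice centre
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- t(rr)
  rr^2 + cc^2 <= r^2
}

rectMask <- function(h, w, pad = 4L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# A flat-colour RGB image from a single (r,g,b) triple.
flatRGB <- function(nr, nc, rgb) {
  array(rep(as.integer(rgb), each = nr * nc), dim = c(nr, nc, 3L))
}

# Random orthonormal 3x3 matrix via QR, sign-fixed.
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q * sign(diag(qr.R(qr_)))[col(q)]
}
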