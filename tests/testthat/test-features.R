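test_that("area is the foreground pixel count", {
  expect_identical(cellArea(matrix(TRUE, 10, 10)), 100L)
  r <- 20
  byHand <- sum(outer((-30):30, (-30):30,
                      function(x, y) x^2 + y^2 <= r^2))
  expect_identical(cellArea(diskMask(r)), byHand)
  expect_error(cellArea(matrix(FALSE, 5, 5)), "empty cell")
})

test_that("boundary pixels are the 4-adjacent rim of the cell", {
  # 3x3 solid square: all but the centre pixel touch the rim
  sq <- rectMask(3, 3)
  len <- boundaryLengths(sq)
  expect_length(len, 8L)
  expect_setequal(round(sort(unique(len)), 10), round(c(1, sqrt(2)), 10))
  # large disk: boundary distances track the radius
  r <- 25
  lenD <- boundaryLengths(diskMask(r))
  expect_true(all(lenD >= r - 1.5 & lenD <= r + 0.5))
  # 1-pixel-thin line: every pixel is boundary
  line <- rectMask(1, 12)
  expect_length(boundaryLengths(line), 12L)
})

test_that("boundary-length variance separates round from elongated shapes", {
  r <- 30
  expect_lt(lengthVar(diskMask(r)), 0.5)
  rect <- rectMask(4, 40)
  diskEq <- diskMask(round(sqrt(160 / pi)))   # roughly equal area
  expect_gt(lengthVar(rect), lengthVar(diskEq))
  # constant hand-listed lengths give zero variance: the plus shape has
  # exactly 4 boundary pixels (the arm tips), all at distance 1
  plus <- matrix(FALSE, 5, 5)
  plus[3, 2:4] <- TRUE; plus[2:4, 3] <- TRUE
  expect_length(boundaryLengths(plus), 4L)
  expect_equal(sort(boundaryLengths(plus)), rep(1, 4))
  expect_equal(lengthVar(plus), 0)
})

test_that("compactness has its closed form on squares and orders shapes", {
  for (n in c(3, 10, 25)) {
    sq <- rectMask(n, n)
    expect_equal(compactness(sq), (4 * n - 4)^2 / n^2)
  }
  onePix <- matrix(FALSE, 3, 3); onePix[2, 2] <- TRUE
  expect_equal(compactness(onePix), 1)
  # at comparable area: disk < square < 10:1 rectangle
  disk <- diskMask(13)                        # area ~531
  sq <- rectMask(23, 23)                      # area 529
  rect <- rectMask(7, 73)                     # area 511, ~10:1
  expect_lt(compactness(disk), compactness(sq))
  expect_lt(compactness(sq), compactness(rect))
})

test_that("colour variances are population variances of the masked pixels", {
  img <- flatRGB(8, 8, c(120, 60, 180))
  mask <- rectMask(4, 4, pad = 2)
  expect_equal(unname(colorVariances(rgbToHSI(img), mask)), c(0, 0, 0))
  # two-tone: half hue 10, half hue 20 -> variance 25
  hsi <- array(0, dim = c(4, 4, 3))
  hsi[, 1:2, 1] <- 10; hsi[, 3:4, 1] <- 20
  full <- matrix(TRUE, 4, 4)
  expect_equal(unname(colorVariances(hsi, full))[1], 25)
  # random image against the direct formula
  set.seed(301)
  rnd <- array(runif(8 * 8 * 3, 0, 255), dim = c(8, 8, 3))
  hsiR <- rgbToHSI(rnd)
  got <- colorVariances(hsiR, mask)
  for (ch in 1:3) {
    v <- hsiR[, , ch][mask]
    expect_equal(unname(got[ch]), sum((v - mean(v))^2) / length(v),
                 tolerance = 1e-10)
  }
  expect_error(colorVariances(hsiR, matrix(FALSE, 8, 8)), "empty cell")
})

test_that("the Kirsch bank is the canonical rotation family", {
  ms <- kirschMasks()
  expect_length(ms, 8L)
  expect_identical(ms$M0, rbind(c(-3, -3, 5), c(-3, 0, 5), c(-3, -3, 5)))
  for (m in ms) {
    expect_equal(sum(m), 0)
    expect_identical(sort(as.numeric(m)), c(rep(-3, 5), 0, rep(5, 3)))
  }
  # each mask is the previous one rotated one ring step
  expect_identical(ms$M2, rbind(c(5, 5, 5), c(-3, 0, -3), c(-3, -3, -3)))
})

test_that("Kirsch responses equal a double-loop convolution oracle", {
  # flat field: all responses zero
  flat <- matrix(7, 6, 6)
  rFlat <- kirschResponses(flat)
  expect_true(all(vapply(rFlat, function(m) all(m[2:5, 2:5] == 0),
                         logical(1))))
  expect_true(all(is.na(rFlat$M0[1, ])))
  # vertical step edge: the horizontal-gradient masks dominate
  step <- cbind(matrix(0, 5, 3), matrix(100, 5, 2))
  rs <- kirschResponses(step)
  centre <- vapply(rs, function(m) abs(m[3, 3]), numeric(1))
  expect_true(which.max(centre) %in% c(1L, 5L))   # M0 (east) or M4 (west)
  # brute-force oracle on random patches
  set.seed(302)
  for (rep_ in 1:5) {
    patch <- matrix(runif(25, 0, 255), 5, 5)
    got <- kirschResponses(patch)
    ms <- kirschMasks()
    for (k in 1:8) for (r in 2:4) for (cc in 2:4) {
      acc <- 0
      for (u in 1:3) for (v in 1:3)
        acc <- acc + ms[[k]][u, v] * patch[r + u - 2, cc + v - 2]
      expect_equal(got[[k]][r, cc], acc)
    }
  }
  expect_error(kirschResponses(matrix(0, 2, 5)), "3 x 3")
})

test_that("LDP codes set the three most prominent direction bits", {
  expect_identical(ldpCode(c(9, 8, 7, 0, 0, 0, 0, 0)), 7L)
  expect_identical(ldpCode(c(0, 0, 0, 0, 0, 1, 2, 3)), 224L)
  expect_identical(ldpCode(rep(1, 8)), 7L)         # tie toward low bits
  expect_identical(ldpCode(c(-9, 8, -7, 0, 0, 0, 0, 0)), 7L)  # magnitude rank
  # every admissible code has popcount 3; there are C(8,3) = 56 of them
  codes <- Filter(function(cd) wbcKit:::popcount8(cd) == 3L, 0:255)
  expect_length(codes, 56L)
  expect_identical(range(codes), c(7L, 224L))
})

test_that("labelled images agree with per-pixel recomputation", {
  set.seed(303)
  gray <- matrix(runif(15 * 12, 0, 255), 15, 12)
  mask <- rectMask(9, 6, pad = 3)
  lab <- ldpLabelImage(gray, mask)
  expect_true(all(is.na(lab) | wbcKit:::popcount8(lab) == 3L))
  resp <- kirschResponses(gray)
  idx <- which(!is.na(lab), arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  for (i in sample(nrow(idx), 10)) {
    r <- idx[i, 1]; cc <- idx[i, 2]
    byHand <- ldpCode(vapply(resp, function(m) m[r, cc], numeric(1)))
    expect_identical(lab[r, cc], byHand)
  }
  # excluded pixels: outside the mask, or window off the image
  expect_true(all(is.na(lab[!mask])))
  # constant cell: everything collapses to the tie-break code
  flatLab <- ldpLabelImage(matrix(42, 10, 10), matrix(TRUE, 10, 10))
  expect_true(all(flatLab[!is.na(flatLab)] == 7L))
  expect_error(ldpLabelImage(gray, matrix(FALSE, 15, 12)), "empty cell")
})

test_that("LDP histograms are normalised relative frequencies on 218 bins", {
  lab <- matrix(NA_integer_, 4, 4)
  lab[2, 2] <- 7L
  h <- ldpHistogram(lab)
  expect_length(h$full, 218L)
  expect_identical(names(h$full)[1], "7")
  expect_identical(names(h$full)[218], "224")
  expect_equal(unname(h$full["7"]), 1)
  expect_equal(sum(h$full), 1)
  lab2 <- matrix(NA_integer_, 4, 4)
  lab2[1, 1:3] <- 7L; lab2[2, 1] <- 224L
  h2 <- ldpHistogram(lab2)
  expect_equal(unname(h2$full["7"]), 0.75)
  expect_equal(unname(h2$full["224"]), 0.25)
  expect_equal(sum(h2$full), 1, tolerance = 1e-9)
  # reduced histogram is a sub-vector of the full one
  expect_length(h2$reduced, 14L)
  expect_lte(sum(h2$reduced), 1)
  set.seed(304)
  lab3 <- matrix(sample(c(7L, 19L, 25L, 196L, NA), 100, TRUE), 10, 10)
  h3 <- ldpHistogram(lab3)
  expect_equal(sum(h3$full), 1, tolerance = 1e-9)
  expect_identical(unname(h3$reduced["LDP_19"]), unname(h3$full["19"]))
})

test_that("prominent-bin selection averages counts and applies the threshold", {
  h1 <- setNames(integer(218), 7:224)
  h1[c("19", "25")] <- c(500L, 300L)
  expect_identical(selectProminentBins(list(h1), 400), 19L)
  # threshold 0 returns every nonzero bin
  expect_identical(selectProminentBins(list(h1), 0), c(19L, 25L))
  # averaging two histograms equals the brute-force mean-then-filter
  h2 <- setNames(integer(218), 7:224)
  h2[c("19", "25", "224")] <- c(100L, 700L, 900L)
  got <- selectProminentBins(list(h1, h2), 400)
  avg <- (h1 + h2) / 2
  expect_identical(got, sort(as.integer(names(avg)[avg > 400])))
  # the shipped default list is the documented 14 bins
  expect_identical(ldpDefaultBins(),
                   c(19L, 25L, 35L, 38L, 49L, 50L, 70L, 76L, 98L, 100L,
                     137L, 140L, 145L, 196L))
})

test_that("extractFeatures assembles the 20 features in frozen order", {
  reg <- syntheticToneRegion()
  sc <- generateScene(sceneSpec(seed = 305, speckleFraction = 0))
  seg <- segmentCell(sc@image, reg)
  fv <- extractFeatures(sc@image, seg$mask)
  expect_length(fv, 20L)
  expect_identical(names(fv), featureNames())
  expect_gt(fv[["Area"]], 0)
  expect_true(all(fv[7:20] >= 0 & fv[7:20] <= 1))
  # each component equals its independent recomputation
  expect_equal(fv[["Area"]], as.numeric(cellArea(seg$mask)))
  expect_equal(fv[["Length_var"]], lengthVar(seg$mask))
  expect_equal(fv[["Comp"]], compactness(seg$mask))
  hsi <- rgbToHSI(sc@image)
  expect_equal(unname(fv[4:6]), unname(colorVariances(hsi, seg$mask)))
  cropG <- rgbToGray(seg$crop)
  h <- ldpHistogram(ldpLabelImage(cropG, seg$cropMask))
  expect_equal(unname(fv[7:20]), unname(h$reduced))
  # constant-colour disk cell: zero colour variances
  flat <- flatRGB(40, 40, c(110, 50, 140))
  dm <- diskMask(12, pad = 16)
  fvFlat <- extractFeatures(flat, dm)
  expect_equal(unname(fvFlat[4:6]), c(0, 0, 0))
})

test_that("features are invariant to translating the cell in the frame", {
  reg <- syntheticToneRegion()
  sc <- generateScene(sceneSpec(imageSize = c(140L, 140L),
                                cells = list(list(center = c(50, 50),
                                                  axes = c(22, 18),
                                                  rotation = 0.3)),
                                speckleFraction = 0, seed = 306))
  seg <- segmentCell(sc@image, reg)
  # shift image and mask by (dr, dc) with constant padding
  dr <- 15L; dc <- 22L
  img2 <- array(240L, dim = dim(sc@image))
  img2[(1:125) + dr, (1:118) + dc, ] <- sc@image[1:125, 1:118, ]
  mask2 <- matrix(FALSE, 140, 140)
  mask2[(1:125) + dr, (1:118) + dc] <- seg$mask[1:125, 1:118]
  f1 <- extractFeatures(sc@image, seg$mask)
  f2 <- extractFeatures(img2, mask2)
  # colour variances over the mask and all shape/texture features agree
  expect_equal(f2[c(1:3, 7:20)], f1[c(1:3, 7:20)])
  expect_equal(f2[4:6], f1[4:6], tolerance = 1e-12)
})
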