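test_that("a hidden node fires exactly on box containment", {
  box <- list(m = rep(0.2, 20), M = rep(0.8, 20))
  inside <- rep(0.5, 20)
  expect_identical(hrcnnHidden(inside, box), 1L)
  above <- inside; above[7] <- 0.9
  expect_identical(hrcnnHidden(above, box), 0L)
  onFace <- inside; onFace[3] <- 0.8       # boundary is inclusive
  expect_identical(hrcnnHidden(onFace, box), 1L)
  expect_error(hrcnnHidden(rep(0.5, 19), box), "dimension")
  # oracle equivalence on 1e4 random points
  set.seed(501)
  box2 <- list(m = runif(20, 0, 0.4), M = runif(20, 0.5, 1))
  xs <- matrix(runif(1e4 * 20), ncol = 20)
  got <- apply(xs, 1, hrcnnHidden, box = box2)
  want <- as.integer(wbcKit:::boxContains(box2, xs))
  expect_identical(got, want)
})

test_that("the class network is the disjunction of its boxes", {
  boxes <- list(list(m = c(0, 0), M = c(0.3, 0.3)),
                list(m = c(0.6, 0.6), M = c(1, 1)))
  model <- new("HRCNNModel", classes = c("a", "b"),
               boxes = list(boxes, list(list(m = c(0.4, 0.4),
                                             M = c(0.5, 0.5)))),
               eta = 0.5,
               scaling = list(min = c(0, 0), range = c(1, 1)),
               featureNames = c("x1", "x2"))
  expect_identical(hrcnnOutput(c(0.1, 0.2), model, "a"), 1L)
  expect_identical(hrcnnOutput(c(0.7, 0.9), model, "a"), 1L)
  expect_identical(hrcnnOutput(c(0.45, 0.45), model, "a"), 0L)
  expect_error(hrcnnOutput(c(0.1, 0.1), model, "zebra"), "unknown class")
  set.seed(502)
  for (i in 1:200) {
    x <- runif(2)
    anyBox <- any(vapply(boxes, function(b) all(x >= b$m & x <= b$M),
                         logical(1)))
    expect_identical(hrcnnOutput(x, model, "a"), as.integer(anyBox))
  }
})

test_that("covering training reproduces the hand-run 1-D example", {
  x <- matrix(c(0.1, 0.2, 0.9), ncol = 1)
  y <- c("A", "A", "B")
  m <- hrcnnTrain(x, y)
  a <- m@boxes[[match("A", m@classes)]]
  b <- m@boxes[[match("B", m@classes)]]
  expect_length(a, 1L)
  expect_length(b, 1L)
  # bounds on the raw scale (undo the stored min-max transform)
  aRaw <- a[[1]]$m * m@scaling$range + m@scaling$min
  expect_equal(as.numeric(aRaw), 0.1)
  expect_equal(as.numeric(a[[1]]$M * m@scaling$range + m@scaling$min), 0.2)
  expect_equal(as.numeric(b[[1]]$m * m@scaling$range + m@scaling$min), 0.9)
  expect_identical(hrcnnPredict(m, x), y)
})

test_that("covering training reaches 100% training accuracy", {
  # well-separated clusters
  d <- generateFeatureDataset(50, 5, seed = 503)
  clf <- hrcnnClassifier(d, d$label)
  expect_equal(clf@trainingReport$trainAccuracy, 1)
  ev <- evaluateClassifier(clf, d, d$label)
  expect_equal(ev$overallAccuracy, 1)
  # single training point per class -> degenerate point boxes
  one <- d[!duplicated(d$label), ]
  m1 <- hrcnnTrain(as.matrix(one[, -1]), one$label)
  expect_true(all(lengths(m1@boxes) == 1L))
  expect_identical(hrcnnPredict(m1, as.matrix(one[, -1])), one$label)
  # property: 100% training accuracy holds even with heavy class overlap
  for (sd_ in c(1, 2, 3)) {
    ov <- generateFeatureDataset(30, 0.5, seed = 503 + sd_)
    mOv <- hrcnnClassifier(ov, ov$label, seed = sd_)
    expect_equal(mOv@trainingReport$trainAccuracy, 1)
  }
  # contradictory duplicates are rejected
  xx <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE)
  expect_error(hrcnnTrain(xx, c("A", "B")), "inconsistent")
})

test_that("rules transcribe the boxes and round-trip predictions", {
  d <- generateFeatureDataset(20, 5, seed = 504)
  clf <- hrcnnClassifier(d, d$label)
  rules <- hrcnnRules(clf@model)
  expect_length(rules, sum(lengths(clf@model@boxes)))
  expect_true(all(grepl("^IF .* THEN ", rules)))
  # a single-box model yields exactly one rule with verbatim bounds
  x1 <- matrix(c(0.3, 0.6, 2, 2), 2, 2, byrow = TRUE)
  m1 <- hrcnnTrain(x1, c("A", "B"))
  r1 <- hrcnnRules(m1)
  expect_length(r1, 2L)
  backA <- hrcnnParseRules(r1[grepl("THEN A$", r1)])
  expect_equal(unname(backA@boxes[[1]][[1]]$m), c(0.3, 0.6))
  expect_equal(unname(backA@boxes[[1]][[1]]$M), c(0.3, 0.6))
  # re-parsing reconstructs identical predictions
  back <- hrcnnParseRules(rules, scaling = clf@model@scaling)
  set.seed(504)
  probe <- as.matrix(d[sample(nrow(d), 50), -1]) +
    matrix(rnorm(50 * 20, 0, 0.1), 50)
  colnames(probe) <- colnames(d)[-1]
  expect_identical(hrcnnPredict(back, probe), hrcnnPredict(clf@model, probe))
})

test_that("HRCNN predictions are invariant under the stored scaling round-trip", {
  d <- generateFeatureDataset(30, 5, seed = 505)
  clf <- hrcnnClassifier(d, d$label)
  x <- as.matrix(d[, -1])
  xs <- wbcKit:::hrcnnScale(clf@model, x)
  xBack <- sweep(sweep(xs, 2, clf@model@scaling$range, "*"), 2,
                 clf@model@scaling$min, "+")
  expect_identical(hrcnnPredict(clf@model, xBack), hrcnnPredict(clf@model, x))
})

test_that("the MLP has the promised architecture and is deterministic", {
  set.seed(506)
  x <- matrix(rnorm(40 * 20), 40, 20)
  y <- rep(c("a", "b"), each = 20)
  x[y == "b", ] <- x[y == "b", ] + 4
  clf <- mlpTrain(x, y, seed = 9, epochs = 300)
  expect_identical(clf@sizes, c(20L, 12L, 10L, 2L))
  expect_gte(clf@trainingReport$trainAccuracy, 0.99)
  # 20x12x10x5 parameter arithmetic
  d5 <- generateFeatureDataset(10, 5, seed = 506)
  clf5 <- mlpTrain(d5, d5$label, seed = 2, epochs = 50)
  expect_identical(mlpParameterCount(clf5), 437L)
  # same seed twice -> bitwise-identical predictions
  clfA <- mlpTrain(x, y, seed = 11, epochs = 100)
  clfB <- mlpTrain(x, y, seed = 11, epochs = 100)
  expect_identical(clfA@weights, clfB@weights)
  probe <- matrix(rnorm(200), 10, 20)
  expect_identical(predict(clfA, probe), predict(clfB, probe))
  expect_error(mlpTrain(x, rep("a", 40)), "2 classes")
  expect_error(predict(clfA, matrix(0, 2, 7)), "features")
})

test_that("the RBF-SVM separates well-separated clusters", {
  set.seed(507)
  x <- matrix(rnorm(60 * 20), 60, 20)
  y <- rep(c("a", "b"), each = 30)
  x[y == "b", ] <- x[y == "b", ] + 4
  clf <- svmTrain(x, y)
  xt <- matrix(rnorm(40 * 20), 40, 20)
  yt <- rep(c("a", "b"), each = 20)
  xt[yt == "b", ] <- xt[yt == "b", ] + 4
  expect_gte(evaluateClassifier(clf, xt, yt)$overallAccuracy, 0.99)
  # support vectors are (scaled) training points
  sv <- clf@fit$SV
  xs <- wbcKit:::zscoreApply(x, clf@scaling)
  hits <- apply(sv, 1, function(s)
    any(colSums(abs(t(xs) - s)) < 1e-10))
  expect_true(all(hits))
  expect_gte(clf@trainingReport$nSupportVectors, 1)
  expect_error(svmTrain(x, rep("a", 60)), "2 classes")
})

test_that("evaluation counts correct predictions exactly", {
  d <- generateFeatureDataset(2, 5, seed = 508)   # 10 rows
  clf <- hrcnnClassifier(d, d$label)
  ev <- evaluateClassifier(clf, d, d$label)
  pred <- predict(clf, d)
  expect_equal(ev$overallAccuracy, sum(pred == d$label) / nrow(d))
  expect_named(ev$perClassAccuracy)
  # single correctly-predicted example
  ev1 <- evaluateClassifier(clf, d[1, ], d$label[1])
  expect_equal(ev1$overallAccuracy, 1)
})

test_that("all three classifiers recover well-separated cell classes", {
  dtr <- generateFeatureDataset(200, 5, seed = 11)
  dte <- generateFeatureDataset(200, 5, seed = 1011)
  accs <- c(
    hrcnn = evaluateClassifier(hrcnnClassifier(dtr, dtr$label),
                               dte, dte$label)$overallAccuracy,
    svm = evaluateClassifier(svmTrain(dtr, dtr$label),
                             dte, dte$label)$overallAccuracy,
    mlp = evaluateClassifier(mlpTrain(dtr, dtr$label, seed = 1),
                             dte, dte$label)$overallAccuracy)
  expect_true(all(accs >= 0.95))
})

test_that("classifiers serialize to JSON model files and back", {
  d <- generateFeatureDataset(20, 5, seed = 509)
  probe <- as.matrix(generateFeatureDataset(5, 5, seed = 510)[, -1])
  for (train in list(function() hrcnnClassifier(d, d$label),
                     function() mlpTrain(d, d$label, seed = 3, epochs = 50),
                     function() svmTrain(d, d$label))) {
    clf <- train()
    f <- withr::local_tempfile(fileext = ".json")
    saveClassifier(clf, f)
    back <- loadClassifier(f)
    expect_identical(predict(back, probe), predict(clf, probe))
  }
})

test_that("stratified splitting honours the training fraction per class", {
  d <- generateFeatureDataset(90, 5, seed = 511)
  sp <- trainTestSplit(d$label, trainFraction = 299 / 450, seed = 4)
  expect_identical(sort(c(sp$train, sp$test)), seq_len(450L))
  perClass <- table(d$label[sp$train])
  expect_true(all(perClass == round(90 * 299 / 450)))
})
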