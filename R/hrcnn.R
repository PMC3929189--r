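#' Hidden-node output of a hyperrectangular composite network
#'
#' Evaluates one hidden node on an input vector:
#' \eqn{net_j(x) = \sum_i f((M_{ji}-x_i)(x_i-m_{ji})) - n} followed by the
#' hard threshold \eqn{f(y)=1} iff \eqn{y \ge 0}. Because each product term
#' is non-negative exactly when \eqn{m_{ji} \le x_i \le M_{ji}}, the node
#' fires exactly when the input lies inside the closed box `[m, M]`.
#'
#' @param x numeric input vector
#' @param box list with numeric vectors `m` (lower) and `M` (upper) of the
#'   same length as `x`
#' @return 0 or 1
#' @export
hrcnnHidden <- function(x, box) {
  if (length(x) != length(box$m) || length(x) != length(box$M))
    stop("input dimension does not match box dimension", call. = FALSE)
  n <- length(x)
  net <- sum(((box$M - x) * (x - box$m)) >= 0) - n
  as.integer(net >= 0)
}

#' Class-network output of an HRCNN
#'
#' Output node of the two-layer network for one class:
#' \eqn{Out(x) = f(\sum_j Out_j(x) - \eta)} with \eqn{\eta \in (0,1)}.
#' Since hidden outputs are binary this fires exactly when at least one of
#' the class's hyperrectangles contains `x`.
#'
#' @param x numeric input vector (raw feature scale; the model's stored
#'   min-max scaling is applied internally when `scaled = FALSE`)
#' @param model an [HRCNNModel-class]
#' @param class one of `model@classes`
#' @param scaled set `TRUE` if `x` is already in the model's \[0,1\] scale
#' @return 0 or 1
#' @export
hrcnnOutput <- function(x, model, class, scaled = FALSE) {
  stopifnot(is(model, "HRCNNModel"))
  k <- match(class, model@classes)
  if (is.na(k)) stop("unknown class: ", class, call. = FALSE)
  if (!scaled) x <- hrcnnScale(model, x)
  s <- 0L
  for (b in model@boxes[[k]]) s <- s + hrcnnHidden(x, b)
  as.integer(s - model@eta >= 0)
}

hrcnnScale <- function(model, x) {
  if (is.matrix(x))
    sweep(sweep(x, 2L, model@scaling$min), 2L, model@scaling$range, "/")
  else (x - model@scaling$min) / model@scaling$range
}

# All-inclusive containment of scaled rows in a box: logical vector.
boxContains <- function(box, xs) {
  if (!is.matrix(xs)) xs <- matrix(xs, nrow = 1L)
  ok <- rep(TRUE, nrow(xs))
  for (i in seq_along(box$m))
    ok <- ok & xs[, i] >= box$m[i] & xs[, i] <= box$M[i]
  ok
}

#' Train a hyperrectangular composite neural network
#'
#' Sequential-covering trainer. Features are min-max scaled to \[0,1\]
#' (scaling stored in the model). For each class, training points are
#' visited in order; each point is merged into the first existing box of
#' its class whose minimal expansion to include the point swallows no
#' point of any other class; if no box can absorb it, a new degenerate box
#' is started at the point. On consistently labelled data (no identical
#' vectors with different labels) every training point ends up covered by
#' a box of its own class and by no box of another class, so training-set
#' accuracy is 100% by construction.
#'
#' @param x numeric matrix of feature rows
#' @param y vector of class labels (character or factor), one per row
#' @param eta output threshold in (0,1); any value behaves identically
#' @param seed optional seed; when given, the visiting order of rows is
#'   shuffled reproducibly, otherwise input order is used
#' @return an [HRCNNModel-class]
#' @seealso [hrcnnRules()], [hrcnnClassifier()]
#' @export
hrcnnTrain <- function(x, y, eta = 0.5, seed = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  dup <- duplicated(x) | duplicated(x, fromLast = TRUE)
  if (any(dup)) {
    key <- apply(x, 1L, paste, collapse = "\r")
    if (any(tapply(y, key, function(l) length(unique(l))) > 1L))
      stop("inconsistent data: identical feature vectors with different labels",
           call. = FALSE)
  }
  fmin <- apply(x, 2L, min)
  frange <- apply(x, 2L, max) - fmin
  frange[frange == 0] <- 1
  xs <- sweep(sweep(x, 2L, fmin), 2L, frange, "/")
  ord <- seq_len(nrow(xs))
  if (!is.null(seed)) ord <- withSeed(seed, sample(ord))
  classes <- unique(y[ord])
  boxes <- vector("list", length(classes))
  names(boxes) <- classes
  for (cls in classes) {
    own <- ord[y[ord] == cls]
    others <- xs[y != cls, , drop = FALSE]
    blist <- list()
    for (ri in own) {
      p <- xs[ri, ]
      placed <- FALSE
      for (bi in seq_along(blist)) {
        b <- blist[[bi]]
        grown <- list(m = pmin(b$m, p), M = pmax(b$M, p))
        if (!any(boxContains(grown, others))) {
          blist[[bi]] <- grown
          placed <- TRUE
          break
        }
      }
      if (!placed) blist[[length(blist) + 1L]] <- list(m = p, M = p)
    }
    boxes[[cls]] <- blist
  }
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("x", seq_len(ncol(x)))
  new("HRCNNModel", classes = classes, boxes = unname(boxes), eta = eta,
      scaling = list(min = fmin, range = frange), featureNames = fn)
}

#' Predict class labels with an HRCNN model
#'
#' Runs every class network on each row. When several class networks fire,
#' the class owning the containing box of smallest volume wins (the most
#' specific rule); when none fires, the class of the nearest box under the
#' per-feature scaled distance
#' \eqn{\sum_i \max(0,\, m_i - x_i,\, x_i - M_i)^2} wins. Both rules are
#' deterministic (earlier class wins exact ties).
#'
#' @param model an [HRCNNModel-class]
#' @param x numeric feature matrix (raw scale) or single row vector
#' @return character vector of predicted labels
#' @export
hrcnnPredict <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  xs <- hrcnnScale(model, x)
  out <- character(nrow(xs))
  nC <- length(model@classes)
  for (r in seq_len(nrow(xs))) {
    p <- xs[r, ]
    bestVol <- rep(Inf, nC)
    bestDist <- rep(Inf, nC)
    for (k in seq_len(nC)) {
      for (b in model@boxes[[k]]) {
        if (all(p >= b$m & p <= b$M)) {
          bestVol[k] <- min(bestVol[k], prod(b$M - b$m))
        } else {
          d <- sum(pmax(0, pmax(b$m - p, p - b$M))^2)
          bestDist[k] <- min(bestDist[k], d)
        }
      }
    }
    out[r] <- if (any(is.finite(bestVol)))
      model@classes[which.min(bestVol)]
    else model@classes[which.min(bestDist)]
  }
  out
}

#' Read an HRCNN model as crisp If-Then rules
#'
#' One rule per hyperrectangle: "IF feature_i in \[m_i, M_i\] for all i THEN
#' class". Interval bounds are printed on the raw feature scale at full
#' double precision, so [hrcnnParseRules()] reconstructs a model with
#' identical predictions.
#'
#' @param model an [HRCNNModel-class]
#' @return character vector, one rule per box
#' @export
hrcnnRules <- function(model) {
  stopifnot(is(model, "HRCNNModel"))
  fmt <- function(v) sprintf("%.17g", v)
  rules <- character(0)
  for (k in seq_along(model@classes)) {
    for (b in model@boxes[[k]]) {
      lo <- b$m * model@scaling$range + model@scaling$min
      hi <- b$M * model@scaling$range + model@scaling$min
      cond <- paste(sprintf("%s in [%s, %s]", model@featureNames,
                            fmt(lo), fmt(hi)), collapse = " AND ")
      rules <- c(rules, sprintf("IF %s THEN %s", cond, model@classes[k]))
    }
  }
  rules
}

#' @rdname hrcnnRules
#' @param rules character vector produced by `hrcnnRules()`
#' @param eta output threshold of the reconstructed model
#' @param scaling optional min-max scaling (`list(min, range)`) of the
#'   original model. Rule semantics (which inputs fire) never depend on it,
#'   but the no-fire nearest-box fallback of [hrcnnPredict()] measures
#'   distances in scaled units, so supply the original scaling to reproduce
#'   predictions exactly; without it an identity scaling is assumed.
#' @return `hrcnnParseRules` returns an [HRCNNModel-class]
#' @export
hrcnnParseRules <- function(rules, eta = 0.5, scaling = NULL) {
  stopifnot(length(rules) > 0)
  parse1 <- function(rule) {
    body <- sub("^IF ", "", rule)
    cls <- sub("^.* THEN ", "", body)
    cond <- sub(" THEN .*$", "", body)
    terms <- strsplit(cond, " AND ", fixed = TRUE)[[1]]
    m <- regmatches(terms,
                    regexec("^(.*) in \\[([^,]+), ([^]]+)\\]$", terms))
    feats <- vapply(m, `[`, "", 2L)
    lo <- as.numeric(vapply(m, `[`, "", 3L))
    hi <- as.numeric(vapply(m, `[`, "", 4L))
    list(class = cls, features = feats, m = lo, M = hi)
  }
  parsed <- lapply(rules, parse1)
  classes <- unique(vapply(parsed, `[[`, "", "class"))
  feats <- parsed[[1]]$features
  if (is.null(scaling))
    scaling <- list(min = stats::setNames(rep(0, length(feats)), feats),
                    range = stats::setNames(rep(1, length(feats)), feats))
  boxes <- lapply(classes, function(cls) {
    lapply(Filter(function(p) p$class == cls, parsed),
           function(p) list(m = (p$m - scaling$min) / scaling$range,
                            M = (p$M - scaling$min) / scaling$range))
  })
  new("HRCNNModel", classes = classes, boxes = boxes, eta = eta,
      scaling = scaling, featureNames = feats)
}
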