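#' Version metadata block
#'
#' Identifies the package version, the frozen feature order and the report
#' format; embedded in every pipeline report and model file so outputs are
#' self-describing.
#'
#' @return named list with `package`, `packageVersion`,
#'   `featureOrderVersion` and `formatVersion`
#' @export
versionStamp <- function() {
  list(package = "wbcKit",
       packageVersion = as.character(utils::packageVersion("wbcKit")),
       featureOrderVersion = featureOrderVersion(),
       formatVersion = "1.0")
}

pipelineDefaults <- function() {
  list(seed = 1L,
       regionFile = NULL,          # NULL -> syntheticToneRegion()
       nScenes = 10L,
       imageSize = c(96L, 96L),
       toneQuantile = 0.7,
       speckleFraction = 0.01,
       granuleDensity = 0,
       classifier = "hrcnn",
       nPerClass = 50L,
       separation = 5,
       splitFraction = 299 / 450,
       mlpEpochs = 2000L,
       verbose = FALSE)
}

#' Read and validate a pipeline configuration
#'
#' Merges a JSON config file (or an R list) over the defaults; `overrides`
#' win over the file, mirroring command-line flags. Referenced files are
#' checked up front so a bad configuration fails before any processing.
#'
#' @param config path to a JSON file, a named list, or `NULL` for defaults
#' @param overrides named list applied last
#' @return validated configuration list
#' @export
readPipelineConfig <- function(config = NULL, overrides = list()) {
  cfg <- pipelineDefaults()
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config error: file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  if (!cfg$classifier %in% c("mlp", "svm", "hrcnn"))
    stop("config error: classifier must be mlp, svm or hrcnn", call. = FALSE)
  if (!is.null(cfg$regionFile) && !file.exists(cfg$regionFile))
    stop("config error: region file not found: ", cfg$regionFile,
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full white-blood-cell pipeline on synthetic data
#'
#' Executes the stages in their natural order - scene generation,
#' segmentation against the discriminating region, per-image evaluation,
#' feature-set generation, stratified train/test split, classifier
#' training and evaluation - and assembles a deterministic JSON-ready
#' report. Identical `(config, seed)` give byte-identical reports.
#'
#' @param config see [readPipelineConfig()]
#' @param outFile optional path; when given the report is written as JSON
#' @return the report list, invisibly when `outFile` is given
#' @export
runPipeline <- function(config = NULL, outFile = NULL) {
  cfg <- readPipelineConfig(config)
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  region <- if (is.null(cfg$regionFile)) syntheticToneRegion()
            else loadRegion(cfg$regionFile)
  subseeds <- withSeed(cfg$seed, sample.int(.Machine$integer.max - 1L,
                                            cfg$nScenes + 2L))
  say("stage: segmentation on ", cfg$nScenes, " synthetic scene(s)")
  perImage <- vector("list", cfg$nScenes)
  for (i in seq_len(cfg$nScenes)) {
    spec <- sceneSpec(imageSize = cfg$imageSize,
                      toneQuantile = cfg$toneQuantile,
                      speckleFraction = cfg$speckleFraction,
                      granuleDensity = cfg$granuleDensity,
                      cells = list(list(center = cfg$imageSize / 2,
                                        axes = c(26, 20),
                                        rotation = (i %% 7) / 3)),
                      seed = subseeds[i])
    scene <- generateScene(spec)
    seg <- segmentCell(scene@image, region)
    met <- evaluateSegmentation(seg$mask, scene@truth)
    perImage[[i]] <- list(scene = i, sensitivity = met$sensitivity,
                          specificity = met$specificity)
  }
  sens <- vapply(perImage, `[[`, numeric(1), "sensitivity")
  spec_ <- vapply(perImage, `[[`, numeric(1), "specificity")
  say("stage: classification (", cfg$classifier, ")")
  feats <- generateFeatureDataset(cfg$nPerClass, cfg$separation,
                                  seed = subseeds[cfg$nScenes + 1L])
  split <- trainTestSplit(feats$label, cfg$splitFraction,
                          seed = subseeds[cfg$nScenes + 2L])
  xtr <- feats[split$train, ]; xte <- feats[split$test, ]
  clf <- switch(cfg$classifier,
    mlp = mlpTrain(xtr, xtr$label, seed = cfg$seed,
                   epochs = cfg$mlpEpochs),
    svm = svmTrain(xtr, xtr$label, seed = cfg$seed),
    hrcnn = hrcnnClassifier(xtr, xtr$label))
  evTr <- evaluateClassifier(clf, xtr, xtr$label)
  evTe <- evaluateClassifier(clf, xte, xte$label)
  nTr <- length(split$train); nTe <- length(split$test)
  report <- list(
    version = versionStamp(),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "verbose")],
    segmentation = list(
      perImage = perImage,
      meanSensitivity = mean(sens),
      meanSpecificity = mean(spec_)),
    classification = list(
      classifier = cfg$classifier,
      nTrain = nTr, nTest = nTe,
      trainAccuracy = evTr$overallAccuracy,
      testAccuracy = evTe$overallAccuracy,
      overallAccuracy = (evTr$overallAccuracy * nTr +
                           evTe$overallAccuracy * nTe) / (nTr + nTe),
      perClassTestAccuracy = evTe$perClassAccuracy))
  if (!is.null(outFile)) {
    jsonlite::write_json(report, outFile, digits = NA, auto_unbox = TRUE,
                         null = "null")
    return(invisible(report))
  }
  report
}
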