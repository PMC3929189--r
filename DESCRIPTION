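Package: wbcKit
Title: Segmentation and Classification of White Blood Cells in Stained Smear Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building an automated differential white blood cell count
    from stained smear images. Leukocyte pixels are detected by membership in a
    rotated ellipsoidal discriminating region fitted to their tones in HSI colour
    space, masks are cleaned by morphological refinement, and each segmented cell
    is summarised by twenty features: three geometric (area, boundary-length
    variance, compactness), three colour variances (hue, saturation, intensity)
    and a fourteen-bin reduced local directional pattern (LDP) texture histogram
    built from Kirsch edge responses. Three classifiers map the feature vector to
    one of five cell types (lymphocyte, monocyte, basophil, eosinophil,
    neutrophil): a multilayer perceptron, a radial-basis-function support vector
    machine, and a hyperrectangular composite neural network whose trained
    weights read out as crisp If-Then interval rules. A synthetic smear-scene
    generator with exact ground-truth masks makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
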