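Package: vbmorph
Title: Vascular-Bundle Morphometry and Neural-Network Cultivar
    Classification from Leaflet Cross-Sections
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts nine vascular-bundle descriptors from leaflet
    cross-section images of date palm (Phoenix dactylifera) and
    classifies cultivars with a from-scratch multilayer perceptron.
    Covers the full chain: fluorescence-image preprocessing (channel
    extraction, thresholding, particle removal, contour tracing,
    periodic B-spline smoothing), minor-bundle distribution statistics
    (including a travelling-salesman tour ratio), major-bundle shape
    descriptors (form factor, aspect ratio, rectangularity,
    least-squares ellipse fit and eccentricity), batch-trained
    tanh/softmax neural network with repeated random-split
    cross-validation and permutation variable importance, and a
    seed-deterministic synthetic scene generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
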