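Package: veinrlf
Title: Finger-Vein Recognition via Mean Curvature and Radon-Like Feature
    Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Feature extraction, matching and verification for near-infrared
    finger-vein images. Veins appear as dark, smooth, curvilinear valleys in
    low-contrast images; the package enhances them with a mean-curvature
    valley response (half the divergence of the unit image gradient),
    aggregates the response with Radon-like features along eight families of
    scan lines segmented at Canny-edge knots, binarizes the mean feature
    image with Otsu's threshold, and matches binary vein patterns by
    margin-cropped sliding template matching. Includes genuine/impostor
    verification protocols with FAR/FRR curves and approximate equal error
    rate, a seeded generator of synthetic labelled vein-image datasets with
    ground-truth masks, database crop/resize presets, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
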