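Package: shootpheno
Title: Image-Based Drought Phenotyping of Plant Shoots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for image-based drought-stress
    phenotyping of single potted plants. Generates synthetic longitudinal
    drought-trial images with known ground truth, segments shoots by
    excess-green merging and Otsu thresholding, quantifies thirteen shape
    and colour traits (projected area, Feret caliper length, convex hull,
    minimum-area rectangle, minimum enclosing circle, contour perimeter,
    roundness, and per-channel colour variances), and evaluates treatment
    effects with quantile-regression outlier filtering, Kruskal-Wallis
    screening tables, and PCA / t-SNE embeddings of the trait space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    cluster,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
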