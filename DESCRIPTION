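Package: abcseg
Title: Brain Tumor Segmentation by Artificial Bee Colony Optimised Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Segments bright tumor regions in 2-D grayscale brain MR images by
    K-means-style pixel clustering whose cluster centroids are located with an
    Artificial Bee Colony (ABC) optimiser rather than Lloyd iterations alone.
    Provides the basic ABC, a best-guided modified variant, and a scalarised
    two-term clustering objective that balances worst-case intracluster
    compactness against intercluster separation; an intensity preprocessing
    chain (range adjustment, contrast, colour labelling); a synthetic brain
    phantom generator with ground-truth tumor masks; and confusion-matrix
    evaluation metrics with packaged reference benchmark tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
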