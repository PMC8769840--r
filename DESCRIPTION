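Package: wbcpipe
Title: Segmentation and Classification of White Blood Cells in Stained
    Blood Smear Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for locating and typing white blood cells in color
    microscopy images of stained blood smears. Nuclei are segmented by
    projecting each pixel's RGB vector onto a Gram-Schmidt weight vector
    that is orthogonal to the background and red-cell reference colors and
    maximally aligned with the purple nucleus stain, followed by histogram
    thresholding, fusion of three stain-robust projections, and
    small-object removal. Cells are described by from-scratch SIFT
    descriptors and features from a small convolutional network trained by
    backpropagation, and classified into the five leukocyte types with a
    weighted two-phase test-sample sparse representation (WTPTSSR)
    classifier. Includes segmentation-quality metrics (similarity, relative
    distance error, over/under-segmentation ratios), seeded synthetic-smear
    and feature-cluster generators, and an end-to-end evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
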