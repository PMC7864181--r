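Package: ifcmms
Title: Intuitionistic Fuzzy C-Means Segmentation with Membership
    Transfer and Similarity Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grayscale image segmentation by intuitionistic fuzzy C-means
    clustering with a membership information transfer model (median plus
    guided filtering of per-cluster membership maps between iterations)
    and an adaptive gray/distance similarity measurement (IFCM-MS).
    Includes a classical fuzzy C-means baseline, binary segmentation
    evaluation metrics (accuracy, precision, recall, specificity), a
    seeded synthetic brain-phantom generator with exact-count
    salt-and-pepper noise, PNG/TIFF image input and output, and a
    command-line interface for segmentation, evaluation, phantom
    generation and noise-grid sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
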