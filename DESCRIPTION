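Package: gfpsperm
Title: Quantification and Analysis of GFP-Sperm Occupancy in Insect
    Reproductive Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how much of an insect female reproductive
    tract is occupied by GFP-tagged sperm from two-channel fluorescence
    micrographs, and for analysing factorial sperm-storage experiments built
    on such measurements. The image-quantification chain performs
    rolling-ball background subtraction, reference-ROI autofluorescence
    crosstalk correction, intermodes histogram thresholding, and polygon-ROI
    occupancy metrics (mean/median intensity, percentage cover, presence).
    The inference stage fits identity-link Gaussian and logit-link
    quasi-binomial generalized linear models, assesses overdispersion,
    reduces models by likelihood-ratio tests on two-way interactions,
    and reports post-hoc contrasts, explained deviance and descriptive
    statistics. A seeded synthetic-data generator produces ground-truthed
    micrographs and simulated experiments so the whole pipeline is testable
    without any raw-data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
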