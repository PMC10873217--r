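Package: petgni
Title: Automated Global Noise Index Measurement for Whole-Body PET SUV Volumes
Version: 0.1.0
Authors@R:
    person("Imaging QC", "Maintainer", email = "qc@example.org", role = c("aut", "cre"))
Description: Fully automated measurement of global image noise in whole-body
    PET standardized-uptake-value (SUV) volumes. Patient tissue is segmented by
    thresholding, every axial slice is reduced to a macro-pixel noise map in
    which each 8x8 pixel block is summarized by its sample standard deviation,
    all macro-pixel noise values of the volume are pooled into a histogram, and
    the histogram mode is reported as the Global Noise Index (GNI). The package
    also provides the manual reference measurement (cubic volume-of-interest
    noise), a statistical validation battery (z-scoring, paired
    Kolmogorov-Smirnov permutation tests, Spearman correlation with a verbal
    interpretation scale, ROC/AUC with DeLong confidence intervals and
    Youden-optimal cutoffs), a synthetic whole-body phantom generator with
    known ground-truth noise, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
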