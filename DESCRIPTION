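Package: desiclass
Title: DESI Mass Spectrometry Imaging Tissue Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for desorption electrospray
    ionization mass spectrometry imaging (DESI-MSI) of annotated tissue
    sections: imzML slide input/output, lockmass recalibration, top-N peak
    selection and total-ion-current normalization, kernel-density m/z peak
    binning across slides, stratified region-of-interest sampling,
    PCA/LDA classification with leave-one-patient-out cross-validation,
    per-ion discrimination and volcano differential-abundance analysis,
    putative lipid annotation from monoisotopic deprotonated masses, and
    ion-image rendering. Includes a synthetic slide generator that
    emulates the statistical structure of a colorectal cancer DESI cohort
    so that every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mclust,
    png,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
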