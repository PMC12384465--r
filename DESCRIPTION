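Package: pericor
Title: Pericardial Composition-Change Biomarkers from Longitudinal CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies radiotherapy-induced changes in pericardial tissue
    composition from paired baseline/follow-up CT volumes. Builds the
    pericardial shell and an out-of-field reference ring from a heart mask,
    selects the best-matched follow-up scan by Hounsfield-unit histogram
    distance, converts dose grids to equivalent dose in 2 Gy fractions
    (EQD2), computes three voxel-wise imaging biomarkers (per-HU-change
    volume curves, per-tissue mass change, per-tissue volume change),
    harmonizes contrast-enhancement batch effects with a location/scale
    empirical-Bayes model, and relates biomarkers to dose and to survival
    and cardiovascular-event outcomes. Includes a synthetic phantom-cohort
    generator so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
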