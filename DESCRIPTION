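Package: cbctcorr
Title: Planning-CT-Based Intensity Correction of Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Corrects cone-beam CT (CBCT) volumes for scatter-induced
    cupping and Hounsfield-unit bias using the patient's planning CT as a
    prior: rigid registration, four-class tissue segmentation (air, lung,
    soft tissue, bone), per-class low-pass-filtered ratio fields on an
    attenuation-proportional scale, mask-based recombination, and
    completion of the truncated CBCT field of view from the planning CT.
    Includes a digital thorax/breast phantom simulator with ground-truth
    degradation fields, image-level evaluation metrics (HU error,
    histogram distances, water-equivalent path length), NIfTI and
    MetaImage I/O, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
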