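Package: tsau
Title: Focal and Diffuse Bone Marrow Uptake Scoring for FDG-PET/CT Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated scoring of skeletal and bone-marrow FDG uptake in
    PET/CT staging examinations. Derives a bone-marrow mask by per-bone
    physical erosion of a labelled skeletal segmentation, detects focal
    uptake with the total squared abnormal uptake (TSAU) statistic --
    per-group mean + 2 SD thresholding, watershed-based spill-over
    removal and a minimum-volume filter -- and quantifies diffuse
    marrow uptake as the ratio of median spine-marrow SUV to median
    liver SUV. Includes inter-observer agreement statistics (percentage
    agreement, Cohen's kappa, pairwise grids, majority vote), and a
    synthetic phantom generator with ground-truth manifests for
    end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
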