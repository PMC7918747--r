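Package: gazecourse
Title: Fixation Detection, Dynamic AOI Time Courses, and Cluster-Mass
    Permutation Tests for Infant Eye-Gaze Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for infant eye-tracking studies of face
    scanning: dispersion-threshold (I-DT) fixation detection from raw
    120 Hz gaze samples, assignment of samples and fixations to dynamic
    areas of interest that move with the stimulus face, trial exclusion
    rules, construction of trial- and condition-level looking variables
    and caregiver-experience classifications, 250 ms binned time courses
    of the lower-face-half preference, and a one-sample cluster-mass
    permutation test of that preference against chance. Includes a
    synthetic-session generator with known ground truth so every stage
    is testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
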