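Package: camcrm
Title: Weakly Supervised Surgical Component Localization by CAM Correction
    and Candidate Region Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for weakly supervised localization of
    surgical instruments and operated tissue targets in laparoscopic video
    frames. Corrects mislocated target attention guides by cyclic
    translation of class activation maps along the instrument's inferred
    forward direction, extracts preliminary boxes from positive activation
    components, filters and ranks scored candidate segmentation masks, and
    matches boxes to regions by Hungarian assignment under a class-gated
    complete-IoU cost. Includes detection AP/AR evaluation, a synthetic
    scene generator for end-to-end validation, displacement kernel density
    analysis, and shift-magnitude parameter sweeps. The deep networks that
    produce activation maps and candidate masks are treated as external
    input producers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
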