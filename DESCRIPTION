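Package: dermborder
Title: Border Irregularity Assessment for Dermoscopic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic assessment of skin-lesion border irregularity in
    dermoscopic colour images. Implements a full pipeline: removal of the
    black digitization frame and of dark thick hairs (black top-hat
    detection with shape discrimination and neighbourhood-mean inpainting),
    lesion segmentation by best-first seeded region growing of the healthy
    skin, rotation of the lesion so its principal axis is horizontal,
    construction of a one-dimensional borderline function from four
    per-quadrant distance-to-edge profiles joined with junction gap
    subtraction, Gaussian smoothing, and detection of irregularities as
    turning points (local maxima) of the smoothed signal. Includes the
    classical radial (centroid) distance curve as a baseline, ABCD border
    scoring with total dermoscopy score arithmetic, detection evaluation
    (sensitivity and precision with call-to-truth matching), and a
    synthetic phantom generator with exactly known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
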