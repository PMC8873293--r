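Package: couinaud3d
Title: Couinaud Liver-Segment Segmentation with a Dual-Branch 3D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated Couinaud segmentation of the liver on
    portal-venous-phase volumetric MR images. Implements the five-plane
    Couinaud protocol (three vertical planes along the hepatic veins, two
    horizontal planes through the portal-vein branches, and a caudate
    carve-out) as a geometric labeler, a dual-branch 3D U-Net that jointly
    predicts the liver boundary and a 9-class segment map, spacing and
    grayscale normalization with sliding-window patch inference, the
    standard quantitative segmentation metrics (Dice, mean surface
    distance, Hausdorff distance, volume ratio), a qualitative plane-shift
    grading rubric with inter-segment fault detection, lesion-to-segment
    localization, linearly weighted kappa, and a seeded synthetic liver
    phantom generator that provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
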