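Package: toothprop
Title: Slice-Propagation Segmentation of Individual Teeth in Dental CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomatic separation and segmentation of individual teeth from
    dental (cone-beam) CT volumes in which teeth and alveolar sockets are nearly
    isointense. From user-supplied seed points and a bounding box on a single
    reference axial slice, per-tooth intensity thresholds and shapes are
    propagated slice to slice: each slice is median-denoised, an optimal
    threshold is found by bisection under a shape-continuity constraint
    inherited from the neighbouring slice, teeth are grown by queue-based
    seeded region growing, interior holes caused by dark dentin and pulp are
    recovered by inverse region growing inside a bounding box, and leaks into
    socket bone are pruned against the dilated previous-slice mask, with an
    over-/under-segmentation retry loop. Includes NIfTI/NRRD/raw volume I/O, a
    synthetic dental-phantom generator with ground-truth labels, segmentation
    error metrics (false positive, false negative, volume and similarity
    errors), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
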