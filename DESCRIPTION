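Package: ffdseg
Title: Tri-Planar Free-Form Deformation for Template-Based
    Musculoskeletal Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deforms a labeled 3D template musculoskeletal volume onto a
    target 3D image using free-form deformation with three independent,
    plane-constrained cubic B-spline control lattices (axial, sagittal,
    coronal) whose displacement fields are composed in a fixed order, with
    coarse-to-fine lattice refinement and a topology check via the Jacobian
    determinant. Includes NRRD/NIfTI label-volume input and output, a
    scripted annotation-session workflow, a synthetic limb phantom
    generator for end-to-end testing, and the evaluation machinery for
    segmentation benchmarks: multi-label Dice, element volume error,
    per-participant summaries, k-fold grouping, and Wilcoxon signed-rank
    tests with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
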