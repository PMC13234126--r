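Package: dkparc
Title: Hierarchical Coarse-to-Fine Brain Parcellation from Diffusion MRI
    Scalar Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Desikan-Killiany-style brain parcellation computed
    directly from diffusion-weighted MRI. Fits the diffusion tensor by
    log-linear least squares, derives fractional anisotropy, trace, the
    Westin shape measures and eigenvalue maps, and segments the volume with
    a two-stage coarse-to-fine strategy: a first model predicts seven
    coarse anatomical compartments, then five compartment-specific models
    refine them into the final 101-label parcellation. Includes a
    backbone-agnostic training and sliding-window inference engine with a
    small trainable reference backbone, a connected-component
    post-processing chain, supervised (Dice, 95th-percentile Hausdorff) and
    label-free (relative standard deviation) evaluation metrics, and a
    synthetic diffusion phantom generator so the whole pipeline can be
    exercised end-to-end on a laptop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
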