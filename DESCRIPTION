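Package: optomo
Title: Sparse-View Optical Projection Tomography Reconstruction and
    Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, reconstruction and analysis of optical projection
    tomography (OPT) data under sparse angular sampling. Provides seeded
    digital vascular phantoms, a parallel-beam Radon forward model with its
    exact adjoint, filtered back projection, total-variation-regularised
    reconstruction by the two-step iterative shrinkage/thresholding (TwIST)
    algorithm with a Chambolle dual-projection TV denoiser, multiscale
    Hessian-based vesselness segmentation of vascular networks, and image
    quality scoring with the global structural similarity index (SSIM) and
    the Dice similarity index, together with an end-to-end experiment
    pipeline for angular down-sampling studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
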