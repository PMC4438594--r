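Package: trabstiff
Title: Trabecular Bone Morphometry and Voxel Micro-FE Stiffness from Micro-CT Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing trabecular bone microarchitecture and apparent
    stiffness from micro-CT image stacks of small-animal vertebrae. Provides
    density calibration against hydroxyapatite phantoms, global threshold
    segmentation, cylindrical trabecular region extraction, the standard 3D
    structural parameter panel (BV/TV, apparent BMD, Tb.Th, Tb.Sp, fractal
    dimension, Tb.Pf, degree of anisotropy, connectivity density) together with
    slice-wise 2D analogs along the caudal-cranial axis, difference-curve guided
    selection of a caudal sub-region, voxel-conforming hexahedral (hex8) linear
    elastic finite-element compression with a matrix-free conjugate-gradient
    solver, the normalized stiffness index k/k', nonparametric two-group study
    statistics, and seeded synthetic phantom generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
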