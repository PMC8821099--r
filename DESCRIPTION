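Package: dtialps
Title: Simulation and Analysis of Glymphatic Function with the DTI-ALPS Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying glymphatic function with the diffusion tensor
    image analysis along the perivascular space (DTI-ALPS) index. Provides a
    three-fiber periventricular digital phantom, Stejskal-Tanner forward
    simulation of diffusion-weighted MRI with Rician noise, log-linear
    diffusion tensor estimation, the ALPS fiber-voxel selection procedure and
    index formula, synthetic two-arm cohort generation (end-stage renal
    disease versus healthy controls) with clinical covariates coupled to
    perivascular diffusivity through a Gaussian copula, and the group
    comparison and clinical correlation statistics used in DTI-ALPS studies.
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
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
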