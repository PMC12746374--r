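Package: hpurea
Title: Pharmacokinetic Modeling of Dynamic Hyperpolarized 13C-Urea MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Compartmental pharmacokinetic modeling of dynamic hyperpolarized
    (HP) 13C-urea MRI. Implements forward simulation of HP urea signal under
    snapshot spoiled-gradient-echo sampling for three kinetic models (an
    extended-Tofts-like three-parameter model and two simplified two-parameter
    variants), bounded nonlinear least-squares parameter estimation with
    optional joint vascular-input-function (VIF) amplitude fitting,
    Monte-Carlo studies of acquisition settings, model-misspecification bias
    and noise, and a voxelwise fitting pipeline for dynamic image series with
    a synthetic phantom generator.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    deSolve,
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
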