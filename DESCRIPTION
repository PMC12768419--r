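Package: corneasim
Title: Agent-Based Simulation of Corneal Epithelial Homeostasis, Injury, and Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional cellular Potts (Glazier-Graner-Hogeweg) virtual
    tissue of the corneal limbus and peripheral cornea. Limbal stem, basal,
    wing and superficial cells arise by rule-based proliferation,
    contact-triggered differentiation and probabilistic desquamation on a
    200 x 90 voxel lattice, coupled to an epidermal growth factor (EGF)
    reaction-diffusion field with cell-type-dependent diffusivity. The package
    simulates tissue genesis and homeostasis, circular ablation and chemical
    injuries of graded dose, and quantifies thickness, stratification,
    turnover, transit and wound-healing dynamics as tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
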