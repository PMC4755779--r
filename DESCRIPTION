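Package: haplosterile
Title: Evolution of Non-Reproductive Workers in Haplodiploid Colonies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic colony-genetics model for the evolutionary
    invasion and stability of worker-sterility alleles in haplodiploid
    social insects with n-fold queen mating. Provides exact offspring and
    gamete-pool bookkeeping over queen-genotype by mating-composition
    colony types, the density-constrained selection dynamics as a system
    of ordinary differential equations, closed-form and Jacobian-based
    invasion and stability conditions for recessive and dominant sterility
    alleles, four-regime classification of the (colony efficiency)
    parameter space, phase-diagram grids, and Monte-Carlo plus analytic
    normal-CDF evaluation of outcome probabilities under random sampling
    of colony efficiencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
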