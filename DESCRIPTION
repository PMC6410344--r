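Package: nanotherm
Title: Plasmonic Nanoparticle Hyperthermia and Tumor Response Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates gold-nanoparticle mediated photothermal therapy of
    small spherical tumors from first principles: Mie absorption spectra of
    solid spheres and silica-core/gold-shell particles (with a surface
    scattering correction to the metal dielectric), Gans theory for prolate
    ellipsoids, nanoparticle diffusion and Pennes bioheat transfer on a
    radially symmetric grid, a three-state (alive/vulnerable/dead)
    hyperthermic cell-death model with constrained parameter estimation,
    and multi-session tumor shrinkage and regrowth prediction including an
    HSP90-inhibition growth variant. Includes synthetic viability and
    growth-curve generators for parameter-recovery studies and a
    config-driven end-to-end pipeline.
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
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
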