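Package: motordyn
Title: Structural Ensemble and Dynamics Analysis of Motor Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the conformational landscape and dynamic
    couplings of protein motor domains from crystal-structure ensembles and
    molecular dynamics trajectories. Implements interconformer principal
    component analysis of Cartesian covariance, iterated-superposition
    identification of the structurally invariant core, projection of
    trajectories onto crystallographic principal components, dynamical
    cross-correlation matrices, contact-filtered weighted-network community
    and betweenness analysis, hysteretic contact-event activity analysis
    with trajectory segmentation, and geometric order parameters (subdomain
    protrusion distance/angle, neck-linker docking state, interaction
    traces, secondary-structure content). Ships seed-deterministic
    synthetic-data generators so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
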