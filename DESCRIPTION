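Package: avidpmf
Title: Avidity Geometry and Free-Energy Post-Processing for Multimeric
    Antibody Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained ensembles of multimeric
    (IgM-class) antibodies and for umbrella-sampling free-energy data.
    Provides large-probe accessible surface area of antigen-binding loops,
    nearest-obstruction distances and simultaneous-binding probabilities,
    superposition-based ensemble metrics (RMSD in two fit modes, RMSF,
    principal component analysis, cutoff contacts, centre-of-mass distance
    series), and potential-of-mean-force estimation from umbrella windows
    by the weighted histogram analysis method with overlap diagnostics,
    integrated autocorrelation times and Bayesian bootstrap errors.  A
    synthetic-data module generates toy pentameric antibody ensembles with
    mobile Fab arms and exact Boltzmann samples from known one-dimensional
    potentials so the whole pipeline is testable without molecular
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
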