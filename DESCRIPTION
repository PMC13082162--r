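Package: heartfem
Title: Coupled Four-Chamber Heart Mechanics and Closed-Loop Circulation Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates beating-heart mechanics with a stabilized mixed (P1-P1)
    finite-element solver for active, incompressible, transversely isotropic
    myocardium, bidirectionally coupled to a closed-loop lumped-parameter model
    of the systemic and pulmonary circulations. Includes generators for
    idealized truncated-ellipsoid chamber meshes, rule-based myocardial fiber
    architecture (linear transmural helix), Robin (spring-damper) epicardial
    boundary conditions, time-varying-elastance chamber surrogates,
    pressure-volume loop metrics and myocardial strain waveforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
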