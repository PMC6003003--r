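Package: cardem
Title: Ventricular Electromechanics Under IKs Conductance Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation chain linking ventricular myocyte electrophysiology to
    pump function. Implements the ten Tusscher-Panfilov (2006) human ventricular
    ionic model with endocardial, mid-myocardial and epicardial variants and a
    scalable slow delayed rectifier (IKs) conductance; a Rice-style four-state
    crossbridge model converting the calcium transient into active tension,
    sarcomere-length dynamics and ATP consumption; a one-dimensional monodomain
    cable for conduction velocity and wavelength; and a lumped elastance-
    Windkessel surrogate ventricle for pressure-volume loop metrics (stroke
    volume, ejection fraction, stroke work, stroke work per unit ATP). A sweep
    driver paces each cell type across IKs conductance multipliers at fixed
    cycle length and summarises how action potential duration shortening
    propagates to calcium, tension, wavelength and pumping efficacy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
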