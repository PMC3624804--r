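Package: spedre
Title: Scalable Rate-Parameter Estimation for Mass-Action Networks in
    Data-Rich Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates rate constants of mass-action ordinary
    differential equation models of biochemical signalling networks
    when every molecular species is observed densely in time.  Spline
    curves fitted through the observed time courses supply interpolated
    derivatives; the estimation problem is then decomposed into a
    product of low-dimensional collocation error terms, one per
    experiment, species and timepoint.  Parameters are discretized into
    bins, each error term becomes a pre-computed joint probability
    look-up table via Boltzmann weighting, and a max-product loopy
    belief propagation variant yields MAP bin assignments, which are
    then refined by bounded Levenberg-Marquardt least squares on the
    simulate-and-match objective.  Includes a synthetic benchmark
    generator (ring networks, random low-degree networks, an Akt
    signalling topology), scoring metrics, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
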