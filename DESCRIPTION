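Package: cortdbs
Title: Population Pharmacokinetics Linking Plasma and Dried Blood Spot Cortisol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation tools for a hydrocortisone (cortisol)
    population pharmacokinetic model that links total plasma and dried blood
    spot (whole blood) concentrations through saturable binding to
    corticosteroid-binding globulin, linear binding to albumin, and a linear
    association with red blood cells. Provides the instantaneous
    binding-equilibrium model and its inversion, Michaelis-Menten absorption
    with two-compartment disposition acting on unbound drug, allometric
    scaling, log-normal interindividual variability with a Laplace-type
    marginal likelihood, sampling importance resampling for parameter
    uncertainty, visual predictive checks, and synthetic study generators
    emulating a rich adult and a sparse pediatric design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, jsonlite, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
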