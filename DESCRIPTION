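Package: fontansim
Title: Lumped-Parameter Simulation of the Fenestrated Fontan Circulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A zero-dimensional (lumped-parameter) model of the Fontan
    circulation with an atrial fenestration. Cardiac chambers follow a
    time-varying elastance model interpolating between exponential
    end-diastolic and linear end-systolic pressure-volume relations;
    systemic and pulmonary vascular beds are modified three-element
    Windkessel circuits with venous compliances; valves are ideal diodes
    with small series resistances; the fenestration obeys a simplified
    Bernoulli orifice law. The closed six-compartment ODE system is
    integrated with a fixed-step fourth-order Runge-Kutta scheme to a
    periodic steady state. The package reduces converged cycles to the
    clinical scalars (systolic/diastolic pressure, central venous
    pressure, cardiac index, shunt flows, arterial and venous oxygen
    saturations via a Fick shunt balance, vascular resistance indices in
    Wood units), tunes stressed blood volume to a systolic-pressure
    target, and runs paired fenestrated/non-fenestrated sweeps over
    fenestration diameter, pulmonary and systemic vascular resistance,
    ventricular end-systolic elastance and diastolic stiffness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
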