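Package: coldburst
Title: Conductance-Based Model of Cold-Sensing Neuron Bursting and Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Biophysical Hodgkin-Huxley-type simulator of Drosophila larva
    Class III cold-sensing neurons with a lumped thermoTRP current at two
    levels of description: a constant "TRP leak" conductance (level I) and a
    temperature-activated, calcium-inactivated dynamic conductance (level II).
    Provides temperature stimulation protocols (trapezoid sweeps,
    experimental-like fast/slow cooling, recorded-trace replay), stiff ODE
    integration with a compiled right-hand side, spike detection, burst
    segmentation and activity-pattern classification, two-parameter
    (conductance x temperature) activity maps with TRP-conductance trajectory
    projection, rate and magnitude sweeps, a TRP-parameter phenotype census,
    and seeded synthetic fixtures for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
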