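Package: preventsim
Title: Success-Rate-Oriented Simulation of Blood-Pressure Interventions and
    Cardiovascular Event Rates
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic population model comparing a high-risk prevention
    strategy (antihypertensive medication prescribed above a systolic
    blood-pressure threshold, attenuated by physician-consultation and
    adherence rates) with a population strategy (a metabolic-syndrome health
    promotion program modelled as a blood-pressure shift achieved by a
    successful fraction of the population). Cardiovascular incidence is the
    integral of a normal systolic blood-pressure density times an exponential
    dose-response risk function, evaluated by numerical quadrature and by
    closed form. Provides scenario grids over policy parameters, the reduction
    in incidence rate attributable to each intervention, the number of health
    checks needed to prevent one event per year, pointwise pre/post risk
    curves, CSV/JSON writers, figures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
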