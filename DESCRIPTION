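Package: canocom
Title: A Closed Carbon-Nitrogen Ecosystem Simulator Built on Dynamic
    Energy Budget Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a minimal closed-mass-balance ecosystem of
    nutrients (carbon dioxide and ammonia), a producer with two reserve
    compartments, a consumer, a decomposer and four detritus pools.  All
    living groups are modelled as V1-morph Dynamic Energy Budget (DEB)
    organisms in a mass-mass framework; substrate uptake, maintenance and
    growth are governed by synthesizing-unit (SU) rate laws, including
    demand-driven preference allocation between reserves and structure.
    Provides closed-form SU kinetics with a continuous-time Markov
    equilibrium oracle, an isomorph-to-V1 parameter conversion layer,
    seasonal temperature and irradiance forcing with Arrhenius rate
    correction, a stiff ODE integration driver with exact carbon and
    nitrogen closure, trajectory output and annual bloom-peak detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
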