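Package: cvloop
Title: Closed-Loop Hemodynamic Simulation of LVAD Cannulation in Heart
    Failure with Valvular Regurgitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter (0D) model of the systemic and pulmonary
    circulations coupled to a reduced cross-bridge model of ventricular
    contraction, with leaky-valve (regurgitation) flow laws and a
    continuous-flow ventricular assist device modeled as a flow generator.
    Supports calibration of a failing-heart baseline to a target stroke
    volume and ejection fraction, simulation of mitral or aortic
    regurgitation under left-atrium-to-aorta or left-ventricle-to-aorta
    cannulation, and a per-cycle metric panel (peak chamber pressures,
    pressure-volume loop stroke work, ejection fraction, cross-bridge ATP
    consumption rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
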