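Package: flymembrane
Title: Biophysics of the Fruit Fly Photoreceptor Membrane
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hodgkin-Huxley model of the voltage-dependent K+ conductances
    (Shaker, Shab and the Novel conductance) of Drosophila R1-6 photoreceptors,
    together with the steady-state ionic balance of the light-induced current,
    Na+/K+ pump and Na+/Ca2+ exchanger, the analytic small-signal RrLC membrane
    impedance, contrast gain, gain-bandwidth products and ATP energy accounting.
    Includes neuromodulation variants (serotonin, PIP2 depletion, calmodulin
    scaling of Shab), selective freezing of gating variables, time-domain
    current-pulse simulation, a simulation-based impedance estimator, and a
    deterministic calibration of the maximal conductances against the model's
    published operating anchors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
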