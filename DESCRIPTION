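Package: rpemetab
Title: Kinetic Modeling of Glucose and Lactate Exchange Between the Retinal
    Pigment Epithelium and Rod Photoreceptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a lumped kinetic model of glucose uptake, glycolysis,
    the pentose phosphate and Kennedy pathway branches, and MCT1-mediated
    lactate shuttling between the retinal pigment epithelium (RPE) and rod
    photoreceptors. Provides Hill-type regulatory switches that partition
    glucose between the two cell types, stiff ODE integration with
    steady-state detection, GLUT1-modulation parameter sweeps with
    relative-concentration normalization, in-silico knockout matching
    against relative metabolite intensities, one-at-a-time parameter
    sensitivity scans, and seeded generators for synthetic replicate
    time-series and knockout-cohort datasets used to exercise the
    validation workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
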