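Package: cvloop
Title: Multi-Scale Closed-Loop Cardiovascular Simulation and ESPVR Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a multi-scale model of the cardiovascular system in
    which left-ventricular contraction is generated by four-state
    troponin/cross-bridge kinetics of an equivalent half-sarcomere, mapped to
    ventricular pressure through a spherical ventricle and embedded in a
    six-chamber closed-loop lumped circulation with diode valves and a
    time-varying-elastance right ventricle. Provides in-silico experiment
    protocols (atrial hemorrhage, mitral and arterial load steps,
    contractility changes, isovolumic contractions, flow clamps), detection
    of end-systolic points on pressure-volume loops, iterative linear and
    nonlinear parabolic fitting of the end-systolic pressure-volume
    relationship (ESPVR) with curvature significance testing, and a
    stepwise simplex pipeline that identifies hemodynamic and ventricular
    geometry parameters from reference hemodynamic targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
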