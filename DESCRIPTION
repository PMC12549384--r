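Package: suctionfill
Title: Suction-Pressure and Filling-Yield Modelling of Die Filling on Tablet Presses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models die filling on rotary tablet presses and compaction
    simulators. Implements powder-characterization formulas (flow function
    coefficient, Carr compressibility index, Darcy-law air permeability),
    lower-punch kinematics for conventional and stearate fill cams
    (constant-velocity and three-phase polynomial pull-down profiles,
    instrumentation-report analysis with inverse-variance weighted pooling),
    a physics-based ordinary differential equation for the differential
    suction pressure inside the die during punch pull-down (solved with a
    stiff implicit Runge-Kutta method), and filling-yield analysis of
    tablet-weight experiments over turret-speed by paddle-speed grids.
    A synthetic-data generator produces punch reports and tablet-weight
    datasets with known ground truth for pipeline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
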