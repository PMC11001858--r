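Package: cowbc
Title: Outlet Boundary Conditions and Lumped-Parameter Simulation for
    Cerebrovascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating pressure-based outlet boundary conditions in
    models of the cerebral circulation. Reads and writes time-resolved flow and
    pressure waveform recordings at the inlets and outlets of the Circle of
    Willis, generates physiologically calibrated synthetic waveform sets,
    derives five outlet boundary-condition parameterisations (stationary zero
    pressure, symmetrical pressure, direct experimental pressure playback,
    two-element Windkessel, and a phase-modulated pressure waveform model),
    runs a transient zero-dimensional resistive-inertial network simulation of
    the Circle of Willis, and scores results with pulsatility indices, pulse
    pressures, total cerebral blood flow distributions, and (normalised) root
    mean squared deviations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
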