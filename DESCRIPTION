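Package: catchkin
Title: Kinematics of One-Handed Ball Catching: Simulation, Submovement
    Decomposition, and Mixed-Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying interceptive timing and inter-individual
    variability in one-handed ball catching. Simulates drag-affected ball
    flights and calibrates a virtual launcher by polynomial inversion;
    generates synthetic motion-capture trials (upper-limb markers at 100 Hz)
    whose wrist movements are built from minimum-jerk submovements; processes
    marker trajectories (zero-phase FIR filtering, differentiation, spline
    evaluation of the ball path at planes of interest); detects per-trial
    events (movement latency, impact time, speed extrema, tau-margin);
    computes interception-point geometry (normalized arrival height,
    interception index, posture angles, trunk displacement); decomposes wrist
    tangential speed into the minimal number of minimum-jerk submovements by
    multi-start constrained least squares and classifies movement types; and
    tests condition and subject effects with linear and generalized linear
    mixed models compared by AIC against fixed-effects-only fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    pracma,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
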