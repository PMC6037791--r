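Package: bodygoals
Title: Intrinsically Motivated Goal Discovery on a Simulated Tactile Body
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation of a planar agent -- a torso with two kinematic
    three-joint arms covered by touch sensors -- that autonomously discovers
    touch-outcome goals and learns the motor skills to reach them.  The
    architecture couples a competence-modulated self-organizing map that
    forms goal representations from positive touch changes, a softmax goal
    selector driven by competence improvement, a leaky echo-state network
    motor controller blended with sinusoidal motor babbling, and a delta-rule
    predictor of goal accomplishment that produces the competence-based
    intrinsic-motivation signals gating every learning process.  Includes a
    trial/simulation orchestrator, a random-movement baseline, analysis
    helpers (touch histograms, duration versus goal age, goal-formation
    history, epoch profiles) and a sensor-density variant of the body.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
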