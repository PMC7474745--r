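Package: passivetorque
Title: Passive Shoulder Joint Torque Estimation and Neural-Network
    Prediction from Robot-Guided Abduction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the passive (gravitational plus soft-tissue) torque of
    the human shoulder joint from logs recorded during robot-guided passive
    abduction with a 7-DoF serial manipulator, and predicts the full
    torque-angle field from sparse measurements.  Recovers the interaction
    wrench at the robot flange from external joint torques via the kinematic
    Jacobian, locates the shoulder rotation centre by least-squares sphere
    fitting, expresses posture as two globographic angles (plane of
    elevation, elevation), extracts the passive torque under quasi-static
    assumptions, and trains a three-layer sigmoid feedforward network with
    Levenberg-Marquardt backpropagation to interpolate the torque field.
    Includes a synthetic scene generator (rigid upper limb on a fixed-centre
    ball joint with a parametric passive torque field) so every pipeline
    stage can be exercised and validated without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
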