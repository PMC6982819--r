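Package: comgait
Title: Center-of-Mass Gait Dynamics and Lower-Limb Kinetics Prediction from a
    Single Sacral Accelerometer
Version: 0.1.0
Authors@R:
    person("comgait", "developers", email = "comgait@example.org",
           role = c("aut", "cre"))
Description: Sagittal-plane gait analysis built around the center of mass
    (CoM): a compliant spring-loaded inverted-pendulum walking simulator with
    an off-centered curvy foot, affine maps from CoM position to ground
    reaction forces, ankle torque and segment angles, a synthetic sacrum-IMU
    trial generator with ground-truth gait events and eleven label channels,
    an IMU preprocessing chain (zero-phase Butterworth filtering, heel-strike
    and toe-off detection, drift-removed integration, gait-speed offset
    regression, stance-phase resampling), planar link-segment inverse
    dynamics, and a small feed-forward network that predicts eleven lower-limb
    kinetic and kinematic channels, evaluated leave-one-subject-out.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
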