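Package: skipose
Title: Center-of-Mass and Ski Trajectory Reconstruction from a Single GNSS Antenna Track
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs an alpine skier's center of mass (COM) and both ski
    trajectories from the track of a single GNSS antenna worn behind the neck.
    Implements a dynamically balanced inverted-pendulum estimator (closed-form
    pendulum-angle solution, Kalman-smoothed angular acceleration, slope-mesh
    ray intersection, fixed-point refinement), plus two learned pose models
    mapping a three-dimensional trajectory query (radial acceleration, speed,
    tangent-plane skiing angle) to the nine-dimensional relative pose (COM and
    both skis): a locally weighted regression model with Gaussian receptive
    fields and a feedforward neural network. Includes a synthetic giant-slalom
    run generator whose balanced skier satisfies the pendulum model exactly,
    terrain utilities for elevation grids, and an evaluation protocol with
    path-normalized error curves, cross-validation tables and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
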