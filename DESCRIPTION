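Package: antkin
Title: Whole-Body Kinematic Modeling and Uncertainty Propagation for Ant
    Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds constrained multibody kinematic models of walking
    insects from fitted joint geometry, solves marker-based inverse
    kinematics over a gait cycle, and quantifies how uncertainties in
    marker placement and joint geometrical parameters propagate to joint
    angles.  Joint centers and hinge axes are estimated by least-squares
    sphere fitting of articular-surface point clouds; segment coordinate
    systems follow standard biomechanics conventions.  Marker trajectories
    are read from C3D or TRC files, low-pass filtered with zero-phase
    Butterworth filters, resampled and cropped to a gait cycle.  Inverse
    kinematics minimizes the weighted least-squares marker distance under
    range-of-motion bounds.  Monte Carlo simulation with uniform spherical
    and cylindrical uncertainty zones yields coverage intervals and a
    per-degree-of-freedom signal-to-noise ratio.  A synthetic hexapod
    generator provides fully known test data for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
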