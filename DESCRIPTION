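Package: arthropose
Title: Simulation-Free Repositioning of Finite-Element Human Body Models
Version: 0.1.0
Authors@R:
    person("Arthropose", "Developers", email = "arthropose@example.org",
           role = c("aut", "cre"))
Description: Repositions finite-element human body models in a dummy-like
    manner from pose parameters, without running a physics solver. Skeletons
    are reconfigured along geometry-derived joint trajectories: the
    tibiofemoral flexion path is integrated from instantaneous helical axes
    computed via discrete (normal-cycle) curvature tensors on the femoral
    condyles, while ball and hinge joints use least-squares sphere and
    cylinder fits. Soft tissues follow by thin-plate-spline morphing with a
    morph-contact algorithm that removes bone/capsule penetrations and an
    optimization-based interface refinement. Includes LS-DYNA keyword file
    input/output, hexahedral mesh-quality auditing (scaled Jacobian, warpage,
    aspect ratio), and analytic synthetic fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
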