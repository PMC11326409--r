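Package: psoct3d
Title: Three-Dimensional Fiber Axis and True Birefringence from Dual-Angle
    Polarization-Sensitive OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the three-dimensional optic-axis orientation and
    true (orientation-independent) birefringence of fibrous tissue from
    polarization-sensitive optical coherence tomography measurements taken
    under two illumination angles (normal and tilted by a small angle).
    A per-pixel birefringence-vector forward model links the true axis to
    the apparent birefringence and in-plane orientation seen by each beam;
    the axis is recovered by derivative-free least-squares minimization
    with an xy-axis swap for fibers running near the +/-90 degree seam.
    Includes retardance-slope and orientation-histogram preprocessing of
    depth-resolved A-line stacks, affine registration of the tilted view,
    synthetic phantoms emulating wedge, tilt-sweep and in-plane-rotation
    validation experiments, fiber orientation distribution (FOD) analysis,
    volume assembly, NIfTI vector export and a minimal streamline tracker.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
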