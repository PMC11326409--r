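---
title: "Reconstructing 3D fiber orientation and true birefringence from dual-angle PS-OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D fiber orientation and true birefringence from dual-angle PS-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoct3d)
```

## The measurement problem

Polarization-sensitive optical coherence tomography (PS-OCT) images
myelinated fiber tracts through their birefringence: the myelin sheath
makes white matter optically anisotropic, with the optic axis aligned with
the physical fiber direction. A single illumination beam, however, only
sees the *projection* of that axis onto its transverse plane. Two
quantities come out of a conventional acquisition per pixel:

* the apparent in-plane orientation $\Theta'$, the azimuth of the
  projected axis in the beam frame, on $[-90^\circ, 90^\circ)$; and
* the apparent birefringence $\Delta n' = \Delta n \sin^2\Psi$, where
  $\Psi$ is the polar angle between fiber axis and beam and $\Delta n$ the
  true (orientation-independent) birefringence.

A fiber tipping out of the imaging plane (through-plane angle $\alpha$,
with $\Psi = 90^\circ - \alpha$ for normal incidence) therefore looks
*dimmer* without being less myelinated, and its out-of-plane angle is
invisible. This package recovers the full 3D axis and $\Delta n$ from
measurements under just two illuminations: normal incidence
$p_1 = [0,0,1]^T$ and a second beam tilted by a small angle $\Omega$
(default $15^\circ$) about the $y$ axis, $p_2 = [\sin\Omega, 0,
\cos\Omega]^T$.

## The birefringence-vector model

The central object is the birefringence vector
$$
\Delta\mathbf{n} \;=\; \Delta n \,
[\cos\Theta\cos\alpha,\; \sin\Theta\cos\alpha,\; \sin\alpha]^T ,
$$
a 3-vector whose direction is the optic axis and whose magnitude is the
true birefringence. For any beam $p$ the model-predicted apparent vector is
the projection of $\Delta\mathbf{n}$ onto the plane orthogonal to $p$,
scaled once more by $\sin\Psi$:
$$
\widetilde{\Delta\mathbf{n}'}(p)
 = \left(\Delta\tilde{\mathbf{n}} - (p^T\Delta\tilde{\mathbf{n}})\,p\right)
   \sqrt{1 - \frac{(p^T \Delta\tilde{\mathbf{n}})^2}
                  {\lVert\Delta\tilde{\mathbf{n}}\rVert^2}} ,
$$
a vector of magnitude $\Delta n \sin^2\Psi$ pointing along the apparent
orientation in the laboratory frame. The measured pair
$(\Theta'_i, \Delta n'_i)$ of each beam embeds the same way (for the
normal beam, $\Delta n'_1 [\cos\Theta_1, \sin\Theta_1, 0]^T$; for a tilted
beam, the same azimuth expressed in that beam's transverse frame). The
per-pixel estimate minimizes
$$
\min_{\Delta\tilde{\mathbf{n}}}\;
\lVert \widetilde{\Delta\mathbf{n}'_1} - \Delta\mathbf{n}'_1 \rVert_2^2 +
\lVert \widetilde{\Delta\mathbf{n}'_2} - \Delta\mathbf{n}'_2 \rVert_2^2 .
$$

Two modeling points deserve emphasis:

* **The optic axis is a line, not a ray.** $v$ and $-v$ are the same
  physical axis, and the measured $\Theta'$ carries the same ambiguity.
  The objective therefore scores each residual against $\pm$ the measured
  vector and keeps the smaller distance, and every reported axis is
  canonicalized (first nonzero component of $[o_x, o_y, o_z]$ positive) so
  tests and downstream code see a unique representative.
* **The tilted transverse frame must stay orthogonal to the beam.** The
  package derives the measured-vector embedding from the beam's transverse
  frame vectors ($e_1 = [\cos\Omega, 0, -\sin\Omega]$, $e_2 = [0,1,0]$ for
  the $y$-tilt; $e_1 = [1,0,0]$, $e_2 = [0, \cos\Omega, \sin\Omega]$ for
  the $x$-tilt), which is algebraically forced by the projection form
  above. This keeps every apparent vector unit-consistent and orthogonal
  to its beam — a property the test suite checks directly.

## Why an xy-swap branch exists

Orientation noise is wrapped: a measurement at $\Theta = 89^\circ$
perturbed by $+3^\circ$ reads $-88^\circ$. For fibers running near
$\pm 90^\circ$ the noise distribution on $[-90, 90)$ becomes U-shaped
against the interval edges instead of approximately Gaussian, degrading
the least-squares fit. Pixels with $|\Theta_1| \ge 45^\circ$ (the boundary
inclusive) are therefore estimated in a laboratory frame rotated
$90^\circ$ about $z$ — $(x, y, z) \to (y, -x, z)$ — where the same fibers
lie near $0^\circ$ and the tilted beam becomes a tilt about $x$,
$p_3 = [0, -\sin\Omega, \cos\Omega]^T$. Results are rotated back before
canonicalization. With the sign-resolved objective the two branches are
exactly equivalent on noiseless data (the rotation is rigid), which the
tests exploit as a consistency check; the branch matters for how wrapped
noise enters, and the swap threshold (45°) is configurable in
`axis3d_control()`.

## Optimization choices

`fit_axis3d()` minimizes the objective over the unconstrained trial vector
with Nelder–Mead (`stats::optim`), the standard derivative-free simplex.
Numerical choices, all visible in `axis3d_control()`:

* **Scaling.** The problem is solved in units of
  $s = \max(\Delta n'_1, \Delta n'_2)$, so simplex geometry and stopping
  rules are scale-free. The default objective tolerance `ftol = 1e-20`
  (dimensionless$^2$) corresponds to $\sim 10^{-12}$ on the scaled
  objective at tissue-typical $\Delta n \sim 10^{-4}$ and is attainable in
  double precision.
* **Initialization.** The all-zero start sits exactly on the singularity
  of the projection formula ($\lVert\Delta\tilde{\mathbf{n}}\rVert = 0$),
  so the default start is closed-form: $\Theta$ from $\Theta_1$, and for
  each candidate inclination the magnitude implied by
  $\Delta n'_1 = \Delta n \cos^2\alpha$. A coarse scan over candidate
  inclinations ($2^\circ$ steps) picks the two best basins — one per
  inclination sign, because the magnitude comparison between beams
  determines the sign of $\alpha$ only over part of the range (it is
  uninformative for $\alpha \in (-\Omega/2, 0)$ and in the swapped
  branch, where the tilt is orthogonal to the fiber's in-plane direction
  and the sign is carried by $\Theta_2$ instead). Each start is polished
  by a simplex restart. A near-zero start (`init = "paper_zero"`,
  implemented as $[\varepsilon,\varepsilon,\varepsilon]$ with
  $\varepsilon = 10^{-8}$) is kept as a compatibility option.
* **Degeneracy.** A fiber parallel to a beam has $\Delta n' = 0$ and an
  undefined $\Theta'$ under that beam; that is a flagged condition, not an
  error. Pixels where *both* apparent birefringences fall below
  `dn_floor` (default $10^{-5}$, near the noise floor of typical
  acquisitions) are masked as unidentifiable rather than estimated. For
  noiseless synthetic studies the floor can be lowered; the exhaustive
  grid tests run with `dn_floor = 1e-8` so that steep, weakly birefringent
  corners of the grid ($\Delta n = 2\times10^{-4}$,
  $\alpha = \pm 80^\circ$, both $\Delta n' < 10^{-5}$) are exercised
  rather than masked.
* **Map fitting.** `fit_axis3d_map()` memoizes pixels with identical
  measurements, so homogeneous noiseless phantoms cost one optimization
  per distinct value; results are identical to the per-pixel loop.

An independent check, `brute_force_axis3d()`, evaluates the objective
exhaustively on a $(\Theta, \alpha, \Delta n)$ grid; the test suite
asserts the simplex never returns a worse objective than the grid
minimum.

## What the phantom generator does and does not emulate

`simulate_pair_map()` draws per-pixel measurements from the forward model
and adds (i) wrapped-Gaussian orientation noise (period 180°,
independently per beam — this reproduces the U-shaped edge distribution
that motivates the xy-swap) and (ii) truncated Gaussian relative noise on
the apparent birefringences (physical non-negativity). The preset
`experiment_design()` kinds reproduce the three study geometries on a
flat, uniform sample: wedge inclinations $\{0, -30, +30\}^\circ$ added
rigidly to $\alpha$; a tilt sweep $0\ldots50^\circ$ in $10^\circ$ steps;
and an in-plane rotation $0\ldots90^\circ$ in $30^\circ$ steps with
$\alpha = 0$. Default phantom conditions are $32\times32$ pixels,
$\Omega = 15^\circ$ and $\Delta n = 5\times10^{-4}$
($6.2\times10^{-4}$ for the wedge/birefringence analyses, a typical
corpus-callosum value).

The generator deliberately does **not** model speckle, depolarization,
depth-dependent SNR decay, refraction at the tissue surface, registration
error between the two views, or tissue heterogeneity. Passing the
synthetic validations therefore demonstrates the *estimator's* geometric
correctness and noise behavior under the stated noise model — not
robustness to every artifact of real acquisitions.

## Preprocessing conventions

* Apparent birefringence comes from an ordinary least-squares slope of the
  retardance profile over 150 µm below the surface;
  $\Delta n' = \text{slope} \cdot \lambda_0 / 360$ with the slope in
  deg/µm and $\lambda_0$ in µm (single-pass retardance; a `double_pass`
  flag halves round-trip input first). The slope is invariant to constant
  retardance offsets; windows with fewer than three samples are masked.
* En-face orientation is the peak of a 5°-bin histogram over the same
  window, with bin centers at multiples of the bin width (a constant 30°
  profile maps to exactly 30°) and wrap-aware binning, so clusters
  straddling $\pm90^\circ$ peak at the seam, never near 0. Ties break
  toward the circular mean.
* Surface detection is an input (index map, default $z = 0$): samples are
  flat-faced before imaging, so intensity-based surface finding is out of
  scope.
* Registration of the tilted view is affine-only: at $\Omega = 15^\circ$
  the dominant distortion is an affine foreshortening
  ($\cos 15^\circ \approx 0.966$ along $x$), which a translation-seeded
  (FFT cross-correlation) Nelder–Mead refinement of a 6-parameter affine
  against normalized cross-correlation recovers to sub-pixel accuracy on
  the test fixtures. Orientation maps are resampled nearest-neighbor —
  never linearly interpolated, which would corrupt axial angles across
  the $\pm90^\circ$ wrap — and corrected by the transform's rotation
  component.

## FOD analysis and volume products

Fiber orientation distributions are 5°-bin histograms over 0.5 mm windows
(windows are specified in millimeters so they rescale with pixel size; 50
pixels at the default 10 µm). The primary peak is refined by 3-point
parabolic interpolation — without refinement, 5° bins would quantize
validation statistics reported at 0.1° precision — and the FWHM by linear
interpolation at half peak height, both wrap-aware for in-plane angles.
Through-plane FODs live on the closed interval $[-90^\circ, 90^\circ]$
without wrap: inclination is not axial in this parameterization. ROI
summaries average peaks circularly (period 180) for in-plane angles and
arithmetically for inclinations, and carry the fraction of pixels excluded
by the low-birefringence mask (same configurable floor as the estimator).

Per-slice fits stack into volumes at 10 µm × 10 µm × 150 µm without
inter-slice alignment (blockface geometry). The NIfTI export writes the
axis field as a 4D volume plus a scalar birefringence volume, NIfTI-2 with
double-precision data and header so spacing and values round-trip exactly.
The bundled streamline tracker is intentionally minimal — fixed step
(default half the in-plane voxel), nearest-neighbor lookup, axial sign
chosen to minimize turning, 60° angular threshold, no intensity threshold
— because the reconstruction, not tractography, is this package's
contribution; the NIfTI export is the interop path to dedicated
tractography tools.

## Worked example

A noiseless tilt sweep, the package's central validation: the fitted slope
of recovered versus preset inclination should be 1.

```{r tilt-sweep}
ex <- run_experiment(
  experiment_design("tilt_sweep", seq(0, 50, by = 10), base_dn = 5e-4),
  phantom_spec(c(16, 16), omega_deg = 15))
ex
```

And a single pixel, fitted and inspected:

```{r single-pixel}
truth <- biref_vector(20, 40, 5e-4)
m1 <- apparent_from_true(truth, beam())
m2 <- apparent_from_true(truth, beam(15, "y"))
fit <- fit_axis3d(measurement_pair(m1$theta_app, m1$dn_app,
                                   m2$theta_app, m2$dn_app, 15))
summary(fit)
```

## Known limitations

* En-face only: the model assumes one axis per pixel across the depth
  window; depth-resolved (local) axis estimation is out of scope.
* Exactly two illuminations, the second tilted about one lateral axis;
  no refraction correction at the tissue surface is applied to the tilted
  beam geometry.
* Near $|\alpha| \to 90^\circ$ both apparent birefringences collapse
  toward zero, so noise inflates inclination estimates there; no bias
  correction is applied.
* The affine registration assumes the overlap is dominated by rigid +
  foreshortening distortion; strongly deformable misalignment is not
  handled.

## Problem sizes used in the shipped checks

The validation experiments in the test suite and the acceptance script use
$32\times32$ uniform phantoms per level (the grid-recovery check covers
$18 \times 17 \times 3 = 918$ orientation/birefringence combinations, and
the oracle comparison 50 noisy pixels against a 1° grid), sizes at which
every synthetic study reproduces its theoretical value to well within the
stated tolerances.
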