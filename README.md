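# psoct3d

Three-dimensional fiber-axis orientation and true birefringence from
dual-angle polarization-sensitive OCT (PS-OCT).

Conventional PS-OCT of fibrous tissue (brain white matter above all)
measures, per pixel, only an *apparent* birefringence and the *in-plane*
projection of the fiber axis. Fibers tipping out of the imaging plane look
dimmer — the apparent birefringence is `Δn·sin²Ψ`, with `Ψ` the angle
between fiber and beam — and their through-plane angle is lost entirely,
which makes both tractography and myelin quantification orientation-biased.
`psoct3d` recovers the full 3D axis and the orientation-independent true
birefringence from measurements under just **two** illumination angles:
normal incidence and a second beam tilted by a small angle Ω (default 15°).

The core is the *birefringence vector*

```
Δn = Δn · [cosΘ cosα,  sinΘ cosα,  sinα]ᵀ
```

(`Θ` in-plane orientation, `α` through-plane inclination, `Δn` true
birefringence). Each beam `p` sees the projection of this vector onto its
transverse plane, scaled by `sinΨ`; the per-pixel estimate minimizes

```
min_Δñ  ‖Δñ′₁ − Δn′₁‖² + ‖Δñ′₂ − Δn′₂‖²
```

over the trial vector by Nelder–Mead, where `Δñ′ᵢ = (Δñ − (pᵢᵀΔñ)pᵢ)·
√(1 − (pᵢᵀΔñ)²/|Δñ|²)` is the model prediction and `Δn′ᵢ` the measured
apparent vector of beam `i`. Fibers running near Θ = ±90° — where wrapped
orientation noise turns U-shaped — are estimated in a frame with x and y
interchanged (the xy-swap branch, engaged at |Θ₁| ≥ 45°). Around this
estimator the package provides:

- preprocessing: apparent birefringence from the retardance depth-slope
  (OLS over 150 µm), en-face orientation from 5° depth histograms, affine
  registration of the tilted view (TIFF + JSON sidecar I/O);
- a synthetic phantom generator reproducing the wedge, tilt-sweep and
  in-plane-rotation validation experiments, with wrapped-Gaussian
  orientation noise and truncated birefringence noise;
- fiber orientation distributions (0.5 mm windows, 5° bins, parabolic
  peak refinement, wrap-aware FWHM) and ROI summaries;
- volume assembly (10 µm in-plane / 150 µm slices), color-coded renderings,
  NIfTI vector export, and a minimal deterministic streamline tracker
  (60° angular threshold);
- a thin CLI (`inst/cli/psoct3d`) with verbs `simulate`, `preprocess`,
  `register`, `estimate`, `fod`, `stack`, `export`, `track`, `render`.

## Worked example

Forward-simulate one pixel with Θ = 20°, α = 40°, Δn = 5×10⁻⁴ under the
two beams, then invert it:

```r
library(psoct3d)

truth <- biref_vector(20, 40, 5e-4)
m1 <- apparent_from_true(truth, beam())          # normal incidence
m2 <- apparent_from_true(truth, beam(15, "y"))   # 15 deg tilt about y
m1; m2
#> apparent measurement (tilt 0 deg about 'none'): dn' = 0.0002934, theta' = 20.000 deg
#> apparent measurement (tilt 15 deg about 'y'): dn' = 0.0001742, theta' = 26.350 deg

fit_axis3d(measurement_pair(m1$theta_app, m1$dn_app,
                            m2$theta_app, m2$dn_app, omega_deg = 15))
#> axis3d fit (standard branch): dn = 0.0005, theta = 20.000 deg, alpha = 40.000 deg
#>   objective = 2.45e-39, converged = TRUE, 254 evaluations
```

The single beam sees only `Δn·cos²(40°) = 2.93×10⁻⁴` — 41% of the true
birefringence gone, and no sign of the 40° inclination; the two-beam fit
restores both exactly. The preset validation experiments run the same way
on image phantoms:

```r
run_experiment(experiment_design("wedge", c(0, -30, 30), base_dn = 6.2e-4),
               phantom_spec(c(16, 16)))
#> synthetic wedge experiment, 3 levels
#>  level mean_theta mean_alpha sd_alpha mean_dn n_valid
#>      0          0          0        0 0.00062     256
#>    -30          0        -30        0 0.00062     256
#>     30          0         30        0 0.00062     256
```

i.e. the estimator separates the ±30° wedges from baseline by exactly 30°
*with the correct signs*, while the recovered true birefringence stays at
6.2×10⁻⁴ regardless of inclination.

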