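## Synthetic phantoms: forward-model measurement pairs with the noise
## structure the estimator must survive, plus preset experiment designs
## emulating the wedge, tilt-sweep and in-plane-rotation validations.

#' Phantom specification
#'
#' Ground truth and noise model for a synthetic en-face measurement-pair
#' map. Truth fields may be scalars (uniform phantom) or matrices of the
#' grid shape.
#'
#' @param shape integer c(nx, ny).
#' @param theta,alpha,dn ground truth per pixel (scalar or matrix),
#'   degrees / degrees / dimensionless.
#' @param omega_deg tilt of the second beam, degrees.
#' @param noise_theta_deg wrapped-Gaussian sigma added to each beam's
#'   apparent orientation (period 180), degrees.
#' @param noise_dn_rel relative Gaussian sigma on each apparent
#'   birefringence, truncated so values stay non-negative.
#' @param seed integer RNG seed (reproducibility: identical spec + seed
#'   give bit-identical maps).
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(32, 32), theta = 0, alpha = 0, dn = 5e-4,
                         omega_deg = 15, noise_theta_deg = 0,
                         noise_dn_rel = 0, seed = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 1),
            noise_theta_deg >= 0, noise_dn_rel >= 0, omega_deg > 0)
  expand <- function(x) {
    if (is.matrix(x)) { stopifnot(all(dim(x) == shape)); x }
    else matrix(x, shape[1], shape[2])
  }
  structure(list(shape = as.integer(shape), theta = expand(theta),
                 alpha = expand(alpha), dn = expand(dn),
                 omega_deg = omega_deg, noise_theta_deg = noise_theta_deg,
                 noise_dn_rel = noise_dn_rel, seed = seed),
            class = "phantom_spec")
}

#' Simulate a two-beam measurement-pair map
#'
#' Applies the forward model ([apparent_from_true()]) per pixel under the
#' normal and the y-tilted beam, then adds wrapped-Gaussian noise to the
#' apparent orientations (independently per beam, period 180 so noise near
#' the +/-90 seam wraps into a U-shaped distribution against the interval
#' edges) and truncated Gaussian relative noise to the apparent
#' birefringences.
#'
#' @param spec a [phantom_spec()].
#' @return list with `pairs` (a [measurement_pair_map()]) and `truth`
#'   (list of the ground-truth `theta`, `alpha`, `dn` matrices).
#' @export
simulate_pair_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nx <- spec$shape[1]; ny <- spec$shape[2]
  b1 <- beam(); b2 <- beam(spec$omega_deg, "y")
  th1 <- dn1 <- th2 <- dn2 <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    v <- biref_vector(spec$theta[i, j], spec$alpha[i, j], spec$dn[i, j])
    m1 <- apparent_from_true(v, b1); m2 <- apparent_from_true(v, b2)
    th1[i, j] <- m1$theta_app; dn1[i, j] <- m1$dn_app
    th2[i, j] <- m2$theta_app; dn2[i, j] <- m2$dn_app
  }
  n <- nx * ny
  if (spec$noise_theta_deg > 0) {
    th1[] <- wrap_axial(th1 + stats::rnorm(n, 0, spec$noise_theta_deg))
    th2[] <- wrap_axial(th2 + stats::rnorm(n, 0, spec$noise_theta_deg))
  }
  if (spec$noise_dn_rel > 0) {
    dn1[] <- pmax(0, dn1 * (1 + stats::rnorm(n, 0, spec$noise_dn_rel)))
    dn2[] <- pmax(0, dn2 * (1 + stats::rnorm(n, 0, spec$noise_dn_rel)))
  }
  mask <- is.finite(dn1) & is.finite(dn2)
  list(pairs = measurement_pair_map(th1, dn1, th2, dn2, spec$omega_deg,
                                    mask = mask),
       truth = list(theta = spec$theta, alpha = spec$alpha, dn = spec$dn))
}

#' Validation experiment design
#'
#' Presets mirroring the physical validation experiments: `wedge` and
#' `tilt_sweep` add each level to the through-plane angle of a common base
#' truth (a rigid inclination of the whole flat sample);
#' `inplane_rotation` adds each level to the in-plane angle.
#'
#' @param kind `"wedge"`, `"tilt_sweep"`, `"inplane_rotation"` or
#'   `"custom"` (levels interpreted as through-plane offsets).
#' @param levels numeric vector of preset angles, degrees (non-empty).
#' @param base_theta,base_alpha,base_dn base truth shared by all levels.
#' @return object of class `"experiment_design"`.
#' @export
#' @examples
#' experiment_design("wedge", c(0, -30, 30))
#' experiment_design("tilt_sweep", seq(0, 50, by = 10))
experiment_design <- function(kind = c("wedge", "tilt_sweep",
                                       "inplane_rotation", "custom"),
                              levels, base_theta = 0, base_alpha = 0,
                              base_dn = 5e-4) {
  kind <- match.arg(kind)
  if (missing(levels) || !length(levels)) stop("'levels' must be non-empty")
  structure(list(kind = kind, levels = as.numeric(levels),
                 base_theta = base_theta, base_alpha = base_alpha,
                 base_dn = base_dn),
            class = "experiment_design")
}

#' Run a synthetic validation experiment
#'
#' For each level of the design, offsets the base truth, simulates a
#' measurement-pair map under the phantom's noise model, fits every pixel,
#' and summarizes the recovered orientation per level. For tilt sweeps an
#' ordinary-least-squares slope of mean recovered inclination versus preset
#' level is fitted.
#'
#' @param design an [experiment_design()].
#' @param spec a [phantom_spec()] providing the grid, tilt, noise and seed
#'   (its truth fields are overridden by the design's base truth).
#' @param control an [axis3d_control()].
#' @return object of class `"psoct_experiment"`: a list with `design`, a
#'   per-level data frame `levels` (`level`, `mean_theta`, `mean_alpha`,
#'   `mean_dn`, `sd_alpha`, `n_valid`), and for tilt sweeps `slope` and
#'   `intercept` of the OLS fit.
#' @export
run_experiment <- function(design, spec = phantom_spec(),
                           control = axis3d_control()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(spec, "phantom_spec"))
  rows <- lapply(seq_along(design$levels), function(k) {
    lv <- design$levels[k]
    if (design$kind == "inplane_rotation") {
      th <- wrap_axial(design$base_theta + lv); al <- design$base_alpha
    } else {
      th <- design$base_theta; al <- design$base_alpha + lv
    }
    sp <- phantom_spec(spec$shape, th, al, design$base_dn, spec$omega_deg,
                       spec$noise_theta_deg, spec$noise_dn_rel,
                       seed = if (is.null(spec$seed)) NULL else spec$seed + k)
    sim <- simulate_pair_map(sp)
    fit <- fit_axis3d_map(sim$pairs, control)
    ok <- fit$mask
    data.frame(level = lv,
               mean_theta = axial_mean(fit$theta[ok]),
               mean_alpha = mean(fit$alpha[ok]),
               sd_alpha = stats::sd(fit$alpha[ok]),
               mean_dn = mean(fit$dn[ok]),
               n_valid = sum(ok))
  })
  tab <- do.call(rbind, rows)
  out <- list(design = design, levels = tab)
  if (design$kind == "tilt_sweep") {
    fitls <- stats::lm(mean_alpha ~ level, data = tab)
    out$slope <- unname(stats::coef(fitls)[2])
    out$intercept <- unname(stats::coef(fitls)[1])
  }
  structure(out, class = "psoct_experiment")
}

#' @export
print.psoct_experiment <- function(x, ...) {
  cat(sprintf("synthetic %s experiment, %d levels\n",
              x$design$kind, nrow(x$levels)))
  print(x$levels, row.names = FALSE, digits = 4)
  if (!is.null(x$slope))
    cat(sprintf("OLS slope of mean alpha-hat vs preset: %.4f (intercept %.3f deg)\n",
                x$slope, x$intercept))
  invisible(x)
}
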