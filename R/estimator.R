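## Per-pixel recovery of the true birefringence vector from the two-beam
## apparent measurements: least-squares objective over the laboratory-frame
## apparent vectors, xy-swap branch for fibers near the +/-90 degree seam,
## Nelder-Mead minimization, and a brute-force grid oracle for testing.

#' Two-beam measurement pair
#'
#' The per-pixel input of the estimator: apparent in-plane orientation and
#' apparent birefringence under the normal beam (`theta1`, `dn1`) and under
#' the beam tilted by `omega_deg` about the y axis (`theta2`, `dn2`).
#'
#' @param theta1,theta2 apparent orientations in degrees (beam frame,
#'   wrapped to \code{[-90, 90)}); `NA` when undefined.
#' @param dn1,dn2 apparent birefringences, `>= 0`.
#' @param omega_deg tilt angle of the second beam, degrees, `> 0`.
#' @param valid optional mask bit.
#' @return object of class `"measurement_pair"`.
#' @export
measurement_pair <- function(theta1, dn1, theta2, dn2, omega_deg = 15,
                             valid = TRUE) {
  stopifnot(omega_deg > 0, dn1 >= 0 || is.na(dn1), dn2 >= 0 || is.na(dn2))
  structure(list(theta1 = if (is.na(theta1)) NA_real_ else wrap_axial(theta1),
                 dn1 = dn1,
                 theta2 = if (is.na(theta2)) NA_real_ else wrap_axial(theta2),
                 dn2 = dn2,
                 omega_deg = omega_deg, valid = isTRUE(valid)),
            class = "measurement_pair")
}

#' @export
print.measurement_pair <- function(x, ...) {
  cat(sprintf(paste0(
    "measurement pair (omega = %g deg):\n",
    "  normal: theta1 = %s deg, dn1' = %.4g\n",
    "  tilted: theta2 = %s deg, dn2' = %.4g\n"),
    x$omega_deg, format(x$theta1), x$dn1, format(x$theta2), x$dn2))
  invisible(x)
}

#' Registered en-face grids of measurement pairs
#'
#' @param theta1,dn1 matrices from the normal beam.
#' @param theta2,dn2 matrices from the tilted beam, registered onto the
#'   normal-beam grid.
#' @param omega_deg tilt angle, degrees.
#' @param mask logical matrix of valid pixels (default: all finite).
#' @return object of class `"measurement_pair_map"`.
#' @export
measurement_pair_map <- function(theta1, dn1, theta2, dn2, omega_deg = 15,
                                 mask = NULL) {
  dims <- dim(theta1)
  if (!all(vapply(list(dn1, theta2, dn2), function(m)
    identical(dim(m), dims), logical(1))))
    stop("all maps must share the same dimensions")
  if (is.null(mask))
    mask <- is.finite(dn1) & is.finite(dn2)
  stopifnot(identical(dim(mask), dims), omega_deg > 0)
  structure(list(theta1 = theta1, dn1 = dn1, theta2 = theta2, dn2 = dn2,
                 omega_deg = omega_deg, mask = mask),
            class = "measurement_pair_map")
}

#' @export
print.measurement_pair_map <- function(x, ...) {
  cat(sprintf("measurement pair map: %d x %d pixels, omega = %g deg, %d valid\n",
              nrow(x$theta1), ncol(x$theta1), x$omega_deg, sum(x$mask)))
  invisible(x)
}

#' Estimator settings
#'
#' @param init `"closed_form"` (default) starts the simplex from the
#'   normal-beam orientation and the inclination implied by the ratio of
#'   the two apparent birefringences (run with both signs of the starting
#'   inclination, keeping the better optimum); `"paper_zero"` starts from a
#'   near-zero vector `[1e-8, 1e-8, 1e-8]` (the all-zero start sits on a
#'   singularity of the model).
#' @param ftol absolute tolerance on the least-squares objective
#'   (dimensionless squared; default 1e-20, attainable because objective
#'   magnitudes are ~(1e-4)^2).
#' @param max_iter simplex iteration cap per start.
#' @param swap_threshold_deg `|theta1|` at or above which the xy-swapped
#'   branch is used (default 45).
#' @param dn_floor pixels with both apparent birefringences below this are
#'   masked as unidentifiable (default 1e-5).
#' @return list of class `"axis3d_control"`.
#' @export
axis3d_control <- function(init = c("closed_form", "paper_zero"),
                           ftol = 1e-20, max_iter = 2000,
                           swap_threshold_deg = 45, dn_floor = 1e-5) {
  init <- match.arg(init)
  stopifnot(ftol > 0, max_iter >= 1,
            swap_threshold_deg > 0, swap_threshold_deg < 90)
  structure(list(init = init, ftol = ftol, max_iter = max_iter,
                 swap_threshold_deg = swap_threshold_deg,
                 dn_floor = dn_floor),
            class = "axis3d_control")
}

#' Branch selection for the xy-swap strategy
#'
#' Fibers whose normal-beam orientation is near +/-90 degrees sit at the
#' wrap-around seam of the orientation measurement, where angular noise is
#' U-shaped rather than approximately Gaussian. Those pixels are estimated
#' in a laboratory frame rotated 90 degrees about z (x and y interchanged),
#' where the same fibers lie near 0 degrees and the tilted beam becomes a
#' tilt about x.
#'
#' @param theta1 normal-beam apparent orientation, degrees; `NA` is an error
#'   (callers mask such pixels).
#' @param threshold_deg swap threshold (default 45).
#' @return `"standard"` if `|theta1| < threshold_deg`, else `"swapped"`
#'   (the boundary itself swaps).
#' @export
#' @examples
#' choose_branch(10)   # "standard"
#' choose_branch(80)   # "swapped"
#' choose_branch(45)   # "swapped" (boundary belongs to >=)
choose_branch <- function(theta1, threshold_deg = 45) {
  if (is.na(theta1)) stop("theta1 is undefined; pixel must be masked")
  if (abs(wrap_axial(theta1)) < threshold_deg) "standard" else "swapped"
}

## ---- internal branch machinery ------------------------------------------
## The swapped branch works in a laboratory frame rotated +90 deg about z:
## new = (y, -x, z) of old. The y-tilted beam p2 maps exactly onto the
## x-tilted beam p3 = [0, -sin, cos], and every in-plane angle shifts by
## -90 deg. Axes found in the rotated frame are rotated back with
## old = (-y_new, x_new, z_new).

.rotate_axis_back <- function(u) c(-u[2], u[1], u[3])
.rotate_axis_fwd  <- function(u) c(u[2], -u[1], u[3])

## beams and measured lab-frame vectors for a pair under one branch
.pair_setup <- function(pair, branch) {
  om <- pair$omega_deg
  if (branch == "standard") {
    b1 <- beam(); b2 <- beam(om, "y")
    th1 <- pair$theta1; th2 <- pair$theta2
  } else {
    b1 <- beam(); b2 <- beam(om, "x")
    th1 <- if (is.na(pair$theta1)) NA_real_ else wrap_axial(pair$theta1 - 90)
    th2 <- if (is.na(pair$theta2)) NA_real_ else wrap_axial(pair$theta2 - 90)
  }
  mvec <- function(dn_app, th, b) {
    if (is.na(th) || dn_app == 0) return(c(0, 0, 0))
    r <- deg2rad(th)
    dn_app * (cos(r) * b$e1 + sin(r) * b$e2)
  }
  list(p1 = b1$p, p2 = b2$p,
       m1 = mvec(pair$dn1, th1, b1), m2 = mvec(pair$dn2, th2, b2))
}

## scaled objective kernel: w trial vector, setup from .pair_setup, all in
## units of the scale factor. Sign-resolved: the measured orientation is
## axial, so each residual is taken against +/- the measured vector,
## whichever is closer.
.objective_kernel <- function(w, setup) {
  n2 <- sum(w * w)
  if (n2 < 1e-24) return(sum(setup$m1^2) + sum(setup$m2^2))
  obj <- 0
  for (nm in 1:2) {
    p <- if (nm == 1) setup$p1 else setup$p2
    m <- if (nm == 1) setup$m1 else setup$m2
    d <- sum(p * w)
    a <- (w - d * p) * sqrt(max(0, 1 - d * d / n2))
    obj <- obj + min(sum((a - m)^2), sum((a + m)^2))
  }
  obj
}

#' Least-squares objective of a trial birefringence vector
#'
#' Sum over the two beams of the squared Euclidean distance between the
#' model-predicted apparent vector of `v_trial` and the measured apparent
#' vector, the latter taken with whichever axial sign is closer (the
#' measured orientation only defines a line). Zero exactly when `v_trial`
#' reproduces both measurements.
#'
#' @param v_trial a [biref_vector()] with `dn > 0`.
#' @param pair a [measurement_pair()].
#' @param branch `"auto"` (select by `|theta1|` vs 45), `"standard"` or
#'   `"swapped"`. The two branches are related by a rigid rotation of the
#'   laboratory frame and give identical values; the distinction matters
#'   for how measured angles near the seam wrap, not for the objective.
#' @return non-negative scalar (dimensionless squared).
#' @export
pair_objective <- function(v_trial, pair,
                           branch = c("auto", "standard", "swapped")) {
  branch <- match.arg(branch)
  stopifnot(inherits(v_trial, "biref_vector"), inherits(pair, "measurement_pair"))
  if (!pair$valid) stop("pair is masked invalid")
  if (v_trial$dn <= 0) stop("trial vector must have dn > 0")
  if (branch == "auto") branch <- choose_branch(pair$theta1)
  setup <- .pair_setup(pair, branch)
  u <- if (branch == "swapped") .rotate_axis_fwd(v_trial$axis) else v_trial$axis
  .objective_kernel(v_trial$dn * u, setup)
}

## closed-form starts in the (possibly rotated) estimation frame: theta is
## taken from the normal-beam orientation, and for each candidate
## inclination alpha the true birefringence implied by the normal beam
## (dn1' = dn cos^2 alpha) fixes the trial magnitude. A coarse scan of the
## objective over alpha picks the two best basins (one per inclination
## sign); the simplex is started from each. This stays well-behaved for
## steep fibers, where both apparent birefringences are far below the true
## value.
.closed_form_starts <- function(setup, th1, dn1, dn2, s) {
  th <- if (is.na(th1)) 0 else th1
  dnf <- max(dn1, dn2, s * 1e-3)
  alphas <- seq(-88, 88, by = 2)
  cand <- lapply(alphas, function(a) {
    ca2 <- cos(deg2rad(a))^2
    dnc <- min(max(dn1 / ca2, dnf), 60 * dnf)
    (dnc / s) * .unit_axis(th, a)
  })
  vals <- vapply(cand, .objective_kernel, numeric(1), setup = setup)
  i_best <- which.min(vals)
  opp <- which(sign(alphas) == -sign(alphas[i_best]) | alphas == 0)
  i_opp <- opp[which.min(vals[opp])]
  unique(list(cand[[i_best]], cand[[i_opp]]))
}

.unit_axis <- function(theta, alpha) {
  th <- deg2rad(theta); al <- deg2rad(alpha)
  c(cos(th) * cos(al), sin(th) * cos(al), sin(al))
}

#' Fit the 3D axis and true birefringence of one pixel
#'
#' Minimizes [pair_objective()] over the trial birefringence 3-vector with
#' a derivative-free Nelder-Mead simplex (two starts with opposite initial
#' inclination signs, each polished by a simplex restart), after selecting
#' the standard or xy-swapped branch from the normal-beam orientation.
#' The optimization runs in units of the larger apparent birefringence so
#' the stopping tolerance is scale-free.
#'
#' @param pair a [measurement_pair()]; or a [measurement_pair_map()], in
#'   which case every valid pixel is fitted (see [fit_axis3d_map()]).
#' @param control an [axis3d_control()].
#' @return for a single pair, object of class `"axis3d_fit"` with elements
#'   `v_hat` (the fitted [biref_vector()]), `objective`, `branch`,
#'   `converged`, `n_eval`, `masked` and the input `pair`; masked
#'   (unidentifiable) pixels return `masked = TRUE` and `v_hat = NULL`.
#' @seealso [fit_axis3d_map()], [brute_force_axis3d()]
#' @export
#' @examples
#' truth <- biref_vector(20, 40, 5e-4)
#' m1 <- apparent_from_true(truth, beam())
#' m2 <- apparent_from_true(truth, beam(15, "y"))
#' pair <- measurement_pair(m1$theta_app, m1$dn_app, m2$theta_app, m2$dn_app, 15)
#' fit_axis3d(pair)
fit_axis3d <- function(pair, control = axis3d_control()) {
  if (inherits(pair, "measurement_pair_map"))
    return(fit_axis3d_map(pair, control))
  stopifnot(inherits(pair, "measurement_pair"),
            inherits(control, "axis3d_control"))
  masked_result <- function() {
    structure(list(v_hat = NULL, objective = NA_real_, branch = NA_character_,
                   converged = FALSE, n_eval = 0L, masked = TRUE, pair = pair,
                   control = control),
              class = "axis3d_fit")
  }
  if (!pair$valid) return(masked_result())
  if (max(pair$dn1, pair$dn2, na.rm = TRUE) < control$dn_floor)
    return(masked_result())
  if (is.na(pair$theta1)) return(masked_result())

  branch <- choose_branch(pair$theta1, control$swap_threshold_deg)
  setup <- .pair_setup(pair, branch)
  s <- max(pair$dn1, pair$dn2)            # scale: objective in units of s^2
  setup$m1 <- setup$m1 / s; setup$m2 <- setup$m2 / s
  fn <- function(w) .objective_kernel(w, setup)
  abstol <- control$ftol / s^2

  th1b <- if (branch == "swapped") wrap_axial(pair$theta1 - 90) else pair$theta1
  starts <- if (control$init == "closed_form") {
    .closed_form_starts(setup, th1b, pair$dn1, pair$dn2, s)
  } else {
    list(rep(1e-8 / s, 3))
  }

  best <- NULL; n_eval <- 0L
  for (w0 in starts) {
    opt <- stats::optim(w0, fn, method = "Nelder-Mead",
                        control = list(maxit = control$max_iter,
                                       abstol = abstol, reltol = 1e-15))
    # simplex restart from the optimum polishes the final digits
    opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                         control = list(maxit = control$max_iter,
                                        abstol = abstol, reltol = 1e-15))
    n_eval <- n_eval + opt$counts[["function"]] + opt2$counts[["function"]]
    if (is.null(best) || opt2$value < best$value) best <- opt2
  }

  w <- best$par * s
  dn_hat <- sqrt(sum(w^2))
  u <- w / dn_hat
  if (branch == "swapped") u <- .rotate_axis_back(u)
  v_hat <- biref_vector_from_axis(u, dn_hat)
  structure(list(v_hat = v_hat, objective = best$value * s^2, branch = branch,
                 converged = best$convergence == 0L, n_eval = n_eval,
                 masked = FALSE, pair = pair, control = control),
            class = "axis3d_fit")
}

#' Fit every pixel of a registered measurement-pair map
#'
#' Applies [fit_axis3d()] to each valid pixel. Pixels sharing identical
#' measurements (common in noiseless phantoms) are solved once and reused,
#' so the result is identical to the per-pixel loop but much faster on
#' homogeneous regions.
#'
#' @param maps a [measurement_pair_map()].
#' @param control an [axis3d_control()].
#' @return object of class `"axis3d_map"`: matrices `dn`, `theta`, `alpha`,
#'   `objective`, logical `converged`, `swapped` and `mask` (valid output
#'   pixels), an `nx x ny x 3` array `axis`, plus `omega_deg` and the
#'   control used. Masked input pixels stay masked in every output.
#' @export
fit_axis3d_map <- function(maps, control = axis3d_control()) {
  stopifnot(inherits(maps, "measurement_pair_map"))
  dims <- dim(maps$theta1)
  out <- list(dn = array(NA_real_, dims), theta = array(NA_real_, dims),
              alpha = array(NA_real_, dims), objective = array(NA_real_, dims),
              converged = array(FALSE, dims), swapped = array(FALSE, dims),
              mask = array(FALSE, dims),
              axis = array(NA_real_, c(dims, 3L)))
  cache <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    if (!maps$mask[i, j]) next
    key <- paste(maps$theta1[i, j], maps$dn1[i, j],
                 maps$theta2[i, j], maps$dn2[i, j], sep = "|")
    fit <- if (!is.null(cache[[key]])) cache[[key]] else {
      f <- fit_axis3d(measurement_pair(maps$theta1[i, j], maps$dn1[i, j],
                                       maps$theta2[i, j], maps$dn2[i, j],
                                       maps$omega_deg),
                      control)
      cache[[key]] <- f
      f
    }
    if (fit$masked) next
    out$mask[i, j] <- TRUE
    out$dn[i, j] <- fit$v_hat$dn
    out$theta[i, j] <- fit$v_hat$theta
    out$alpha[i, j] <- fit$v_hat$alpha
    out$axis[i, j, ] <- fit$v_hat$axis
    out$objective[i, j] <- fit$objective
    out$converged[i, j] <- fit$converged
    out$swapped[i, j] <- fit$branch == "swapped"
  }
  structure(c(out, list(omega_deg = maps$omega_deg, control = control)),
            class = "axis3d_map")
}

#' Brute-force grid oracle
#'
#' Exhaustive evaluation of the pair objective over a regular
#' `(theta, alpha, dn)` grid; returns the global grid minimizer. Intended
#' as an independent check of the simplex estimator, not for production
#' use.
#'
#' @param pair a [measurement_pair()].
#' @param grid_step_deg angular grid step, degrees (`<= 5`).
#' @param dn_grid numeric vector of candidate true-birefringence values.
#' @return list with `v_hat` (a [biref_vector()]), `objective`, and the
#'   grid dimensions.
#' @export
brute_force_axis3d <- function(pair, grid_step_deg = 1,
                               dn_grid = NULL) {
  stopifnot(inherits(pair, "measurement_pair"), grid_step_deg <= 5,
            grid_step_deg > 0)
  if (is.null(dn_grid))
    dn_grid <- max(pair$dn1, pair$dn2) * seq(1, 2, by = 0.05)
  if (!length(dn_grid)) stop("empty dn grid")
  branch <- choose_branch(pair$theta1)
  setup <- .pair_setup(pair, branch)
  thetas <- seq(-90, 90 - grid_step_deg, by = grid_step_deg)
  alphas <- seq(-90, 90, by = grid_step_deg)
  g <- expand.grid(theta = thetas, alpha = alphas)
  th <- deg2rad(g$theta); al <- deg2rad(g$alpha)
  U <- cbind(cos(th) * cos(al), sin(th) * cos(al), sin(al))
  best <- list(value = Inf)
  for (dn in dn_grid) {
    obj <- numeric(nrow(U))
    for (nm in 1:2) {
      p <- if (nm == 1) setup$p1 else setup$p2
      m <- if (nm == 1) setup$m1 else setup$m2
      d <- as.vector(U %*% p)
      A <- dn * (U - outer(d, p)) * sqrt(pmax(0, 1 - d^2))
      r1 <- (A[, 1] - m[1])^2 + (A[, 2] - m[2])^2 + (A[, 3] - m[3])^2
      r2 <- (A[, 1] + m[1])^2 + (A[, 2] + m[2])^2 + (A[, 3] + m[3])^2
      obj <- obj + pmin(r1, r2)
    }
    k <- which.min(obj)
    if (obj[k] < best$value)
      best <- list(value = obj[k], axis = U[k, ], dn = dn)
  }
  u <- if (branch == "swapped") .rotate_axis_back(best$axis) else best$axis
  list(v_hat = biref_vector_from_axis(u, best$dn),
       objective = best$value, branch = branch,
       n_theta = length(thetas), n_alpha = length(alphas),
       n_dn = length(dn_grid))
}

## ---- S3 methods ----------------------------------------------------------

#' @export
print.axis3d_fit <- function(x, ...) {
  if (x$masked) {
    cat("axis3d fit: pixel masked (unidentifiable)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "axis3d fit (%s branch): dn = %.4g, theta = %.3f deg, alpha = %.3f deg\n",
    x$branch, x$v_hat$dn, x$v_hat$theta, x$v_hat$alpha))
  cat(sprintf("  objective = %.3g, converged = %s, %d evaluations\n",
              x$objective, x$converged, x$n_eval))
  invisible(x)
}

#' @export
coef.axis3d_fit <- function(object, ...) {
  if (object$masked) return(c(dn = NA_real_, theta = NA_real_, alpha = NA_real_))
  c(dn = object$v_hat$dn, theta = object$v_hat$theta,
    alpha = object$v_hat$alpha)
}

#' @export
summary.axis3d_fit <- function(object, ...) {
  print(object)
  if (!object$masked) {
    for (b in list(beam(), beam(object$pair$omega_deg, "y"))) {
      m <- apparent_from_true(object$v_hat, b)
      cat(sprintf("  predicted under tilt %2g deg: dn' = %.4g, theta' = %s\n",
                  b$omega_deg, m$dn_app,
                  if (m$defined) sprintf("%.3f deg", m$theta_app) else "undef"))
    }
  }
  invisible(object)
}

#' Predict the apparent measurement the fitted axis would give
#'
#' @param object an `"axis3d_fit"`.
#' @param beam a [beam()] (default: the pair's tilted beam).
#' @param ... unused.
#' @return an [apparent_measurement()].
#' @export
predict.axis3d_fit <- function(object, beam = NULL, ...) {
  if (object$masked) stop("cannot predict from a masked fit")
  if (is.null(beam)) beam <- psoct3d::beam(object$pair$omega_deg, "y")
  apparent_from_true(object$v_hat, beam)
}

#' @export
residuals.axis3d_fit <- function(object, ...) {
  if (object$masked) return(NULL)
  setup <- .pair_setup(object$pair, object$branch)
  u <- if (object$branch == "swapped") .rotate_axis_fwd(object$v_hat$axis)
  else object$v_hat$axis
  w <- object$v_hat$dn * u
  res <- lapply(1:2, function(nm) {
    p <- if (nm == 1) setup$p1 else setup$p2
    m <- if (nm == 1) setup$m1 else setup$m2
    d <- sum(p * w)
    a <- (w - d * p) * sqrt(max(0, 1 - d^2 / sum(w^2)))
    if (sum((a - m)^2) <= sum((a + m)^2)) a - m else a + m
  })
  names(res) <- c("normal", "tilted")
  res
}

#' Simulate replicate measurement pairs from a fitted axis
#'
#' Draws new two-beam measurements from the fitted birefringence vector
#' under the forward model, with optional wrapped-Gaussian orientation
#' noise and truncated relative birefringence noise.
#'
#' @param object an `"axis3d_fit"`.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param noise_theta_deg,noise_dn_rel noise levels (defaults 0).
#' @param ... unused.
#' @return list of [measurement_pair()] objects.
#' @export
simulate.axis3d_fit <- function(object, nsim = 1, seed = NULL,
                                noise_theta_deg = 0, noise_dn_rel = 0, ...) {
  if (object$masked) stop("cannot simulate from a masked fit")
  if (!is.null(seed)) set.seed(seed)
  v <- object$v_hat; om <- object$pair$omega_deg
  m1 <- apparent_from_true(v, beam())
  m2 <- apparent_from_true(v, beam(om, "y"))
  lapply(seq_len(nsim), function(k) {
    th1 <- wrap_axial(m1$theta_app + stats::rnorm(1, 0, noise_theta_deg))
    th2 <- wrap_axial(m2$theta_app + stats::rnorm(1, 0, noise_theta_deg))
    d1 <- max(0, m1$dn_app * (1 + stats::rnorm(1, 0, noise_dn_rel)))
    d2 <- max(0, m2$dn_app * (1 + stats::rnorm(1, 0, noise_dn_rel)))
    measurement_pair(th1, d1, th2, d2, om)
  })
}

#' @export
print.axis3d_map <- function(x, ...) {
  cat(sprintf("axis3d map: %d x %d pixels, %d valid (%d swapped branch)\n",
              nrow(x$dn), ncol(x$dn), sum(x$mask), sum(x$swapped)))
  if (any(x$mask))
    cat(sprintf("  dn: median %.4g | theta: mean %.2f deg | alpha: mean %.2f deg\n",
                stats::median(x$dn[x$mask]),
                axial_mean(x$theta[x$mask]), mean(x$alpha[x$mask])))
  invisible(x)
}

#' @export
summary.axis3d_map <- function(object, ...) {
  print(object)
  if (any(object$mask)) {
    q <- stats::quantile(object$objective[object$mask], c(0.5, 0.9, 1))
    cat(sprintf("  objective: median %.3g, p90 %.3g, max %.3g; %.1f%% converged\n",
                q[1], q[2], q[3],
                100 * mean(object$converged[object$mask])))
  }
  invisible(object)
}

#' @export
coef.axis3d_map <- function(object, ...) {
  list(dn = object$dn, theta = object$theta, alpha = object$alpha)
}

#' @export
residuals.axis3d_map <- function(object, ...) object$objective

#' Image panels of a fitted orientation map
#'
#' @param x an `"axis3d_map"`.
#' @param which subset of `c("theta", "alpha", "dn")`.
#' @param ... passed to [graphics::image()].
#' @export
plot.axis3d_map <- function(x, which = c("theta", "alpha", "dn"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  for (w in which) {
    z <- x[[w]]
    graphics::image(z, main = w, useRaster = TRUE,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
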