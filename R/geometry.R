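## Geometry core: birefringence vector, illumination beams, and the forward
## model mapping a true 3D optic axis to the apparent (per-beam)
## birefringence and in-plane orientation.
##
## Coordinate frame: right-handed, x-y in the imaging plane, z along the
## normal beam into the tissue. The optic axis of a fiber with in-plane
## orientation Theta and through-plane orientation alpha (both degrees) is
##   [ox, oy, oz] = [cos(Theta)cos(alpha), sin(Theta)cos(alpha), sin(alpha)],
## alpha > 0 tipping the fiber toward +z. The axis is axial: v and -v are
## the same physical axis, so a canonical sign is fixed by the first
## nonzero of (ox, oy, oz) being positive.

#' Canonicalize an axial 3-vector
#'
#' Resolves the sign ambiguity of an optic axis (a line, not a ray): the
#' representative has `ox >= 0`; if `ox == 0` then `oy >= 0`; if both are
#' zero then `oz >= 0`.
#'
#' @param axis numeric length-3 vector (need not be unit length).
#' @return the sign-resolved vector.
#' @export
canonical_axis <- function(axis) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  tol <- 1e-14 * max(1, sqrt(sum(axis^2)))
  s <- if (axis[1] > tol) 1
  else if (axis[1] < -tol) -1
  else if (axis[2] > tol) 1
  else if (axis[2] < -tol) -1
  else if (axis[3] >= 0) 1
  else -1
  v <- s * axis
  # snap near-zero leading components exactly to zero so the canonical
  # representative is stable under round-off
  v[abs(v) <= tol] <- 0
  v
}

#' Spherical angles of a unit axis
#'
#' Inverse of the `(Theta, alpha) -> axis` map. The axis is canonicalized
#' first, so angles at the Theta = +/-90 seam come back as the canonical
#' representative (which may flip the sign of alpha, as required by axial
#' symmetry).
#'
#' @param axis numeric length-3 vector.
#' @return named numeric vector `c(theta =, alpha =)` in degrees,
#'   `theta` in \code{[-90, 90)}, `alpha` in \code{[-90, 90]}.
#' @export
axis_to_angles <- function(axis) {
  u <- unname(canonical_axis(axis))
  u <- u / sqrt(sum(u^2))
  alpha <- rad2deg(asin(pmin(1, pmax(-1, u[3]))))
  theta <- if (abs(u[1]) < 1e-15 && abs(u[2]) < 1e-15) 0
  else wrap_axial(rad2deg(atan2(u[2], u[1])))
  c(theta = theta, alpha = alpha)
}

#' True birefringence vector
#'
#' Bundles the true (orientation-independent) birefringence `dn` with the
#' 3D optic-axis direction, parameterized by the in-plane orientation
#' `theta` and the through-plane orientation `alpha`. The stored angles are
#' re-derived from the canonical axis so each physical axis has a unique
#' representation.
#'
#' @param theta in-plane orientation, degrees.
#' @param alpha through-plane orientation, degrees in \code{[-90, 90]}.
#' @param dn true birefringence (dimensionless, typically ~1e-4), `>= 0`.
#' @return object of class `"biref_vector"`: list with `dn`, `theta`,
#'   `alpha` and the unit 3-vector `axis`.
#' @export
#' @examples
#' biref_vector(30, 45, 5e-4)
biref_vector <- function(theta, alpha, dn) {
  stopifnot(is.numeric(theta), is.numeric(alpha), is.numeric(dn),
            length(theta) == 1, length(alpha) == 1, length(dn) == 1)
  if (!is.finite(dn) || dn < 0)
    stop("'dn' must be a finite non-negative number")
  theta <- unname(theta); alpha <- unname(alpha); dn <- unname(dn)
  th <- deg2rad(theta); al <- deg2rad(alpha)
  axis <- canonical_axis(c(cos(th) * cos(al), sin(th) * cos(al), sin(al)))
  ang <- axis_to_angles(axis)
  structure(list(dn = dn, theta = unname(ang["theta"]),
                 alpha = unname(ang["alpha"]), axis = axis),
            class = "biref_vector")
}

#' @rdname biref_vector
#' @param axis unit 3-vector alternative to angles.
#' @export
biref_vector_from_axis <- function(axis, dn) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("zero axis has no direction")
  ang <- axis_to_angles(axis / n)
  biref_vector(ang["theta"], ang["alpha"], dn)
}

#' @export
print.biref_vector <- function(x, ...) {
  cat(sprintf(
    "birefringence vector: dn = %.4g, theta = %.3f deg, alpha = %.3f deg\n",
    x$dn, x$theta, x$alpha))
  cat(sprintf("  axis = [%.6f, %.6f, %.6f]\n",
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Illumination beam
#'
#' The normal beam propagates along +z (`p1 = [0,0,1]`). The tilted beam is
#' rotated by `omega_deg` about the y axis (`p2 = [sin, 0, cos]`) or, in the
#' xy-swapped branch, about the x axis (`p3 = [0, -sin, cos]`).
#'
#' @param omega_deg tilt angle in degrees; must be 0 for `tilt_axis = "none"`.
#' @param tilt_axis `"none"` (normal incidence), `"y"` or `"x"`.
#' @return object of class `"beam"` with the propagation unit vector `p`
#'   and the in-plane frame vectors `e1`, `e2` of the beam's transverse
#'   plane (the measured in-plane orientation is the azimuth in this frame).
#' @export
#' @examples
#' beam()           # normal illumination
#' beam(15, "y")    # 15-degree tilt about y
beam <- function(omega_deg = 0, tilt_axis = c("none", "y", "x")) {
  tilt_axis <- match.arg(tilt_axis)
  stopifnot(is.numeric(omega_deg), length(omega_deg) == 1,
            is.finite(omega_deg))
  if (tilt_axis == "none" && omega_deg != 0)
    stop("normal beam must have omega_deg = 0")
  if (tilt_axis != "none" && omega_deg == 0)
    stop("tilted beam must have omega_deg != 0")
  w <- deg2rad(omega_deg)
  fr <- switch(tilt_axis,
    none = list(p = c(0, 0, 1), e1 = c(1, 0, 0), e2 = c(0, 1, 0)),
    y    = list(p = c(sin(w), 0, cos(w)),
                e1 = c(cos(w), 0, -sin(w)), e2 = c(0, 1, 0)),
    x    = list(p = c(0, -sin(w), cos(w)),
                e1 = c(1, 0, 0), e2 = c(0, cos(w), sin(w))))
  structure(c(fr, list(omega_deg = omega_deg, tilt_axis = tilt_axis)),
            class = "beam")
}

#' @export
print.beam <- function(x, ...) {
  cat(sprintf("beam: tilt %g deg about '%s', p = [%.4f, %.4f, %.4f]\n",
              x$omega_deg, x$tilt_axis, x$p[1], x$p[2], x$p[3]))
  invisible(x)
}

#' Apparent measurement under one beam
#'
#' Container for the per-pixel pair (apparent birefringence, apparent
#' in-plane orientation) one beam observes. `theta_app` is undefined
#' (`defined = FALSE`) when the fiber is parallel to the beam.
#'
#' @param dn_app apparent birefringence, `>= 0`.
#' @param theta_app apparent in-plane orientation in the beam frame,
#'   degrees, wrapped to \code{[-90, 90)}; may be `NA` when undefined.
#' @param beam a [beam()] object.
#' @param defined is the orientation identifiable?
#' @return object of class `"apparent_measurement"`.
#' @export
apparent_measurement <- function(dn_app, theta_app, beam, defined = TRUE) {
  stopifnot(inherits(beam, "beam"), dn_app >= 0)
  structure(list(dn_app = dn_app,
                 theta_app = if (defined) wrap_axial(theta_app) else NA_real_,
                 beam = beam, defined = isTRUE(defined)),
            class = "apparent_measurement")
}

#' @export
print.apparent_measurement <- function(x, ...) {
  cat(sprintf(
    "apparent measurement (tilt %g deg about '%s'): dn' = %.4g, theta' = %s\n",
    x$beam$omega_deg, x$beam$tilt_axis, x$dn_app,
    if (x$defined) sprintf("%.3f deg", x$theta_app) else "undefined"))
  invisible(x)
}

#' Forward model: apparent measurement of a true axis
#'
#' A beam with propagation `p` sees the projection of the birefringence
#' vector onto its transverse plane. With `Psi` the polar angle of the axis
#' in the beam frame (`cos(Psi) = |p . axis|`, and `Psi = 90 - alpha` for
#' the normal beam), the apparent birefringence is `dn' = dn sin^2(Psi)`
#' and the apparent orientation is the azimuth of the projected axis in the
#' beam's transverse frame.
#'
#' @param v a [biref_vector()].
#' @param b a [beam()].
#' @return an [apparent_measurement()]; when the axis is parallel to the
#'   beam `dn_app = 0` and the orientation is flagged undefined.
#' @export
#' @examples
#' apparent_from_true(biref_vector(0, 30, 6.2e-4), beam())
apparent_from_true <- function(v, b) {
  stopifnot(inherits(v, "biref_vector"), inherits(b, "beam"))
  u <- v$axis
  cpsi <- sum(b$p * u)
  s2 <- max(0, 1 - cpsi^2)           # sin^2(Psi)
  dn_app <- v$dn * s2
  proj <- u - cpsi * b$p
  if (sqrt(sum(proj^2)) < 1e-12)
    return(apparent_measurement(0, NA_real_, b, defined = FALSE))
  theta_app <- wrap_axial(rad2deg(atan2(sum(b$e2 * proj), sum(b$e1 * proj))))
  apparent_measurement(dn_app, theta_app, b)
}

#' Laboratory-frame apparent birefringence 3-vector
#'
#' Embeds an apparent measurement as the 3-vector
#' `dn' (cos(theta') e1 + sin(theta') e2)` in the laboratory frame, where
#' `(e1, e2)` span the beam's transverse plane. For the normal beam this is
#' `dn' [cos(theta'), sin(theta'), 0]`.
#'
#' @param m an [apparent_measurement()].
#' @return numeric length-3 vector; all-`NA` with attribute
#'   `undefined = TRUE` if the measurement's orientation is undefined.
#' @export
apparent_vector <- function(m) {
  stopifnot(inherits(m, "apparent_measurement"))
  if (!m$defined)
    return(structure(rep(NA_real_, 3), undefined = TRUE))
  th <- deg2rad(m$theta_app)
  m$dn_app * (cos(th) * m$beam$e1 + sin(th) * m$beam$e2)
}

#' Model-predicted apparent vector of a trial birefringence vector
#'
#' Closed-form prediction used inside the least-squares objective: the
#' trial vector `dn~ = dn u` is projected onto the plane orthogonal to the
#' beam and scaled by `sqrt(1 - (p.u)^2)`, yielding a vector of magnitude
#' `dn sin^2(Psi)` along the apparent orientation. Identical to
#' `apparent_vector(apparent_from_true(v, b))` up to the axial sign.
#'
#' @param v a [biref_vector()] (trial value); `dn` must be positive.
#' @param b a [beam()].
#' @return numeric length-3 vector.
#' @export
estimated_apparent_vector <- function(v, b) {
  stopifnot(inherits(v, "biref_vector"), inherits(b, "beam"))
  if (v$dn <= 0) stop("trial vector must have dn > 0 (singular at 0)")
  dnvec <- v$dn * v$axis
  .estimated_apparent_vector_raw(dnvec, b$p)
}

## raw kernel shared with the optimizer: w is the (possibly scaled)
## birefringence 3-vector, p the beam propagation unit vector
.estimated_apparent_vector_raw <- function(w, p) {
  n2 <- sum(w * w)
  if (n2 <= 0) stop("trial vector must be nonzero")
  d <- sum(p * w)
  (w - d * p) * sqrt(max(0, 1 - d * d / n2))
}
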