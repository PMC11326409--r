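## Angle utilities. All public angles are in degrees; optic-axis angles are
## axial (period 180) and live on the half-open interval [-90, 90).

#' Wrap an axial angle to [-90, 90)
#'
#' Optic-axis orientations are lines, not rays: `theta` and `theta + 180`
#' are the same physical axis. All in-plane angles in the package are kept
#' on the half-open interval \code{[-90, 90)}.
#'
#' @param theta numeric vector of angles in degrees.
#' @return angles wrapped to \code{[-90, 90)}.
#' @export
#' @examples
#' wrap_axial(c(-90, 90, 135, 270))
wrap_axial <- function(theta) {
  ((theta + 90) %% 180) - 90
}

#' Wrapped difference between two axial angles
#'
#' Smallest signed difference `a - b` on the period-180 circle, in degrees,
#' in \code{[-90, 90)}.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return signed wrapped differences.
#' @export
axial_diff <- function(a, b) {
  wrap_axial(a - b)
}

#' Circular mean of axial angles (period 180)
#'
#' Computed by angle doubling: the mean resultant of unit vectors at
#' `2*theta` is halved back. Robust across the +/-90 seam, e.g. the mean of
#' 88 and -88 degrees is +/-90, not 0.
#'
#' @param theta angles in degrees.
#' @param na.rm drop missing values.
#' @return mean angle in degrees in \code{[-90, 90)}; `NA` if the resultant
#'   vanishes (perfectly uniform input).
#' @export
axial_mean <- function(theta, na.rm = TRUE) {
  if (na.rm) theta <- theta[!is.na(theta)]
  if (!length(theta)) return(NA_real_)
  z <- exp(2i * theta * pi / 180)
  m <- mean(z)
  if (Mod(m) < 1e-12) return(NA_real_)
  wrap_axial(Arg(m) * 180 / pi / 2)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
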