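## Preprocessing: depth-resolved retardance/orientation A-line stacks to
## en-face apparent-birefringence and orientation maps, and affine
## registration of the tilted-illumination maps onto the normal frame.

#' Depth-resolved A-line stack
#'
#' @param retardance 3D array (x, y, z) of single-pass phase retardance in
#'   degrees (see `double_pass` in [apparent_birefringence()] for
#'   round-trip input).
#' @param orientation 3D array of optic-axis orientation in degrees
#'   \code{[-90, 90)}; may be `NULL` if only birefringence is needed.
#' @param dz_um axial sampling, micrometers.
#' @param wavelength_nm center wavelength (default 1300).
#' @return object of class `"aline_stack"`.
#' @export
aline_stack <- function(retardance, orientation = NULL, dz_um,
                        wavelength_nm = 1300) {
  stopifnot(length(dim(retardance)) == 3, dz_um > 0, wavelength_nm > 0)
  if (!is.null(orientation))
    stopifnot(identical(dim(orientation), dim(retardance)))
  structure(list(retardance = retardance, orientation = orientation,
                 dz_um = dz_um, wavelength_nm = wavelength_nm),
            class = "aline_stack")
}

#' Apparent birefringence from the retardance depth-slope
#'
#' Per pixel, ordinary least squares of retardance (degrees) against depth
#' (micrometers) over a window below the tissue surface; the apparent
#' birefringence is `slope * lambda0 / 360` with the wavelength in
#' micrometers (single-pass retardance convention). The slope is invariant
#' to any constant retardance offset.
#'
#' @param stack an [aline_stack()].
#' @param depth_um regression depth below the surface (default 150).
#' @param surface_z integer matrix of per-pixel surface indices (first
#'   in-tissue z sample); default 1 everywhere (flat-faced block).
#' @param double_pass if `TRUE` the stored retardance is round-trip
#'   (cumulative double-pass) and is halved before the regression.
#' @return list with matrices `dn_app` (apparent birefringence, negative
#'   slopes clamped to 0) and `r2` (regression R^2); pixels with fewer
#'   than 3 samples in the window are `NA`.
#' @export
apparent_birefringence <- function(stack, depth_um = 150, surface_z = NULL,
                                   double_pass = FALSE) {
  stopifnot(inherits(stack, "aline_stack"))
  d <- dim(stack$retardance)
  if (is.null(surface_z)) surface_z <- matrix(1L, d[1], d[2])
  stopifnot(identical(dim(surface_z), d[1:2]))
  nwin <- floor(depth_um / stack$dz_um) + 1L
  lam_um <- stack$wavelength_nm / 1000
  dn_app <- r2 <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    z0 <- surface_z[i, j]
    zi <- z0:min(d[3], z0 + nwin - 1L)
    y <- stack$retardance[i, j, zi]
    ok <- is.finite(y)
    if (sum(ok) < 3) next
    z <- (zi[ok] - z0) * stack$dz_um
    y <- y[ok]
    if (double_pass) y <- y / 2
    zc <- z - mean(z); yc <- y - mean(y)
    szz <- sum(zc^2)
    slope <- sum(zc * yc) / szz                 # deg per um
    dn_app[i, j] <- max(0, slope) * lam_um / 360
    sst <- sum(yc^2)
    r2[i, j] <- if (sst > 0) slope^2 * szz / sst else 1
  }
  list(dn_app = dn_app, r2 = r2)
}

#' En-face orientation from the depth histogram peak
#'
#' Per pixel, the orientation samples over the depth window are binned on
#' \code{[-90, 90)} with bin centers at multiples of `bin_deg` (a constant
#' 30-degree profile returns exactly 30; any value in `[27.5, 32.5)` votes
#' for that bin) and the center of the maximal bin is returned. Binning is
#' wrap-aware (period 180): the bin at -90 collects samples from both ends
#' of the interval, so a cluster straddling +/-90 peaks near +/-90, never
#' near 0. Ties are broken toward the bin nearest the circular mean of the
#' window.
#'
#' @param stack an [aline_stack()] with orientation data.
#' @param depth_um depth window below the surface (default 150).
#' @param bin_deg bin width in degrees; must divide 180 (default 5).
#' @param surface_z per-pixel surface index matrix (default 1).
#' @return matrix of en-face orientations (bin centers, degrees); empty
#'   windows are `NA`.
#' @export
enface_orientation <- function(stack, depth_um = 150, bin_deg = 5,
                               surface_z = NULL) {
  stopifnot(inherits(stack, "aline_stack"), !is.null(stack$orientation))
  if (180 %% bin_deg != 0) stop("bin_deg must divide 180")
  d <- dim(stack$orientation)
  if (is.null(surface_z)) surface_z <- matrix(1L, d[1], d[2])
  nwin <- floor(depth_um / stack$dz_um) + 1L
  nb <- as.integer(180 / bin_deg)
  centers <- -90 + (seq_len(nb) - 1L) * bin_deg
  theta <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    z0 <- surface_z[i, j]
    zi <- z0:min(d[3], z0 + nwin - 1L)
    v <- stack$orientation[i, j, zi]
    v <- v[is.finite(v)]
    if (!length(v)) next
    v <- wrap_axial(v)
    idx <- (round((v + 90) / bin_deg) %% nb) + 1L
    counts <- tabulate(idx, nbins = nb)
    top <- which(counts == max(counts))
    if (length(top) > 1) {
      cm <- axial_mean(v)
      top <- top[which.min(abs(axial_diff(centers[top], cm)))]
    }
    theta[i, j] <- centers[top]
  }
  theta
}

#' En-face map container
#'
#' @param dn_app matrix of apparent birefringence.
#' @param theta_app matrix of apparent in-plane orientation, degrees.
#' @param fit_r2 optional regression-quality matrix.
#' @param pixel_um in-plane pixel size, micrometers (default 10).
#' @return object of class `"enface_maps"`.
#' @export
enface_maps <- function(dn_app, theta_app, fit_r2 = NULL, pixel_um = 10) {
  stopifnot(identical(dim(dn_app), dim(theta_app)), pixel_um > 0)
  structure(list(dn_app = dn_app, theta_app = theta_app, fit_r2 = fit_r2,
                 pixel_um = pixel_um),
            class = "enface_maps")
}

#' @export
print.enface_maps <- function(x, ...) {
  cat(sprintf("en-face maps: %d x %d pixels at %g um\n",
              nrow(x$dn_app), ncol(x$dn_app), x$pixel_um))
  invisible(x)
}

## bilinear sample of matrix `img` at fractional coords (x, y), 1-based;
## NA outside
.bilinear <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= nx & y0 + 1 <= ny
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
  i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
  out[ok] <- img[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
    img[i10] * fx[ok] * (1 - fy[ok]) +
    img[i01] * (1 - fx[ok]) * fy[ok] +
    img[i11] * fx[ok] * fy[ok]
  out
}

.nearest <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  xi <- round(x); yi <- round(y)
  ok <- xi >= 1 & yi >= 1 & xi <= nx & yi <= ny
  out <- rep(NA_real_, length(x))
  if (any(ok)) out[ok] <- img[cbind(xi[ok], yi[ok])]
  out
}

## affine par = c(a11, a12, a21, a22, tx, ty): ref pixel (x, y) samples
## moving image at A %*% (x - c) + c + t, with c the image center
.affine_coords <- function(par, dims) {
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  dx <- g$x - cx; dy <- g$y - cy
  list(x = par[1] * dx + par[2] * dy + cx + par[5],
       y = par[3] * dx + par[4] * dy + cy + par[6])
}

.ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 16) return(NA_real_)
  a <- a[ok] - mean(a[ok]); b <- b[ok] - mean(b[ok])
  s <- sqrt(sum(a^2) * sum(b^2))
  if (s == 0) return(NA_real_)
  sum(a * b) / s
}

## integer translation maximizing circular cross-correlation (FFT)
.coarse_shift <- function(ref, mov) {
  a <- ref - mean(ref); b <- mov - mean(mov)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  k <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sh <- k - 1L
  n <- dim(ref)
  sh <- ifelse(sh > n / 2, sh - n, sh)
  # ref(x) ~ mov(x + shift): cross-correlation peak at ref-to-mov offset
  unname(-sh)
}

#' Register the tilted-illumination maps onto the normal frame
#'
#' Estimates a 2D affine transform (about the image center) maximizing the
#' normalized cross-correlation between the two apparent-birefringence
#' maps — an FFT cross-correlation fixes the bulk translation, then a
#' Nelder-Mead refinement fits the full affine — and applies it to the
#' moving maps: birefringence with bilinear interpolation, orientation with
#' nearest-neighbor lookup plus correction by the transform's rotation
#' component (orientation values are axial; they are never linearly
#' interpolated).
#'
#' @param ref [enface_maps()] from the normal beam (fixed).
#' @param mov [enface_maps()] from the tilted beam (moving).
#' @param ncc_floor minimum acceptable post-registration correlation;
#'   below it the registration aborts with an error (default 0.2).
#' @param refine run the affine refinement (default `TRUE`; `FALSE` keeps
#'   the translation-only estimate).
#' @return list with `transform` (list: `A` 2x2 matrix, `t` translation in
#'   pixels, `rotation_deg`, `ncc`) and `registered` (an [enface_maps()]
#'   on the reference grid; out-of-field pixels `NA`).
#' @export
register_enface <- function(ref, mov, ncc_floor = 0.2, refine = TRUE) {
  stopifnot(inherits(ref, "enface_maps"), inherits(mov, "enface_maps"))
  dims <- dim(ref$dn_app)
  sh <- if (all(dims == dim(mov$dn_app))) .coarse_shift(ref$dn_app, mov$dn_app)
  else c(0, 0)
  par0 <- c(1, 0, 0, 1, sh[1], sh[2])
  score <- function(par) {
    co <- .affine_coords(par, dims)
    w <- .bilinear(mov$dn_app, co$x, co$y)
    v <- -.ncc(as.vector(ref$dn_app), w)
    if (is.na(v)) 1 else v
  }
  par <- par0
  if (refine) {
    opt <- stats::optim(par0, score, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-10,
                                       parscale = c(0.1, 0.1, 0.1, 0.1, 1, 1)))
    par <- opt$par
  }
  ncc <- -score(par)
  if (!is.finite(ncc) || ncc < ncc_floor)
    stop(sprintf("registration failed: NCC %.3f below floor %.3f", ncc,
                 ncc_floor))
  A <- matrix(par[1:4], 2, 2, byrow = TRUE)
  rot_deg <- rad2deg(atan2(A[2, 1] - A[1, 2], A[1, 1] + A[2, 2]))
  co <- .affine_coords(par, dims)
  dn_reg <- matrix(.bilinear(mov$dn_app, co$x, co$y), dims[1], dims[2])
  th_reg <- matrix(.nearest(mov$theta_app, co$x, co$y), dims[1], dims[2])
  th_reg <- wrap_axial(th_reg - rot_deg)
  r2_reg <- if (!is.null(mov$fit_r2))
    matrix(.nearest(mov$fit_r2, co$x, co$y), dims[1], dims[2]) else NULL
  list(transform = list(A = A, t = par[5:6], rotation_deg = rot_deg,
                        ncc = ncc),
       registered = enface_maps(dn_reg, th_reg, r2_reg, ref$pixel_um))
}

#' Write / read en-face maps as TIFF with a JSON sidecar
#'
#' The birefringence and orientation maps are stored as 16-bit TIFFs,
#' linearly scaled to the unit interval; the scaling, pixel size, tilt
#' angle and wavelength live in a JSON sidecar so the round trip restores
#' physical units (to 16-bit quantization).
#'
#' @param maps an [enface_maps()].
#' @param prefix output path prefix; writes `<prefix>_dn.tif`,
#'   `<prefix>_theta.tif`, `<prefix>.json`.
#' @param omega_deg,wavelength_nm metadata recorded in the sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_enface_tiff <- function(maps, prefix, omega_deg = NA,
                              wavelength_nm = 1300) {
  stopifnot(inherits(maps, "enface_maps"))
  dn_max <- max(maps$dn_app, na.rm = TRUE)
  dn_scaled <- maps$dn_app / max(dn_max, .Machine$double.eps)
  th_scaled <- (wrap_axial(maps$theta_app) + 90) / 180
  dn_scaled[!is.finite(dn_scaled)] <- 0
  th_scaled[!is.finite(th_scaled)] <- 0
  tiff::writeTIFF(dn_scaled, paste0(prefix, "_dn.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(th_scaled, paste0(prefix, "_theta.tif"),
                  bits.per.sample = 16)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(list(dn_max = dn_max, pixel_um = maps$pixel_um,
                            omega_deg = omega_deg,
                            wavelength_nm = wavelength_nm,
                            generator = "psoct3d"),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname write_enface_tiff
#' @export
read_enface_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dn <- tiff::readTIFF(paste0(prefix, "_dn.tif")) * meta$dn_max
  th <- tiff::readTIFF(paste0(prefix, "_theta.tif")) * 180 - 90
  m <- enface_maps(dn, wrap_axial(th), pixel_um = meta$pixel_um)
  attr(m, "meta") <- meta
  m
}
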