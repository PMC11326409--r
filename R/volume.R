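## Volume assembly from serial blockface slices, color-coded rendering,
## NIfTI vector export, and a minimal deterministic streamline tracker.

#' Stack per-slice orientation maps into a volume
#'
#' Blockface acquisition preserves inter-slice geometry, so slices are
#' stacked in acquisition order with no alignment step.
#'
#' @param slices list of `"axis3d_map"` objects (or lists with matrices
#'   `dn`, `theta`, `alpha`, array `axis` and logical `mask`), congruent
#'   shapes.
#' @param slice_um slice spacing, micrometers (default 150).
#' @param pixel_um in-plane pixel size, micrometers (default 10).
#' @return object of class `"orientation_volume"`: 3D arrays `dn`,
#'   `theta`, `alpha`, `mask`, a 4D array `axis` (x, y, z, component) and
#'   `spacing_um = c(pixel_um, pixel_um, slice_um)`.
#' @export
stack_slices <- function(slices, slice_um = 150, pixel_um = 10) {
  stopifnot(length(slices) >= 1, slice_um > 0, pixel_um > 0)
  dims <- dim(slices[[1]]$dn)
  for (s in slices)
    if (!identical(dim(s$dn), dims)) stop("slice shapes differ")
  nz <- length(slices)
  vol <- list(dn = array(NA_real_, c(dims, nz)),
              theta = array(NA_real_, c(dims, nz)),
              alpha = array(NA_real_, c(dims, nz)),
              mask = array(FALSE, c(dims, nz)),
              axis = array(NA_real_, c(dims, nz, 3L)),
              spacing_um = c(pixel_um, pixel_um, slice_um))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    vol$dn[, , k] <- s$dn; vol$theta[, , k] <- s$theta
    vol$alpha[, , k] <- s$alpha; vol$mask[, , k] <- s$mask
    vol$axis[, , k, ] <- s$axis
  }
  structure(vol, class = "orientation_volume")
}

#' @export
print.orientation_volume <- function(x, ...) {
  d <- dim(x$dn)
  ext <- d * x$spacing_um / 1000
  cat(sprintf(
    "orientation volume: %d x %d x %d voxels (%.2f x %.2f x %.2f mm), %d valid\n",
    d[1], d[2], d[3], ext[1], ext[2], ext[3], sum(x$mask)))
  invisible(x)
}

#' Color-coded orientation rendering
#'
#' `"inplane"` / `"throughplane"` map the angle onto a cyclic hue wheel;
#' `"axis3d"` uses the dMRI convention `|ox|, |oy|, |oz| -> R, G, B`.
#' Brightness is modulated by the birefringence, normalized to its maximum
#' (zero birefringence renders black).
#'
#' @param x an `"axis3d_map"` or an `"orientation_volume"` (then `slice`
#'   selects the plane).
#' @param kind `"inplane"`, `"throughplane"` or `"axis3d"`.
#' @param brightness matrix of birefringence values modulating brightness;
#'   default the object's true-birefringence map.
#' @param slice slice index for volumes.
#' @return `nx x ny x 3` RGB array in `[0, 1]`; masked pixels are black.
#' @export
colorize <- function(x, kind = c("inplane", "throughplane", "axis3d"),
                     brightness = NULL, slice = 1L) {
  kind <- match.arg(kind)
  if (inherits(x, "orientation_volume")) {
    obj <- list(dn = x$dn[, , slice], theta = x$theta[, , slice],
                alpha = x$alpha[, , slice], mask = x$mask[, , slice],
                axis = x$axis[, , slice, ])
  } else obj <- x
  if (is.null(brightness)) brightness <- obj$dn
  b <- brightness
  b[!is.finite(b)] <- 0
  bmax <- max(b, na.rm = TRUE)
  b <- if (bmax > 0) pmin(pmax(b / bmax, 0), 1) else b * 0
  dims <- dim(b)
  rgb <- array(0, c(dims, 3L))
  if (kind == "axis3d") {
    for (k in 1:3) {
      comp <- abs(obj$axis[, , k])
      comp[!is.finite(comp)] <- 0
      rgb[, , k] <- comp * b
    }
  } else {
    ang <- if (kind == "inplane") obj$theta else obj$alpha
    hue <- (wrap_axial(ang) + 90) / 180
    hue[!is.finite(hue)] <- 0
    col <- grDevices::hsv(pmin(1, pmax(0, hue)), 1, 1)
    cm <- grDevices::col2rgb(col) / 255
    for (k in 1:3) rgb[, , k] <- matrix(cm[k, ], dims[1], dims[2]) * b
  }
  rgb
}

#' Export an orientation volume to NIfTI
#'
#' Writes the unit-axis field as a 4D (x, y, z, 3) NIfTI volume and the
#' true birefringence as a scalar volume, with voxel spacing converted to
#' millimeters in the header. Masked voxels export as zero vectors.
#'
#' @param vol an `"orientation_volume"`.
#' @param prefix output prefix; writes `<prefix>_axis.nii.gz` and
#'   `<prefix>_dn.nii.gz`.
#' @return invisibly, the two file paths.
#' @export
export_nifti <- function(vol, prefix) {
  stopifnot(inherits(vol, "orientation_volume"))
  sp_mm <- vol$spacing_um / 1000
  ax <- vol$axis
  ax[!is.finite(ax)] <- 0
  for (k in 1:3) ax[, , , k][!vol$mask] <- 0
  dn <- vol$dn
  dn[!is.finite(dn) | !vol$mask] <- 0
  f_axis <- paste0(prefix, "_axis.nii.gz")
  f_dn <- paste0(prefix, "_dn.nii.gz")
  img_ax <- RNifti::asNifti(ax)
  RNifti::pixdim(img_ax) <- c(sp_mm, 1)
  img_dn <- RNifti::asNifti(dn)
  RNifti::pixdim(img_dn) <- sp_mm
  # NIfTI-2: double-precision header fields, so voxel spacing round-trips
  # exactly
  RNifti::writeNifti(img_ax, f_axis, datatype = "double", version = 2)
  RNifti::writeNifti(img_dn, f_dn, datatype = "double", version = 2)
  invisible(c(axis = f_axis, dn = f_dn))
}

#' @rdname export_nifti
#' @export
read_nifti_volume <- function(prefix) {
  ax <- RNifti::readNifti(paste0(prefix, "_axis.nii.gz"))
  dn <- RNifti::readNifti(paste0(prefix, "_dn.nii.gz"))
  list(axis = unclass(as.array(ax)), dn = unclass(as.array(dn)),
       spacing_mm = RNifti::pixdim(dn)[1:3])
}

#' Deterministic streamline tracking through the axis field
#'
#' Bidirectional fixed-step integration with nearest-neighbor axis lookup.
#' The axis field is axial, so at every step the sign of the local axis is
#' chosen to minimize the turning angle relative to the incoming
#' direction; the streamline terminates when the turning angle exceeds the
#' threshold, a masked voxel or the volume boundary is reached, or the
#' maximum length is exhausted. No intensity threshold is applied.
#'
#' @param vol an `"orientation_volume"`.
#' @param seeds numeric matrix (n x 3) of seed positions in micrometers;
#'   seeds outside the volume are skipped with a warning.
#' @param step_um integration step; default half the in-plane voxel size.
#' @param angle_threshold_deg maximum turning angle per step (default 60).
#' @param max_length_um maximum half-length per direction (default 1e5).
#' @return list of `"streamline"` objects: `points` (m x 3, micrometers),
#'   `seed`, and `termination_reason` (named character of length 2 with
#'   the backward and forward stop reasons: `"angle"`, `"mask"`,
#'   `"bounds"` or `"max_length"`).
#' @export
track_streamlines <- function(vol, seeds, step_um = NULL,
                              angle_threshold_deg = 60,
                              max_length_um = 1e5) {
  stopifnot(inherits(vol, "orientation_volume"))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  if (is.null(step_um)) step_um <- vol$spacing_um[1] / 2
  dims <- dim(vol$mask)
  ext <- dims * vol$spacing_um
  cos_thr <- cos(deg2rad(angle_threshold_deg))
  max_steps <- max(1L, floor(max_length_um / step_um))

  voxel_of <- function(pos) {
    i <- floor(pos / vol$spacing_um) + 1L
    if (any(i < 1L) || any(i > dims)) return(NULL)
    i
  }
  axis_at <- function(i) vol$axis[i[1], i[2], i[3], ]

  march <- function(seed, dir0) {
    pts <- matrix(seed, ncol = 3)
    pos <- seed; dir <- dir0
    for (s in seq_len(max_steps)) {
      nxt <- pos + step_um * dir
      i <- voxel_of(nxt)
      if (is.null(i)) return(list(pts = pts, reason = "bounds"))
      if (!vol$mask[i[1], i[2], i[3]]) return(list(pts = pts, reason = "mask"))
      a <- axis_at(i)
      ca <- sum(a * dir)
      if (ca < 0) { a <- -a; ca <- -ca }     # axial sign disambiguation
      if (ca < cos_thr) return(list(pts = pts, reason = "angle"))
      pos <- nxt
      pts <- rbind(pts, pos)
      dir <- a
    }
    list(pts = pts, reason = "max_length")
  }

  out <- list()
  for (r in seq_len(nrow(seeds))) {
    seed <- as.numeric(seeds[r, ])
    i <- voxel_of(seed)
    if (is.null(i) || !vol$mask[i[1], i[2], i[3]]) {
      warning(sprintf("seed %d outside valid volume; skipped", r))
      next
    }
    a0 <- axis_at(i)
    fwd <- march(seed, a0)
    bwd <- march(seed, -a0)
    pts <- rbind(bwd$pts[rev(seq_len(nrow(bwd$pts))), , drop = FALSE],
                 fwd$pts[-1, , drop = FALSE])
    out[[length(out) + 1L]] <- structure(
      list(points = unname(pts), seed = seed,
           termination_reason = c(backward = bwd$reason,
                                  forward = fwd$reason),
           step_um = step_um),
      class = "streamline")
  }
  out
}

#' @export
print.streamline <- function(x, ...) {
  len <- if (nrow(x$points) > 1)
    sum(sqrt(rowSums(diff(x$points)^2))) else 0
  cat(sprintf("streamline: %d points, length %.1f um, ends: %s / %s\n",
              nrow(x$points), len, x$termination_reason[["backward"]],
              x$termination_reason[["forward"]]))
  invisible(x)
}
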