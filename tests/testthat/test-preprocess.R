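# Retardance-slope birefringence, en-face orientation histograms, and
# affine registration of the tilted view.

make_linear_stack <- function(dn_app, nx = 3, ny = 3, nz = 60, dz = 3,
                              offset = 0, wavelength_nm = 1300) {
  slope <- 360 * dn_app / (wavelength_nm / 1000)   # deg per um
  z <- (seq_len(nz) - 1) * dz
  ret <- array(rep(offset + slope * z, each = nx * ny), c(nx, ny, nz))
  aline_stack(ret, NULL, dz_um = dz, wavelength_nm = wavelength_nm)
}

test_that("synthetic linear retardance profiles invert exactly", {
  st <- make_linear_stack(5.8e-4)
  ab <- apparent_birefringence(st, 150)
  expect_lt(max(abs(ab$dn_app - 5.8e-4)), 1e-9)
  expect_equal(min(ab$r2), 1, tolerance = 1e-12)
})

test_that("the slope ignores constant retardance offsets and flat profiles", {
  a0 <- apparent_birefringence(make_linear_stack(4e-4, offset = 0), 150)
  a7 <- apparent_birefringence(make_linear_stack(4e-4, offset = 70), 150)
  expect_equal(a0$dn_app, a7$dn_app, tolerance = 1e-15)
  flat <- aline_stack(array(25, c(2, 2, 40)), NULL, dz_um = 3)
  expect_true(all(apparent_birefringence(flat, 150)$dn_app == 0))
})

test_that("double-pass retardance input is halved before regression", {
  st_single <- make_linear_stack(5e-4)
  st_double <- aline_stack(st_single$retardance * 2, NULL, dz_um = 3)
  ab <- apparent_birefringence(st_double, 150, double_pass = TRUE)
  expect_equal(ab$dn_app, apparent_birefringence(st_single, 150)$dn_app,
               tolerance = 1e-15)
})

test_that("windows with fewer than 3 samples are masked", {
  st <- make_linear_stack(5e-4, nz = 2)
  expect_true(all(is.na(apparent_birefringence(st, 150)$dn_app)))
})

test_that("en-face orientation takes the depth histogram peak", {
  nz <- 50
  ret <- array(0, c(2, 2, nz))
  ori <- array(30, c(2, 2, nz))
  st <- aline_stack(ret, ori, dz_um = 3)
  expect_true(all(enface_orientation(st, 150, 5) == 30))
  # bimodal 60/40 split: majority bin wins
  ori2 <- array(rep(c(rep(10, 30), rep(80, 20))), c(2, 2, nz))
  st2 <- aline_stack(ret, ori2, dz_um = 3)
  expect_true(all(enface_orientation(st2, 150, 5) == 10))
})

test_that("orientation histogram is wrap-aware at the +/-90 seam", {
  nz <- 40
  ret <- array(0, c(1, 1, nz))
  ori <- array(rep(c(89, -89), nz / 2), c(1, 1, nz))
  st <- aline_stack(ret, ori, dz_um = 3)
  peak <- enface_orientation(st, 150, 5)[1, 1]
  expect_equal(abs(wrap_axial(peak)), 90)   # the -90 bin straddles the seam
})

make_blob_map <- function(n = 64, seed = 1) {
  set.seed(seed)
  img <- matrix(0, n, n)
  for (k in 1:12) {
    cx <- runif(1, 12, n - 12); cy <- runif(1, 12, n - 12)
    img <- img + outer(seq_len(n), seq_len(n),
                       function(x, y) exp(-((x - cx)^2 + (y - cy)^2) / 16))
  }
  img
}

test_that("registration recovers a pure translation within half a pixel", {
  base <- make_blob_map()
  mov <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    si <- i + 5; sj <- j - 3
    if (si >= 1 && si <= 64 && sj >= 1 && sj <= 64)
      mov[si, sj] <- base[i, j]
  }
  r <- register_enface(enface_maps(base, matrix(10, 64, 64)),
                       enface_maps(mov, matrix(10, 64, 64)))
  expect_equal(r$transform$t, c(5, -3), tolerance = 0.5)
  expect_gt(r$transform$ncc, 0.98)
})

test_that("identity input yields the identity transform", {
  base <- make_blob_map(seed = 2)
  r <- register_enface(enface_maps(base, matrix(0, 64, 64)),
                       enface_maps(base, matrix(0, 64, 64)))
  expect_equal(r$transform$A, diag(2), tolerance = 0.01)
  expect_equal(r$transform$t, c(0, 0), tolerance = 0.2)
  expect_equal(r$transform$rotation_deg, 0, tolerance = 0.5)
})

test_that("tilt foreshortening (x-scale cos 15) is recovered", {
  base <- make_blob_map(seed = 3)
  sc <- cos(15 * pi / 180)
  cx <- (64 + 1) / 2
  # moving image: base compressed along x about the center
  mov <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    xs <- (i - cx) / sc + cx      # sample base at stretched coordinate
    i0 <- floor(xs)
    if (i0 >= 1 && i0 + 1 <= 64) {
      f <- xs - i0
      mov[i, j] <- base[i0, j] * (1 - f) + base[i0 + 1, j] * f
    }
  }
  r <- register_enface(enface_maps(base, matrix(0, 64, 64)),
                       enface_maps(mov, matrix(0, 64, 64)))
  expect_equal(r$transform$A[1, 1], sc, tolerance = 0.01)
  expect_equal(r$transform$A[2, 2], 1, tolerance = 0.01)
})

test_that("orientation values are corrected by the registration rotation", {
  base <- make_blob_map(seed = 4)
  phi <- 8 * pi / 180
  cx <- (64 + 1) / 2
  mov <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    # mov is base rotated by +phi about the center (pull from base)
    xs <- cos(phi) * (i - cx) + sin(phi) * (j - cx) + cx
    ys <- -sin(phi) * (i - cx) + cos(phi) * (j - cx) + cx
    i0 <- floor(xs); j0 <- floor(ys)
    if (i0 >= 1 && i0 + 1 <= 64 && j0 >= 1 && j0 + 1 <= 64) {
      fx <- xs - i0; fy <- ys - j0
      mov[i, j] <- base[i0, j0] * (1 - fx) * (1 - fy) +
        base[i0 + 1, j0] * fx * (1 - fy) +
        base[i0, j0 + 1] * (1 - fx) * fy +
        base[i0 + 1, j0 + 1] * fx * fy
    }
  }
  # fibers at 20 deg in the reference appear at 20 + phi in the moving frame
  th_ref <- matrix(20, 64, 64)
  th_mov <- matrix(20 + 8, 64, 64)
  r <- register_enface(enface_maps(base, th_ref),
                       enface_maps(mov, th_mov))
  expect_equal(r$transform$rotation_deg, 8, tolerance = 0.5)
  reg <- r$registered$theta_app
  expect_equal(mean(abs(axial_diff(reg[!is.na(reg)], 20))), 0,
               tolerance = 0.6)
})

test_that("registration aborts below the correlation floor", {
  set.seed(9)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- matrix(runif(32 * 32), 32, 32)
  expect_error(register_enface(enface_maps(a, a * 0),
                               enface_maps(b, b * 0), ncc_floor = 0.9),
               "registration failed")
})

test_that("en-face TIFF round trip preserves values and metadata", {
  skip_if_not_installed("tiff")
  dn <- matrix(seq(0, 8e-4, length.out = 48), 8, 6)
  th <- matrix(seq(-89, 89, length.out = 48), 8, 6)
  maps <- enface_maps(dn, th, pixel_um = 10)
  prefix <- file.path(tempdir(), "enface_test")
  write_enface_tiff(maps, prefix, omega_deg = 15)
  back <- read_enface_tiff(prefix)
  expect_equal(back$dn_app, dn, tolerance = 1e-4)      # 16-bit quantization
  expect_equal(back$theta_app, th, tolerance = 0.005)
  expect_equal(attr(back, "meta")$omega_deg, 15)
  expect_equal(back$pixel_um, 10)
})
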