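# Per-pixel least-squares estimation: objective, branch selection, simplex
# recovery, map fitting, and the brute-force oracle.

test_that("objective vanishes exactly at the generating truth", {
  for (tt in list(c(20, 40), c(0, -30), c(80, 25), c(-45, 0))) {
    pair <- make_pair(tt[1], tt[2], 5e-4)
    v <- biref_vector(tt[1], tt[2], 5e-4)
    expect_lt(pair_objective(v, pair), 1e-24)
  }
})

test_that("objective of an underscaled trial follows the closed form", {
  dn <- 6e-4; omega <- 15
  pair <- make_pair(0, 0, dn, omega)
  half <- biref_vector(0, 0, dn / 2)
  # normal-beam residual 0.5 dn; tilted residual 0.5 dn cos^2(omega), both
  # colinear with the measured vectors
  expected <- (dn / 2)^2 * (1 + cos(omega * pi / 180)^4)
  expect_equal(pair_objective(half, pair), expected, tolerance = 1e-12)
  # in the small-tilt limit both residuals have magnitude 0.5 dn
  pair0 <- make_pair(0, 0, dn, 1e-4)
  expect_equal(pair_objective(biref_vector(0, 0, dn / 2), pair0),
               2 * (dn / 2)^2, tolerance = 1e-9)
})

test_that("objective is invariant under trial-axis negation and branch", {
  pair <- make_pair(30, 20, 5e-4)
  v <- biref_vector(25, 30, 4e-4)
  vneg <- biref_vector_from_axis(-v$axis, v$dn)
  expect_equal(pair_objective(v, pair), pair_objective(vneg, pair))
  # the swapped branch is a rigid rotation of the same problem
  expect_equal(pair_objective(v, pair, branch = "standard"),
               pair_objective(v, pair, branch = "swapped"),
               tolerance = 1e-20)
})

test_that("branch selection swaps at |theta1| >= 45", {
  expect_equal(choose_branch(10), "standard")
  expect_equal(choose_branch(80), "swapped")
  expect_equal(choose_branch(45), "swapped")
  expect_equal(choose_branch(-45), "swapped")
  expect_equal(choose_branch(-44.9), "standard")
  expect_error(choose_branch(NA), "masked")
})

test_that("noiseless single-pixel recovery is sharp", {
  f <- fit_axis3d(make_pair(20, 40, 5e-4))
  expect_false(f$masked)
  expect_lt(abs(f$v_hat$theta - 20), 0.5)
  expect_lt(abs(f$v_hat$alpha - 40), 0.5)
  expect_lt(abs(f$v_hat$dn / 5e-4 - 1), 0.01)
  expect_true(f$converged)
})

test_that("the sign of the through-plane angle is distinguished", {
  fp <- fit_axis3d(make_pair(0, 30, 5e-4))
  fm <- fit_axis3d(make_pair(0, -30, 5e-4))
  expect_equal(fp$v_hat$alpha, 30, tolerance = 0.5)
  expect_equal(fm$v_hat$alpha, -30, tolerance = 0.5)
  expect_true(sign(fp$v_hat$alpha) != sign(fm$v_hat$alpha))
})

test_that("unidentifiable pixels are masked, not estimated", {
  pair <- measurement_pair(NA, 0, NA, 0, 15)
  f <- fit_axis3d(pair)
  expect_true(f$masked)
  expect_equal(coef(f), c(dn = NA_real_, theta = NA_real_, alpha = NA_real_))
})

test_that("noiseless recovery holds over the full angular grid incl. the swap boundary and the co-planar plane", {
  ctl <- axis3d_control(dn_floor = 1e-8)
  # coarse sweep here; the exhaustive grid runs in the acceptance suite
  for (th in c(-85, -45, -15, 0, 15, 40, 44, 45, 46, 50, 85)) {
    for (al in c(-80, -30, 0, 25, 80)) {
      f <- fit_axis3d(make_pair(th, al, 5e-4), ctl)
      expect_lt(abs(axial_diff(f$v_hat$theta, th)), 0.5)
      expect_lt(abs(f$v_hat$alpha - al), 0.5)
      expect_lt(abs(f$v_hat$dn / 5e-4 - 1), 0.01)
    }
  }
})

test_that("true birefringence is invariant to inclination (noiseless)", {
  dn_hats <- vapply(seq(-60, 60, by = 20), function(al)
    fit_axis3d(make_pair(10, al, 6.2e-4))$v_hat$dn, numeric(1))
  expect_lt(stats::sd(dn_hats) / mean(dn_hats), 0.01)
})

test_that("map fitting reproduces the single-pixel result and propagates masks", {
  sim <- make_uniform_sim(c(8, 8), 20, 35, 5e-4)
  sim$pairs$mask[2, 3] <- FALSE
  fit <- fit_axis3d_map(sim$pairs)
  single <- fit_axis3d(make_pair(20, 35, 5e-4))
  expect_false(fit$mask[2, 3])
  expect_true(all(is.na(fit$alpha[!fit$mask])))
  ok <- fit$mask
  expect_equal(unique(round(fit$alpha[ok], 9)),
               round(single$v_hat$alpha, 9))
  expect_equal(unique(round(fit$theta[ok], 9)),
               round(single$v_hat$theta, 9))
  expect_equal(sum(ok), 63)
})

test_that("two homogeneous halves give two uniform output regions", {
  th <- rbind(matrix(10, 4, 8), matrix(70, 4, 8))
  al <- rbind(matrix(20, 4, 8), matrix(-35, 4, 8))
  sim <- simulate_pair_map(phantom_spec(c(8, 8), th, al, 5e-4))
  fit <- fit_axis3d_map(sim$pairs)
  f_top <- fit_axis3d(make_pair(10, 20, 5e-4))
  f_bot <- fit_axis3d(make_pair(70, -35, 5e-4))
  expect_equal(max(abs(fit$alpha[1:4, ] - f_top$v_hat$alpha)), 0)
  expect_equal(max(abs(fit$alpha[5:8, ] - f_bot$v_hat$alpha)), 0)
  expect_true(all(fit$swapped[5:8, ]))
  expect_false(any(fit$swapped[1:4, ]))
})

test_that("map fitting rejects shape mismatches", {
  expect_error(measurement_pair_map(matrix(0, 4, 4), matrix(1e-4, 4, 4),
                                    matrix(0, 4, 5), matrix(1e-4, 4, 5)),
               "dimensions")
})

test_that("the simplex never loses to the brute-force grid", {
  # grid-aligned noiseless truth: the oracle lands exactly on it
  pair <- make_pair(20, 30, 5e-4)
  o <- brute_force_axis3d(pair, grid_step_deg = 5,
                          dn_grid = c(4e-4, 5e-4, 6e-4))
  expect_equal(o$v_hat$theta, 20)
  expect_equal(o$v_hat$alpha, 30)
  expect_equal(o$v_hat$dn, 5e-4)
  expect_lt(o$objective, 1e-24)

  set.seed(101)
  for (k in 1:8) {
    p <- make_noisy_pair(runif(1, -90, 90), runif(1, -75, 75),
                         runif(1, 3e-4, 7e-4))
    f <- fit_axis3d(p, axis3d_control(dn_floor = 1e-8))
    o <- brute_force_axis3d(p, grid_step_deg = 2)
    expect_lte(f$objective, o$objective * (1 + 1e-9) + 1e-16)
  }
})

test_that("the co-planar configuration stays identifiable", {
  # axis in the plane spanned by the two beams (theta = 0)
  for (al in c(-50, -10, 35, 70)) {
    p <- make_pair(0, al, 5e-4)
    f <- fit_axis3d(p)
    o <- brute_force_axis3d(p, grid_step_deg = 1,
                            dn_grid = 5e-4 * seq(0.9, 1.1, 0.05))
    expect_lt(abs(f$v_hat$alpha - al), 0.5)
    expect_lt(abs(o$v_hat$alpha - al), 1 + 1e-9)  # within one grid step
  }
})

test_that("recovery error shows no discontinuity across the swap boundary", {
  errs <- vapply(seq(40, 50, by = 1), function(th) {
    f <- fit_axis3d(make_pair(th, 30, 5e-4))
    max(abs(axial_diff(f$v_hat$theta, th)), abs(f$v_hat$alpha - 30))
  }, numeric(1))
  expect_lt(max(errs), 0.5)
})

test_that("estimation survives realistic orientation and birefringence noise", {
  set.seed(2024)
  errs <- replicate(500, {
    p <- make_noisy_pair(runif(1, -90, 90), 30, 5e-4,
                         sd_theta = 3, sd_dn_rel = 0.05)
    fit_axis3d(p)$v_hat$alpha - 30
  })
  expect_lt(stats::median(abs(errs)), 5)
})

test_that("fit methods expose prediction, residuals and replication", {
  f <- fit_axis3d(make_pair(15, 25, 5e-4))
  pred <- predict(f)                       # tilted beam by default
  expect_s3_class(pred, "apparent_measurement")
  expect_equal(pred$dn_app, f$pair$dn2, tolerance = 1e-6)
  r <- residuals(f)
  expect_named(r, c("normal", "tilted"))
  expect_lt(sqrt(sum(r$normal^2)) + sqrt(sum(r$tilted^2)), 1e-8)
  sims <- simulate(f, nsim = 3, seed = 1, noise_theta_deg = 2)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "measurement_pair")
})
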