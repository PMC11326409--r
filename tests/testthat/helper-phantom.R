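# Shared fixture builders: noiseless and noisy measurement pairs from the
# forward model.

make_pair <- function(theta, alpha, dn, omega_deg = 15) {
  truth <- biref_vector(theta, alpha, dn)
  m1 <- apparent_from_true(truth, beam())
  m2 <- apparent_from_true(truth, beam(omega_deg, "y"))
  measurement_pair(m1$theta_app, m1$dn_app, m2$theta_app, m2$dn_app,
                   omega_deg)
}

make_noisy_pair <- function(theta, alpha, dn, omega_deg = 15,
                            sd_theta = 3, sd_dn_rel = 0.05) {
  truth <- biref_vector(theta, alpha, dn)
  m1 <- apparent_from_true(truth, beam())
  m2 <- apparent_from_true(truth, beam(omega_deg, "y"))
  measurement_pair(
    wrap_axial(m1$theta_app + stats::rnorm(1, 0, sd_theta)),
    max(0, m1$dn_app * (1 + stats::rnorm(1, 0, sd_dn_rel))),
    wrap_axial(m2$theta_app + stats::rnorm(1, 0, sd_theta)),
    max(0, m2$dn_app * (1 + stats::rnorm(1, 0, sd_dn_rel))),
    omega_deg)
}

# uniform-truth maps for small map-level tests
make_uniform_sim <- function(shape, theta, alpha, dn, omega_deg = 15, ...) {
  simulate_pair_map(phantom_spec(shape, theta, alpha, dn, omega_deg, ...))
}
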