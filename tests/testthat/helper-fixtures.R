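# shared fixtures: default geometry/medium, a diffusion LUT, and small
# synthetic inputs built in code at load time

geom0 <- probe_geometry()
med0 <- medium_assumptions()
tau0 <- exp(seq(log(1e-7), log(1e-2), length.out = 50))

# one diffusion LUT for the whole suite (fast to build, deterministic)
lut0 <- build_fd_lut()

# noise-free g2 curve for given flow/optics
make_g2 <- function(bfi_cm2s, beta = 0.5, props = optical_properties(852, 0.015, 0.85),
                    tau = tau0) {
  fl <- flow_model(bfi_cm2s, beta = beta)
  siegert(g1_semi_infinite(props, fl, geom0, tau), beta, tau)
}

# forward FD measurement tibble at given truth
make_fd_meas <- function(mua, musp, wavelength_nm = 730) {
  r <- fd_reflectance(optical_properties(wavelength_nm, mua, musp),
                      med0, geom0, modulation_frequency(geom0, wavelength_nm))
  tibble::tibble(wavelength_nm = wavelength_nm,
                 amplitude = r$amplitude, phase = r$phase)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
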