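test_that("serial replacement matches its closed form and edge cases", {
  proto <- titration_protocol("absorption", n_steps = 12)
  truth <- titration_truth(proto)
  # step 0 is the untouched baseline composition
  expect_equal(truth$nigrosin_g_l[1], 0)
  expect_equal(truth$lipid_pct[1], 0.5)
  # recursion computed independently step by step
  f <- proto$replacement_ml / (proto$fill_volume_l * 1000)
  C <- 0
  for (k in 1:12) {
    C <- C * (1 - f) + proto$nigrosin_stock_g_l * f
    expect_equal(truth$nigrosin_g_l[k + 1], C, tolerance = 1e-12)
  }
  # zero replacement volume leaves the series constant
  const <- titration_truth(titration_protocol("absorption", n_steps = 5,
                                              replacement_ml = 0))
  expect_equal(length(unique(const$mua_730)), 1)
  expect_error(titration_protocol("absorption", n_steps = 2), "3")
})

test_that("titration kinds move their own parameter", {
  abs_t <- titration_truth(titration_protocol("absorption"))
  expect_gt(dplyr::last(abs_t$mua_730) / abs_t$mua_730[1], 3)
  expect_equal(abs_t$musp_730, rep(abs_t$musp_730[1], nrow(abs_t)))
  expect_equal(abs_t$bfi, rep(abs_t$bfi[1], nrow(abs_t)))
  sca_t <- titration_truth(titration_protocol("scattering"))
  expect_gt(dplyr::last(sca_t$musp_730) / sca_t$musp_730[1], 1.5)
  # water displacement slightly lowers absorption
  expect_lt(dplyr::last(sca_t$mua_730), sca_t$mua_730[1])
  flow_t <- titration_truth(titration_protocol("flow"))
  expect_equal(flow_t$rpm, 64 + 7 * (0:10))
  expect_equal(flow_t$bfi / flow_t$bfi[1], flow_t$rpm / 64, tolerance = 1e-12)
})

test_that("streams are reproducible under a fixed seed", {
  truth <- titration_truth(titration_protocol("absorption", n_steps = 3))
  s1 <- simulate_stream(truth, seed = 33)
  s2 <- simulate_stream(truth, seed = 33)
  expect_identical(s1$fd, s2$fd)
  expect_identical(s1$dcs, s2$dcs)
  s3 <- simulate_stream(truth, seed = 34)
  expect_false(identical(s1$fd$amplitude, s3$fd$amplitude))
})

test_that("a zero-noise identity-instrument stream inverts back to truth", {
  truth <- titration_truth(titration_protocol("absorption", n_steps = 4))
  stream <- simulate_stream(truth, noise = noise_spec(0, 0, 0), seed = 1)
  inv <- invert_fd(stream$fd, lut0)
  for (wl in c(730, 830)) {
    got <- inv[inv$wavelength_nm == wl, ]
    expect_rel_equal(got$mua, truth[[paste0("mua_", wl)]], 1e-6)
    expect_rel_equal(got$musp, truth[[paste0("musp_", wl)]], 1e-6)
  }
  cc <- stream$dcs[stream$dcs$time_s == stream$dcs$time_s[1], ]
  props <- optical_properties(852, mean(c(truth$mua_730[1], truth$mua_830[1])),
                              mean(c(truth$musp_730[1], truth$musp_830[1])))
  fit <- invert_dcs(correlation_curve(cc$tau_s, cc$g2), props)
  expect_lt(abs(fit$bfi_cm2s / truth$bfi[1] - 1), 0.01)
})

test_that("doubling amplitude noise doubles recovered-absorption scatter", {
  truth <- tibble::tibble(mua_730 = 0.012, mua_830 = 0.017,
                          musp_730 = 0.9, musp_830 = 0.8,
                          bfi = 1e-8)[rep(1, 150), ]
  s_lo <- simulate_stream(truth, noise = noise_spec(0.005, 0, 0), seed = 5)
  s_hi <- simulate_stream(truth, noise = noise_spec(0.010, 0, 0), seed = 5)
  sd_of <- function(s) {
    inv <- invert_fd(dplyr::filter(s$fd, .data$wavelength_nm == 730), lut0)
    sd(inv$mua)
  }
  ratio <- sd_of(s_hi) / sd_of(s_lo)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("scenario validation enforces the response window and signs", {
  expect_error(subject_scenario(event_peaks_s = c(100, 320)), "240")
  expect_error(subject_scenario(deoxy_amp_pct = c(5, -5)), "negative")
  expect_error(subject_scenario(breathing_hz = 2), "breathing")
})

test_that("sessions are internally consistent and seed-stable", {
  sess <- simulate_scm_session(subject_scenario(seed = 21))
  tr <- sess$truth
  expect_equal(nrow(tr), 960)
  expect_equal(tr$total_um, tr$oxy_um + tr$deoxy_um)
  expect_equal(tr$sto2_pct, 100 * tr$oxy_um / tr$total_um)
  # saturation recomputed from generated pools equals the stored trace
  expect_equal(sto2(tr$oxy_um, tr$total_um), tr$sto2_pct)
  # baseline window means sit at the configured baselines
  first50 <- tr[tr$time_s < 50, ]
  expect_equal(mean(first50$oxy_um), 60, tolerance = 0.01)
  expect_equal(mean(first50$deoxy_um), 30, tolerance = 0.01)
  expect_equal(mean(first50$bfi_cm2s), 1e-8, tolerance = 1e-10)
  # configured signs: oxy rises, deoxy falls
  expect_gt(max(tr$oxy_um), 60)
  expect_lt(min(tr$deoxy_um), 30)
  expect_gt(min(tr$oxy_um), 59.99)
  # deterministic
  sess2 <- simulate_scm_session(subject_scenario(seed = 21))
  expect_identical(sess$fd, sess2$fd)
  # MRO2 trace consistent with the Fick expression
  expect_equal(tr$mro2,
               as.numeric(mro2(tr$bfi_cm2s, tr$sto2_pct, sess$assume)))
})

test_that("the breathing oscillation lands on the raw amplitudes", {
  sess <- simulate_scm_session(subject_scenario(seed = 8,
                                                noise = noise_spec(0, 0, 0)))
  amp730 <- dplyr::filter(sess$fd, .data$wavelength_nm == 730)
  # isolate the oscillation from the slow hemodynamic drift first
  hp <- highpass(time_trace(amp730$time_s, amp730$amplitude))
  sp <- stats::spec.pgram(hp$value, plot = FALSE, taper = 0)
  f_peak <- sp$freq[which.max(sp$spec)] * 2 # per sample -> Hz at 2 Hz rate
  expect_equal(f_peak, 0.25, tolerance = 0.02)
})
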