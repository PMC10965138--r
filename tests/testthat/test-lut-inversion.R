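test_that("grid-node queries recover the node parameters exactly", {
  i <- 17L; j <- 41L
  ch <- lut0$channels$nm730
  res <- invert_fd(tibble::tibble(wavelength_nm = 730,
                                  amplitude = ch$amplitude[i, j],
                                  phase = ch$phase[i, j]),
                   lut0, refine_engine = FALSE)
  expect_equal(res$mua, lut0$mua_grid[i], tolerance = 1e-9)
  expect_equal(res$musp, lut0$musp_grid[j], tolerance = 1e-9)
})

test_that("forward-inverse round trip is accurate on random interior points", {
  set.seed(101)
  n <- 12
  mua <- exp(runif(n, log(0.004), log(0.045)))
  musp <- runif(n, 0.4, 2.3)
  for (wl in c(730, 830)) {
    q <- purrr::map_dfr(seq_len(n), function(i) {
      m <- make_fd_meas(mua[i], musp[i], wl)
      m
    })
    inv <- invert_fd(q, lut0)
    expect_lt(max(abs(inv$mua / mua - 1)), 0.02)
    expect_lt(max(abs(inv$musp / musp - 1)), 0.02)
    # bilinear-only path also meets the round-trip bound
    inv2 <- invert_fd(q, lut0, refine_engine = FALSE)
    expect_lt(max(abs(inv2$mua / mua - 1)), 0.02)
    expect_lt(max(abs(inv2$musp / musp - 1)), 0.02)
  }
})

test_that("LUT inversion matches the direct least-squares oracle", {
  set.seed(7)
  for (k in 1:6) {
    mua <- exp(runif(1, log(0.005), log(0.04)))
    musp <- runif(1, 0.5, 2.2)
    m <- make_fd_meas(mua, musp, 730)
    inv <- invert_fd(m, lut0)
    dir <- fit_direct_fd(m$amplitude, m$phase, 730, med0, geom0)
    expect_equal(inv$mua, dir$mua, tolerance = 1e-4)
    expect_equal(inv$musp, dir$musp, tolerance = 1e-4)
  }
})

test_that("direct fit converges immediately from the true parameters", {
  m <- make_fd_meas(0.013, 1.1, 830)
  fit <- fit_direct_fd(m$amplitude, m$phase, 830, med0, geom0,
                       init = c(mua = 0.013, musp = 1.1))
  expect_true(fit$converged)
  expect_equal(fit$mua, 0.013, tolerance = 1e-6)
  expect_equal(fit$musp, 1.1, tolerance = 1e-6)
})

test_that("out-of-range queries clamp with a flag, or raise in strict mode", {
  m <- make_fd_meas(0.09, 2.4, 730) # mua beyond the table
  expect_warning(inv <- invert_fd(m, lut0, refine_engine = FALSE), "clamped")
  expect_true(inv$lut_clamped)
  expect_error(
    suppressWarnings(invert_fd(m, lut0, refine_engine = FALSE,
                               strict = TRUE)),
    class = "nirsdcs_range")
})

test_that("a planted instrument distortion is recovered exactly", {
  phantom <- tibble::tibble(wavelength_nm = c(730, 830),
                            mua = c(0.012, 0.014), musp = c(1.0, 0.9))
  pred <- purrr::map_dfr(1:2, function(i)
    dplyr::mutate(make_fd_meas(phantom$mua[i], phantom$musp[i],
                               phantom$wavelength_nm[i])))
  raw <- dplyr::mutate(pred, amplitude = amplitude * 2.7,
                       phase = phase + 0.3)
  cal <- calibrate(raw, phantom, med0, geom0)
  expect_equal(cal$gain, c(2.7, 2.7), tolerance = 1e-12)
  expect_equal(cal$phase_offset_rad, c(0.3, 0.3), tolerance = 1e-12)
  # applying the factors to the calibration measurement restores the model
  back <- apply_calibration(raw, cal)
  expect_equal(back$amplitude, pred$amplitude, tolerance = 1e-12)
  expect_equal(back$phase, pred$phase, tolerance = 1e-12)
})

test_that("identity instrument yields identity factors and idempotence", {
  phantom <- tibble::tibble(wavelength_nm = c(730, 830),
                            mua = c(0.012, 0.014), musp = c(1.0, 0.9))
  pred <- purrr::map_dfr(1:2, function(i)
    make_fd_meas(phantom$mua[i], phantom$musp[i], phantom$wavelength_nm[i]))
  cal <- calibrate(pred, phantom, med0, geom0)
  expect_equal(cal$gain, c(1, 1), tolerance = 1e-12)
  expect_equal(cal$phase_offset_rad, c(0, 0), tolerance = 1e-12)
  # calibrating an already-calibrated stream with identity factors
  once <- apply_calibration(pred, cal)
  twice <- apply_calibration(once, identity_calibration())
  expect_equal(twice$amplitude, once$amplitude)
  expect_equal(twice$phase, once$phase)
  expect_error(calibrate(dplyr::mutate(pred, amplitude = -1), phantom),
               "amplitude")
})

test_that("noise-free correlation curves invert to the planted flow index", {
  props <- optical_properties(852, 0.015, 0.85)
  for (bfi in c(1e-8, 5e-8, 2e-7, 1e-6)) {
    fit <- invert_dcs(make_g2(bfi, props = props), props)
    expect_lt(abs(fit$bfi_cm2s / bfi - 1), 0.01)
    expect_equal(fit$beta, 0.5, tolerance = 1e-3)
  }
  # joint direct fit agrees
  fit1 <- invert_dcs(make_g2(5e-8, props = props), props)
  fit2 <- fit_direct_dcs(make_g2(5e-8, props = props), props)
  expect_equal(fit1$bfi_cm2s, fit2$bfi_cm2s, tolerance = 1e-3)
})

test_that("overstated scattering biases the recovered flow index low", {
  props <- optical_properties(852, 0.015, 0.85)
  curve <- make_g2(5e-8, props = props)
  wrong <- optical_properties(852, 0.015, 1.7)
  fit <- invert_dcs(curve, wrong)
  expect_lt(fit$bfi_cm2s, 5e-8)
})

test_that("a flat correlation curve raises a degenerate-curve error", {
  flat <- correlation_curve(tau0, rep(1.5, length(tau0)))
  props <- optical_properties(852, 0.015, 0.85)
  expect_error(invert_dcs(flat, props), class = "nirsdcs_degenerate")
})

test_that("a Monte Carlo engine table is buildable and self-consistent", {
  lut_mc <- build_fd_lut(mua_grid = exp(seq(log(0.006), log(0.03),
                                            length.out = 5)),
                         musp_grid = seq(0.7, 1.4, length.out = 5),
                         engine = "monte_carlo",
                         wavelengths_nm = 730,
                         n_photons = 2e4, seed = 9)
  expect_s3_class(lut_mc, "fd_lut")
  expect_gt(lut_mc$meta$jacobian_consistent_fraction, 0.9)
  ch <- lut_mc$channels$nm730
  res <- invert_fd(tibble::tibble(wavelength_nm = 730,
                                  amplitude = ch$amplitude[3, 3],
                                  phase = ch$phase[3, 3]), lut_mc)
  expect_equal(res$mua, lut_mc$mua_grid[3], tolerance = 1e-6)
  expect_equal(res$musp, lut_mc$musp_grid[3], tolerance = 1e-6)
})

test_that("LUT CSV export round-trips the surfaces", {
  path <- tempfile(fileext = ".csv")
  lut_to_csv(lut0, path)
  df <- read.csv(path, comment.char = "#")
  expect_equal(nrow(df), 2 * 60 * 60)
  i <- 5L; j <- 12L
  row <- df[df$wavelength_nm == 730 &
              abs(df$mua - lut0$mua_grid[i]) < 1e-12 &
              abs(df$musp - lut0$musp_grid[j]) < 1e-12, ]
  expect_equal(row$amplitude, lut0$channels$nm730$amplitude[i, j])
  unlink(path)
})
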