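test_that("percent change from baseline behaves on simple sequences", {
  expect_equal(percent_change_from_baseline(c(2, 4)), c(0, 100))
  expect_equal(percent_change_from_baseline(c(3, 3, 3)), c(0, 0, 0))
  # a linear titration yields a linear percent-change sequence
  v <- 10 * (1 + 0.05 * (0:8))
  pc <- percent_change_from_baseline(v)
  expect_equal(pc, 5 * (0:8), tolerance = 1e-12)
  expect_error(percent_change_from_baseline(c(0, 1)), "baseline")
})

test_that("decibel crosstalk follows the power-ratio convention", {
  expect_equal(crosstalk_db(286, 19), 10 * log10(19 / 286))
  expect_equal(crosstalk_db(286, 19), -11.78, tolerance = 0.005)
  expect_equal(crosstalk_db(50, 50), 0)
  expect_equal(crosstalk_db(100, 10, convention = "amplitude"), -20)
  expect_error(crosstalk_db(0, 5), "undefined")
  # antisymmetry under swapping desired and undesired
  expect_equal(crosstalk_db(300, 12), -crosstalk_db(12, 300))
})

test_that("wavelength-averaged titration summaries match hand arithmetic", {
  expect_equal(titration_summary(544, 286), 415)
  expect_equal(titration_summary(70, 67), 68.5)
  expect_equal(titration_summary(13, -3), 5)
  expect_equal(titration_summary(-8, 1), -3.5)
  expect_equal(titration_summary(4.2, 4.2), 4.2)
})

test_that("linear trend fits report slope, intercept and R^2", {
  x <- 0:9
  exact <- linear_fit(x, 2 + 3 * x)
  expect_equal(exact$slope, 3, tolerance = 1e-12)
  expect_equal(exact$intercept, 2, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  flat <- linear_fit(x, rep(5, 10))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  set.seed(3)
  noisy <- linear_fit(x, 1 + 0.5 * x + rnorm(10, 0, 0.2))
  ci <- confint(noisy$fit)["x", ]
  expect_true(ci[1] < 0.5 && 0.5 < ci[2])
  expect_error(linear_fit(1:2, 1:2), "3 points")
  expect_equal(glance(noisy)$slope, noisy$slope)
})

test_that("the published change table reproduces the printed bound", {
  pairs <- crosstalk_from_changes(published_titration_changes())
  worst <- pairs[1, ]
  expect_equal(worst$undesired, "bfi")
  expect_equal(worst$desired_change_pct, 286)
  expect_equal(worst$crosstalk_db, -11.78, tolerance = 0.005)
  # every pair is attenuated by at least 11 dB
  expect_true(all(pairs$crosstalk_db <= -11))
  # zero undesired changes give the sentinel
  expect_true(any(pairs$crosstalk_db == -Inf))
})

test_that("the floor metric isolates algorithm-added crosstalk from real coupling", {
  steps <- 0:5
  truth <- tibble::tibble(
    titration = "scattering", step = steps,
    mua_730 = 0.010 * (1 - 0.001 * steps), # genuine physical drift
    mua_830 = rep(0.015, 6),
    musp_730 = 1.0 * (1 + 0.2 * steps), musp_830 = 0.9 * (1 + 0.2 * steps),
    bfi = rep(1e-8, 6))
  # a perfect algorithm recovers the truth: excess = 0, floor = -Inf
  perfect <- crosstalk_floor(truth, truth)
  expect_true(all(perfect$crosstalk_db == -Inf))
  # a 1%-of-desired algorithmic leak shows up at -20 dB
  leaky <- truth
  leaky$mua_830 <- truth$mua_830 * (1 + 0.002 * steps) # +1% at final step
  fl <- crosstalk_floor(leaky, truth)
  row <- fl[fl$undesired == "mua_830" & fl$desired == "musp_730", ]
  expect_equal(row$excess_change_pct, 1, tolerance = 1e-9)
  expect_equal(row$crosstalk_db, 10 * log10(1 / 100), tolerance = 1e-6)
  # the genuine mua_730 drift present in both cancels exactly
  drift <- fl[fl$undesired == "mua_730", ]
  expect_true(all(drift$crosstalk_db == -Inf))
})

test_that("the per-step report computes pairs, trends and the worst pair", {
  steps <- 0:6
  data <- tibble::tibble(
    titration = "absorption", step = steps, rpm = NA_real_,
    mua_730 = 0.005 * (1 + 0.5 * steps),
    mua_830 = 0.004 * (1 + 0.3 * steps),
    musp_730 = rep(1, 7), musp_830 = rep(0.9, 7),
    bfi = 1e-8 * (1 + 0.002 * steps))
  rep <- validate_crosstalk(data)
  expect_s3_class(rep, "crosstalk_report")
  expect_true(all(tidy(rep)$crosstalk_db < -20))
  expect_equal(nrow(rep$pairs), 3 * 2) # 3 undesired x 2 desired channels
  musp_rows <- rep$changes[rep$changes$parameter == "musp_730", ]
  expect_equal(musp_rows$final_change_pct, 0)
  expect_equal(glance(rep)$worst_crosstalk_db, max(tidy(rep)$crosstalk_db))
  expect_error(validate_crosstalk(data[1:2, ]), "3 steps")
  expect_error(validate_crosstalk(dplyr::select(data, -"bfi")), "missing")
})
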