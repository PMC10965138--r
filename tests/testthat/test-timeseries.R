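make_trace <- function(value, fs = 2, t0 = 0) {
  n <- length(value)
  time_trace(t0 + (seq_len(n) - 1) / fs, value)
}

test_that("low-pass preserves constants exactly in both modes", {
  tr <- make_trace(rep(7, 400))
  expect_equal(lowpass(tr)$value, rep(7, 400), tolerance = 1e-9)
  expect_equal(lowpass(tr, zero_phase = FALSE)$value, rep(7, 400),
               tolerance = 1e-9)
})

test_that("single-pass attenuation matches the analog Butterworth magnitude", {
  # 0.25 Hz tone sampled fast enough that bilinear warping is negligible
  fs <- 10
  t <- seq(0, 2000, by = 1 / fs)
  tr <- time_trace(t, sin(2 * pi * 0.25 * t))
  y <- lowpass(tr, cutoff_hz = 0.02, order = 2, zero_phase = FALSE)$value
  ss <- y[round(length(y) * 0.5):round(length(y) * 0.95)]
  measured <- sqrt(mean(ss^2)) / sqrt(0.5)
  analog <- 1 / sqrt(1 + (0.25 / 0.02)^4)
  expect_lt(abs(measured / analog - 1), 0.05)
})

test_that("filtering is linear", {
  set.seed(5)
  x <- cumsum(rnorm(300)); y <- cumsum(rnorm(300))
  a <- 2.3; b <- -0.7
  lx <- lowpass(make_trace(x))$value
  ly <- lowpass(make_trace(y))$value
  lxy <- lowpass(make_trace(a * x + b * y))$value
  expect_equal(lxy, a * lx + b * ly, tolerance = 1e-8)
})

test_that("filter rejects unusable inputs", {
  expect_error(lowpass(make_trace(rep(1, 5))), "warm-up")
  slow <- time_trace(seq(0, 300, by = 30), rnorm(11))
  expect_error(lowpass(slow, cutoff_hz = 0.02), "sample rate")
})

test_that("baseline is the mean over the first 50 s only", {
  tr <- make_trace(rep(7, 960))
  expect_equal(baseline_value(tr), 7)
  # sampled ramp a*t on [0, 50): mean of t over 0, 0.5, ..., 49.5
  a <- 0.3
  ramp <- make_trace(a * (0:959) / 2)
  expect_equal(baseline_value(ramp), a * 24.75)
  # locality: later samples do not affect the baseline
  mod <- ramp
  mod$value[ramp$time_s >= 50] <- 1e6
  expect_equal(baseline_value(mod), a * 24.75)
  expect_error(baseline_value(make_trace(rep(1, 20))), "window")
})

test_that("normalization divides by baseline and round-trips", {
  tr <- make_trace(rep(4, 200))
  expect_equal(normalize_trace(tr)$value, rep(1, 200))
  set.seed(1)
  tr2 <- make_trace(10 + rnorm(400, 0, 0.1))
  bl <- baseline_value(tr2)
  norm <- normalize_trace(tr2, bl)
  expect_equal(baseline_value(norm), 1, tolerance = 1e-12)
  expect_equal(norm$value * bl, tr2$value)
  expect_error(normalize_trace(tr2, 0), "baseline")
})

test_that("planted activation events are located and quantified", {
  t <- (0:959) / 2
  # hump peaking at 95 s (+20% of baseline 10) and a valley trace
  hump <- 10 * (1 + 0.2 * exp(-(t - 95)^2 / (2 * 8^2)))
  tr <- time_trace(t, hump)
  fe <- extract_activation(tr, polarity = "peak")
  expect_true(fe$found[1])
  expect_equal(fe$offset_s[1], 35, tolerance = 0.5)
  expect_equal(fe$percent_change[1], 20, tolerance = 0.1)
  dip <- 10 * (1 - 0.12 * exp(-(t - 200)^2 / (2 * 12^2)))
  fv <- extract_activation(time_trace(t, dip), polarity = "valley")
  expect_true(fv$found[2])
  expect_equal(fv$percent_change[2], -12, tolerance = 0.1)
  expect_equal(fv$event_time_s[2], 200, tolerance = 0.5)
})

test_that("flat traces report no activation in either region", {
  fe <- extract_activation(make_trace(rep(3, 960)), polarity = "peak")
  expect_false(any(fe$found))
  short <- make_trace(rep(3, 100))
  expect_error(extract_activation(short), "regions")
})

test_that("feature extraction is invariant to consistent time relabeling", {
  t <- (0:959) / 2
  y <- 5 * (1 + 0.15 * exp(-(t - 110)^2 / (2 * 10^2)))
  f1 <- extract_activation(time_trace(t, y))
  shift <- 30
  w2 <- protocol_windows(baseline = c(30, 90), load = c(90, 150),
                         recovery = c(150, 510),
                         baseline_average = c(30, 80),
                         region1 = c(90, 180), region2 = c(180, 330))
  f2 <- extract_activation(time_trace(t + shift, y), w2)
  expect_equal(f1$offset_s, f2$offset_s)
  expect_equal(f1$percent_change, f2$percent_change)
})

test_that("a double hump survives filtering with little peak displacement", {
  t <- (0:959) / 2
  clean <- 1 + 0.3 * exp(-(t - 100)^2 / (2 * 15^2)) +
    0.25 * exp(-(t - 210)^2 / (2 * 20^2))
  noisy <- clean + 0.05 * sin(2 * pi * 0.25 * t)
  filt <- lowpass(time_trace(t, noisy))
  fe_clean <- extract_activation(lowpass(time_trace(t, clean)))
  fe_noisy <- extract_activation(filt)
  expect_true(all(fe_noisy$found))
  expect_lt(max(abs(fe_noisy$event_time_s - fe_clean$event_time_s)), 2)
})

test_that("breathing tones give the expected breaths per minute", {
  t <- (0:959) / 2
  pure <- time_trace(t, 1 + 0.02 * sin(2 * pi * 0.25 * t))
  rr <- respiration_rate(pure)
  full <- rr[rr$defined, ]
  expect_gt(nrow(full), 10)
  expect_true(all(abs(full$breaths_per_minute - 15) < 0.5))
})

test_that("a rate change across windows is tracked within one breath", {
  t <- (0:1199) / 2 # 600 s
  f1 <- 12 / 60; f2 <- 20 / 60
  phase <- 2 * pi * ifelse(t < 300, f1 * t, f1 * 300 + f2 * (t - 300))
  tr <- time_trace(t, 1 + 0.02 * sin(phase))
  rr <- respiration_rate(tr)
  early <- rr[rr$defined & rr$window_end_s <= 300, ]
  late <- rr[rr$defined & rr$window_start_s >= 330, ]
  expect_true(all(abs(early$breaths_per_minute - 12) < 1))
  expect_true(all(abs(late$breaths_per_minute - 20) < 1))
})

test_that("constant signals yield undefined respiration windows", {
  rr <- respiration_rate(make_trace(rep(2, 960)))
  expect_false(any(rr$defined))
  expect_true(all(is.na(rr$breaths_per_minute)))
})

test_that("g2 block averaging has the right shape and noise reduction", {
  tau <- tau0[1:20]
  base <- make_g2(5e-8, tau = tau)
  # four identical curves average to themselves
  four <- purrr::map_dfr(1:4, function(i)
    tibble::tibble(time_s = (i - 1) / 2, tau_s = tau, g2 = base$g2))
  ds <- downsample_g2(four, 4)
  expect_equal(unique(ds$time_s), mean((0:3) / 2))
  expect_equal(ds$g2, base$g2)
  # N = 10 curves, factor 4 -> 2 output curves
  ten <- purrr::map_dfr(1:10, function(i)
    tibble::tibble(time_s = (i - 1) / 2, tau_s = tau, g2 = base$g2))
  expect_equal(length(unique(downsample_g2(ten, 4)$time_s)), 2)
  # iid noise variance drops by ~4
  set.seed(42)
  n_curves <- 400
  noisy <- purrr::map_dfr(seq_len(n_curves), function(i)
    tibble::tibble(time_s = (i - 1) / 2, tau_s = tau,
                   g2 = base$g2 + rnorm(length(tau), 0, 0.05)))
  dsn <- downsample_g2(noisy, 4)
  v_in <- 0.05^2
  resid <- dsn$g2 - rep(base$g2, length(unique(dsn$time_s)))
  expect_lt(abs(var(resid) / (v_in / 4) - 1), 0.25)
  # mismatched grids refuse
  bad <- dplyr::bind_rows(
    tibble::tibble(time_s = 0, tau_s = tau, g2 = base$g2),
    tibble::tibble(time_s = 0.5, tau_s = tau * 2, g2 = base$g2))
  expect_error(downsample_g2(bad, 2), "grid")
})
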