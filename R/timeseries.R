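#' Parameter time trace
#'
#' A uniformly sampled time series of one extracted parameter, held as a
#' tibble with columns `time_s` and `value` plus `parameter` and
#' `sample_rate_hz` attributes.
#'
#' @param time_s Uniform time grid, seconds.
#' @param value Parameter values (no missing values; gaps must be resolved
#'   upstream).
#' @param parameter Label, e.g. "oxy_um".
#' @return A `time_trace` tibble.
#' @export
time_trace <- function(time_s, value, parameter = "value") {
  if (length(time_s) != length(value)) abort("length mismatch")
  if (anyNA(value)) abort("time trace contains missing values")
  dt <- diff(time_s)
  if (length(dt) > 0 &&
      (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)))
    abort("`time_s` must be a uniform increasing grid")
  out <- tibble(time_s = as.numeric(time_s), value = as.numeric(value))
  attr(out, "parameter") <- parameter
  attr(out, "sample_rate_hz") <- if (length(dt) > 0) 1 / mean(dt) else NA_real_
  class(out) <- c("time_trace", class(out))
  out
}

trace_rate <- function(trace) {
  r <- attr(trace, "sample_rate_hz")
  if (is.null(r) || is.na(r)) 1 / mean(diff(trace$time_s)) else r
}

rewrap_trace <- function(trace, value, parameter = attr(trace, "parameter")) {
  out <- trace
  out$value <- value
  attr(out, "parameter") <- parameter
  out
}

# causal filter started in steady state for the first sample's level, so a
# constant input yields the same constant output from the first sample
steady_filter <- function(flt, x) {
  n <- max(length(flt$a), length(flt$b)) - 1
  dc <- sum(flt$b) / sum(flt$a)
  as.numeric(signal::filter(flt$b, flt$a, x,
                            init = rep(x[1] * dc, n),
                            init.x = rep(x[1], n)))
}

# zero-phase forward-backward application with odd-symmetric edge padding
filtfilt_padded <- function(flt, x) {
  n <- length(x)
  npad <- min(n - 1, 30 * max(length(flt$a), length(flt$b)))
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  ext <- c(pre, x, post)
  y <- steady_filter(flt, ext)
  y <- rev(steady_filter(flt, rev(y)))
  y[seq(npad + 1, npad + n)]
}

single_pass <- function(flt, x) steady_filter(flt, x)

apply_butterworth <- function(trace, cutoff_hz, order, type, zero_phase) {
  fs <- trace_rate(trace)
  if (fs <= 2 * cutoff_hz)
    abort("sample rate must exceed twice the filter cutoff")
  minlen <- 3 * (order + 1)
  if (nrow(trace) < minlen)
    abort("trace shorter than filter warm-up")
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = type)
  y <- if (zero_phase) filtfilt_padded(flt, trace$value)
       else single_pass(flt, trace$value)
  rewrap_trace(trace, as.numeric(y))
}

#' Low-pass filter a parameter trace
#'
#' Second-order Butterworth low-pass with a 0.02 Hz cutoff by default,
#' removing breathing oscillations (0.2-0.3 Hz) from the extracted
#' parameter traces before feature extraction.  Applied zero-phase
#' (forward-backward) by default so event times are not delayed; a causal
#' single pass is available via `zero_phase = FALSE`.  Constant traces are
#' preserved exactly (unit DC gain with steady-state initialization).
#'
#' @param trace A [time_trace()] (or data frame with `time_s`, `value`).
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param order Filter order.
#' @param zero_phase Forward-backward (TRUE, default) or single pass.
#' @return The filtered `time_trace`.
#' @export
lowpass <- function(trace, cutoff_hz = 0.02, order = 2, zero_phase = TRUE) {
  if (!inherits(trace, "time_trace"))
    trace <- time_trace(trace$time_s, trace$value)
  apply_butterworth(trace, cutoff_hz, order, "low", zero_phase)
}

#' High-pass filter a trace
#'
#' Second-order Butterworth high-pass, 0.03 Hz cutoff by default: the
#' respiration-rate pathway, which isolates breathing oscillations from
#' the slow hemodynamic drift in the raw 730 nm amplitude signal.
#'
#' @inheritParams lowpass
#' @return The filtered `time_trace`.
#' @export
highpass <- function(trace, cutoff_hz = 0.03, order = 2, zero_phase = TRUE) {
  if (!inherits(trace, "time_trace"))
    trace <- time_trace(trace$time_s, trace$value)
  apply_butterworth(trace, cutoff_hz, order, "high", zero_phase)
}

#' Baseline value of a trace
#'
#' Arithmetic mean over the initial baseline window, by default the first
#' 50 s (the last 10 s before load onset are excluded to avoid any
#' anticipatory response).
#'
#' @param trace A [time_trace()].
#' @param window Two-element numeric, seconds; samples with
#'   `window[1] <= time_s < window[2]` enter the mean.
#' @return Scalar baseline value.
#' @export
baseline_value <- function(trace, window = c(0, 50)) {
  sel <- trace$time_s >= window[1] & trace$time_s < window[2]
  slack <- 1.5 / trace_rate(trace)
  if (!any(sel) || min(trace$time_s) > window[1] + slack ||
      max(trace$time_s) < window[2] - slack)
    abort("trace does not cover the baseline window")
  mean(trace$value[sel])
}

#' Normalize a trace to its baseline
#'
#' Pointwise division by the baseline value, giving a dimensionless trace
#' whose baseline mean is 1.
#'
#' @param trace A [time_trace()].
#' @param baseline Baseline value (nonzero); defaults to
#'   [baseline_value()] of the trace.
#' @return Normalized `time_trace`.
#' @export
normalize_trace <- function(trace, baseline = baseline_value(trace)) {
  if (!is.finite(baseline) || baseline == 0)
    abort("zero or non-finite baseline")
  rewrap_trace(trace, trace$value / baseline)
}

#' Protocol windows of the loading exercise
#'
#' The 8-minute protocol: 1 min baseline (mean over its first 50 s), 1 min
#' load starting at 60 s, 6 min recovery.  The double-hump activation
#' response is confined to roughly 240 s after load onset; the two regions
#' of activation default to \[60, 150) s and \[150, 300) s and are
#' configurable.
#'
#' @param baseline,load,recovery Two-element windows, seconds.
#' @param baseline_average First part of baseline entering the mean.
#' @param region1,region2 Activation search windows, seconds.
#' @return A `protocol_windows` list.
#' @export
protocol_windows <- function(baseline = c(0, 60), load = c(60, 120),
                             recovery = c(120, 480),
                             baseline_average = c(0, 50),
                             region1 = c(60, 150), region2 = c(150, 300)) {
  for (w in list(baseline, load, recovery, baseline_average, region1, region2))
    if (length(w) != 2 || w[2] <= w[1]) abort("windows must be increasing pairs")
  if (region2[2] > load[1] + 240 + 1e-9)
    warn("region 2 extends beyond 240 s after load onset")
  structure(list(baseline = baseline, load = load, recovery = recovery,
                 baseline_average = baseline_average,
                 region1 = region1, region2 = region2,
                 load_onset_s = load[1]),
            class = "protocol_windows")
}

#' Extract activation features from a filtered trace
#'
#' For each region of activation, locates the extremum of the configured
#' polarity (peak for parameters that rise under load, valley for those
#' that fall, e.g. deoxy \[Hb+Mb\]) and reports its offset from load onset
#' and percent change from baseline.  An event is reported as not found
#' when its deviation from baseline does not exceed `significance` times
#' the residual standard deviation of the baseline window (plus a small
#' absolute floor), so flat or noise-only traces yield `found = FALSE`.
#'
#' @param trace Filtered [time_trace()] covering both regions.
#' @param windows A [protocol_windows()].
#' @param polarity "peak" or "valley".
#' @param baseline Baseline value; defaults to the mean over the
#'   baseline-average window.
#' @param significance Multiple of baseline residual SD required.
#' @return A tibble with one row per region: `region`, `event_time_s`,
#'   `offset_s`, `percent_change`, `polarity`, `found`.
#' @export
extract_activation <- function(trace, windows = protocol_windows(),
                               polarity = c("peak", "valley"),
                               baseline = NULL, significance = 3) {
  polarity <- match.arg(polarity)
  if (max(trace$time_s) < windows$region2[2] - 1.5 / trace_rate(trace) ||
      min(trace$time_s) > windows$region1[1])
    abort("trace does not cover the activation regions")
  if (is.null(baseline))
    baseline <- baseline_value(trace, windows$baseline_average)
  bsel <- trace$time_s >= windows$baseline_average[1] &
    trace$time_s < windows$baseline_average[2]
  noise_sd <- sd(trace$value[bsel] - mean(trace$value[bsel]))
  floor_abs <- 1e-12 + 1e-9 * abs(baseline)
  threshold <- significance * noise_sd + floor_abs
  one_region <- function(region, name) {
    sel <- trace$time_s >= region[1] & trace$time_s < region[2]
    tt <- trace$time_s[sel]
    vv <- trace$value[sel]
    idx <- if (polarity == "peak") which.max(vv) else which.min(vv)
    dev <- vv[idx] - baseline
    found <- if (polarity == "peak") dev > threshold else dev < -threshold
    tibble(region = name,
           event_time_s = if (found) tt[idx] else NA_real_,
           offset_s = if (found) tt[idx] - windows$load_onset_s else NA_real_,
           percent_change = if (found) 100 * dev / baseline else NA_real_,
           polarity = polarity, found = found)
  }
  bind_rows(one_region(windows$region1, "region1"),
            one_region(windows$region2, "region2"))
}

#' Respiration rate from the raw 730 nm amplitude
#'
#' High-pass filters the raw amplitude trace (second-order Butterworth,
#' 0.03 Hz), isolates the breathing band with a gentle low-pass before
#' peak detection (sample-level measurement noise otherwise seeds
#' spurious peaks), detects breath peaks, and reports breaths per minute
#' per 30 s window as 60 s divided by the mean inter-peak period in the
#' window.  Windows with fewer than two peaks are flagged undefined.
#'
#' @param trace Raw amplitude [time_trace()] at the native 2 Hz rate.
#' @param window_length_s Window length, seconds.
#' @param cutoff_hz High-pass cutoff.
#' @param smooth_cutoff_hz Low-pass cutoff of the peak-detection
#'   prefilter (well above the 0.2-0.3 Hz breathing band).
#' @param min_period_s Minimum credible breath period for peak detection.
#' @return Tibble: `window_start_s`, `window_end_s`, `n_peaks`,
#'   `breaths_per_minute` (NA when undefined), `defined`.
#' @export
respiration_rate <- function(trace, window_length_s = 30, cutoff_hz = 0.03,
                             smooth_cutoff_hz = 0.6, min_period_s = 2) {
  fs <- trace_rate(trace)
  if (fs < 2) abort("respiration requires the raw >= 2 Hz stream")
  hp <- highpass(trace, cutoff_hz = cutoff_hz)
  if (smooth_cutoff_hz < fs / 2)
    hp <- lowpass(hp, cutoff_hz = smooth_cutoff_hz)
  v <- hp$value
  amp <- stats::quantile(abs(v), 0.9, names = FALSE)
  pk <- pracma::findpeaks(v, minpeakheight = 0.3 * amp,
                          minpeakdistance = max(1L, round(min_period_s * fs)))
  peak_times <- if (is.null(pk)) numeric(0) else sort(hp$time_s[pk[, 2]])
  t0 <- min(trace$time_s)
  t1 <- max(trace$time_s)
  starts <- seq(t0, t1 - window_length_s + 1e-9, by = window_length_s)
  purrr::map_dfr(starts, function(ws) {
    inwin <- peak_times[peak_times >= ws & peak_times < ws + window_length_s]
    if (length(inwin) < 2) {
      tibble(window_start_s = ws, window_end_s = ws + window_length_s,
             n_peaks = length(inwin), breaths_per_minute = NA_real_,
             defined = FALSE)
    } else {
      period <- mean(diff(inwin))
      tibble(window_start_s = ws, window_end_s = ws + window_length_s,
             n_peaks = length(inwin), breaths_per_minute = 60 / period,
             defined = TRUE)
    }
  })
}

#' Average correlation curves in non-overlapping blocks
#'
#' Downsamples a 2 Hz stream of g2 curves to 0.5 Hz by pointwise averaging
#' of non-overlapping blocks of `factor` curves sharing one lag grid,
#' raising the flow-channel signal-to-noise (averaging n curves divides
#' the g2 noise variance by n).  Output timestamps are block centers.
#'
#' @param curves Long tibble with columns `time_s`, `tau_s`, `g2`.
#' @param factor Curves per block (default 4: 2 Hz to 0.5 Hz).
#' @return Long tibble of `floor(n_curves / factor)` averaged curves.
#' @export
downsample_g2 <- function(curves, factor = 4) {
  times <- sort(unique(curves$time_s))
  taus <- curves$tau_s[curves$time_s == times[1]]
  byt <- split(curves, curves$time_s)
  for (b in byt) {
    if (length(b$tau_s) != length(taus) || any(b$tau_s != taus))
      abort("curves do not share a common tau grid")
  }
  nblock <- floor(length(times) / factor)
  if (nblock < 1) abort("fewer curves than one block")
  purrr::map_dfr(seq_len(nblock), function(k) {
    sel_t <- times[seq((k - 1) * factor + 1, k * factor)]
    g2m <- rowMeans(vapply(sel_t, function(tt) byt[[as.character(tt)]]$g2,
                           numeric(length(taus))))
    tibble(time_s = mean(sel_t), tau_s = taus, g2 = g2m)
  })
}
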