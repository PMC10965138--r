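#' Run configuration
#'
#' Aggregates every tunable of the processing chain with defaults equal to
#' the instrument's stated constants: 25 mm separation; 139/149 MHz
#' modulation; 852 nm flow channel; n = 1.37, g = 0.9; 2 Hz native rate
#' downsampled x4 to 0.5 Hz; 0.02 Hz low-pass and 0.03 Hz high-pass
#' second-order Butterworth; 50 s baseline average; load onset 60 s;
#' 62.5% water / 20% lipid; HGB 14/16 g/dL by sex; SpO2 0.98; venous
#' ratio 0.75; 64,500 g/mol; power-style (10 log10) crosstalk decibels.
#'
#' @param geom,medium,basis,composition,windows Component settings.
#' @param lowpass_cutoff_hz,highpass_cutoff_hz,filter_order,zero_phase
#'   Filter settings.
#' @param downsample_factor g2 averaging factor (2 Hz -> 0.5 Hz).
#' @param db_convention Crosstalk convention, "power" or "amplitude".
#' @param trim_tail_s Optional seconds trimmed from trace ends (cough
#'   artifacts); NULL for none.
#' @param seed Default seed for simulators.
#' @return A `run_config` list.
#' @export
run_config <- function(geom = probe_geometry(),
                       medium = medium_assumptions(),
                       basis = chromophore_basis(),
                       composition = tissue_composition(),
                       windows = protocol_windows(),
                       lowpass_cutoff_hz = 0.02,
                       highpass_cutoff_hz = 0.03,
                       filter_order = 2,
                       zero_phase = TRUE,
                       downsample_factor = 4,
                       db_convention = "power",
                       trim_tail_s = NULL,
                       seed = 1) {
  if (!db_convention %in% c("power", "amplitude"))
    abort("`db_convention` must be 'power' or 'amplitude'")
  if (downsample_factor < 1) abort("`downsample_factor` must be >= 1")
  if (lowpass_cutoff_hz <= 0 || highpass_cutoff_hz <= 0)
    abort("filter cutoffs must be positive")
  structure(list(geom = geom, medium = medium, basis = basis,
                 composition = composition, windows = windows,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 highpass_cutoff_hz = highpass_cutoff_hz,
                 filter_order = filter_order, zero_phase = zero_phase,
                 downsample_factor = downsample_factor,
                 db_convention = db_convention,
                 trim_tail_s = trim_tail_s, seed = seed),
            class = "run_config")
}

# non-overlapping block means of a vector
block_mean <- function(x, factor) {
  n <- floor(length(x) / factor)
  if (n < 1) abort("fewer samples than one block")
  colMeans(matrix(x[seq_len(n * factor)], nrow = factor))
}

#' Invert a raw measurement stream to physiological parameters
#'
#' The full per-timepoint chain: calibrate the raw FD stream, block-average
#' both channels to the effective 0.5 Hz rate (g2 curves averaged
#' pointwise, FD amplitude/phase averaged per block), invert amplitude and
#' phase to (mua, musp) per wavelength through the lookup table, unmix
#' chromophores, fit each averaged g2 curve for BFi conditioned on the
#' recovered optics, and combine saturation and flow into MRO2.
#'
#' @param fd Raw FD tibble: `time_s`, `wavelength_nm`, `amplitude`,
#'   `phase`.
#' @param dcs Raw g2 stream: `time_s`, `tau_s`, `g2`.
#' @param cal [calibrate()] factors (identity factors may be built with
#'   gains 1 / offsets 0).
#' @param lut An [build_fd_lut()] table.
#' @param config A [run_config()].
#' @param assume [metabolic_assumptions()] for MRO2.
#' @param beta Known coherence factor, or NULL to estimate per curve.
#' @return Tibble at the downsampled rate: `time_s`, `mua_730`,
#'   `mua_830`, `musp_730`, `musp_830`, `oxy_um`, `deoxy_um`, `total_um`,
#'   `sto2_pct`, `bfi_cm2s`, `mro2`, plus QC columns (`lut_clamped`,
#'   `chromophore_flag`, `dcs_residual_rms`).
#' @export
process_stream <- function(fd, dcs, cal, lut, config = run_config(),
                           assume = metabolic_assumptions(),
                           beta = NULL) {
  if (nrow(fd) == 0) abort("empty FD stream")
  fd_cal <- apply_calibration(fd, cal)
  f <- config$downsample_factor
  fd_ds <- fd_cal |>
    group_by(.data$wavelength_nm) |>
    arrange(.data$time_s, .by_group = TRUE) |>
    summarise(time_s = list(block_mean(.data$time_s, f)),
              amplitude = list(block_mean(.data$amplitude, f)),
              phase = list(block_mean(.data$phase, f)),
              .groups = "drop") |>
    tidyr::unnest(c("time_s", "amplitude", "phase"))
  inv <- invert_fd(fd_ds, lut)
  wide <- inv |>
    select("time_s", "wavelength_nm", "mua", "musp", "lut_clamped") |>
    tidyr::pivot_wider(names_from = "wavelength_nm",
                       values_from = c("mua", "musp", "lut_clamped"),
                       names_sep = "_")
  names(wide) <- sub("^(mua|musp)_(730|830)$", "\\1_\\2", names(wide))
  wide$lut_clamped <- wide$lut_clamped_730 | wide$lut_clamped_830
  chrom <- unmix(wide, config$basis, config$composition)
  g2ds <- downsample_g2(dcs, f)
  dcs_times <- sort(unique(g2ds$time_s))
  n <- min(nrow(chrom), length(dcs_times))
  chrom <- chrom[seq_len(n), ]
  bfi_prev <- NULL # warm start from the previous timepoint
  flow <- purrr::map_dfr(seq_len(n), function(i) {
    cc <- g2ds[g2ds$time_s == dcs_times[i], ]
    props <- optical_properties(
      config$geom$dcs_wavelength_nm,
      mean(c(chrom$mua_730[i], chrom$mua_830[i])),
      mean(c(chrom$musp_730[i], chrom$musp_830[i])))
    fit <- invert_dcs(correlation_curve(cc$tau_s, cc$g2), props,
                      config$geom, config$medium, beta = beta,
                      bfi_init = bfi_prev)
    bfi_prev <<- fit$bfi_cm2s
    tibble(bfi_cm2s = fit$bfi_cm2s, dcs_beta = fit$beta,
           dcs_residual_rms = fit$residual_rms)
  })
  out <- dplyr::bind_cols(chrom, flow)
  out$mro2 <- as.numeric(mro2(out$bfi_cm2s, out$sto2_pct, assume))
  select(out, "time_s", "mua_730", "mua_830", "musp_730", "musp_830",
         "oxy_um", "deoxy_um", "total_um", "sto2_pct", "bfi_cm2s", "mro2",
         "lut_clamped", "chromophore_flag", "dcs_beta", "dcs_residual_rms")
}

# the six analyzed parameters and their activation polarity
parameter_polarities <- c(oxy_um = "peak", deoxy_um = "valley",
                          total_um = "peak", sto2_pct = "peak",
                          bfi_cm2s = "peak", mro2 = "peak")

#' Extract activation features and respiration from a processed session
#'
#' Applies the trace processing to each of the six parameters of a
#' processed session: optional end-trim, low-pass filtering, baseline
#' over the first 50 s, normalization, and two-region activation feature
#' extraction; computes respiration rate from the raw 730 nm amplitude
#' stream when supplied.
#'
#' @param params Processed tibble from [process_stream()] (or a truth
#'   table with the same parameter columns).
#' @param config A [run_config()].
#' @param fd_raw Optional raw FD stream for the respiration pathway.
#' @param parameters Named polarity vector; defaults to the six standard
#'   parameters.
#' @return List of tibbles: `features` (per parameter x region),
#'   `baselines`, `respiration` (NULL without `fd_raw`).
#' @export
analyze_session <- function(params, config = run_config(), fd_raw = NULL,
                            parameters = parameter_polarities) {
  if (nrow(params) == 0) abort("empty parameter table")
  missing_p <- setdiff(names(parameters), names(params))
  if (length(missing_p) > 0)
    abort(paste("missing parameter columns:",
                paste(missing_p, collapse = ", ")))
  feats <- purrr::imap_dfr(parameters, function(pol, p) {
    tr <- time_trace(params$time_s, params[[p]], parameter = p)
    if (!is.null(config$trim_tail_s)) {
      keep <- tr$time_s <= max(tr$time_s) - config$trim_tail_s
      tr <- time_trace(tr$time_s[keep], tr$value[keep], parameter = p)
    }
    filt <- lowpass(tr, config$lowpass_cutoff_hz, config$filter_order,
                    config$zero_phase)
    bl <- baseline_value(filt, config$windows$baseline_average)
    norm <- normalize_trace(filt, bl)
    fe <- extract_activation(norm, config$windows, polarity = pol,
                             baseline = 1)
    fe$parameter <- p
    fe$baseline_value <- bl
    fe
  })
  resp <- NULL
  if (!is.null(fd_raw)) {
    amp730 <- fd_raw |> filter(.data$wavelength_nm == 730) |>
      arrange(.data$time_s)
    resp <- respiration_rate(
      time_trace(amp730$time_s, amp730$amplitude, "amplitude_730"),
      cutoff_hz = config$highpass_cutoff_hz)
  }
  list(features = select(feats, "parameter", "region", "event_time_s",
                         "offset_s", "percent_change", "polarity", "found",
                         "baseline_value"),
       baselines = feats |> group_by(.data$parameter) |>
         summarise(baseline = first(.data$baseline_value), .groups = "drop"),
       respiration = resp)
}

#' Simulate, measure and recover a full titration
#'
#' Convenience workflow for the crosstalk validation: generates the
#' per-step truth for a protocol, synthesizes `n_repeats` raw
#' measurements per step, pushes them through calibration and both
#' inversions, and returns per-step recovered parameters (mean and SD
#' over repeats) in the layout [validate_crosstalk()] consumes.
#'
#' @param protocol A [titration_protocol()].
#' @param config A [run_config()].
#' @param lut Lookup table (built on demand if NULL).
#' @param noise A [noise_spec()]; use zero SDs for the algorithmic floor.
#' @param n_repeats Measurements per titration step.
#' @param beta Coherence factor used in synthesis and fixed in recovery.
#' @param seed Integer seed.
#' @return Tibble: `titration`, `step`, `rpm`, recovered `mua_730` ...
#'   `bfi` (means over repeats) and `sd_` columns.
#' @export
recover_titration <- function(protocol, config = run_config(), lut = NULL,
                              noise = noise_spec(0, 0, 0), n_repeats = 5,
                              beta = 0.5, seed = 1) {
  truth <- titration_truth(protocol)
  if (is.null(lut)) lut <- build_fd_lut(medium = config$medium,
                                        geom = config$geom)
  truth_rep <- truth[rep(seq_len(nrow(truth)), each = n_repeats), ]
  stream <- simulate_stream(truth_rep, config$geom, config$medium,
                            noise = noise, beta = beta, seed = seed)
  # the synthetic stream carries no instrument distortion, so the
  # reference-phantom step reduces to the identity factors; a planted
  # distortion would be removed here by calibrate() on the baseline step
  fd_cal <- apply_calibration(stream$fd, identity_calibration())
  inv <- invert_fd(fd_cal, lut)
  step_of_row <- rep(truth$step, each = n_repeats)
  inv$step <- step_of_row[match(inv$time_s, sort(unique(inv$time_s)))]
  opt_by_step <- inv |>
    group_by(.data$step, .data$wavelength_nm) |>
    summarise(mua = mean(.data$mua), musp = mean(.data$musp),
              sd_mua = sd(.data$mua), sd_musp = sd(.data$musp),
              .groups = "drop")
  wide <- opt_by_step |>
    tidyr::pivot_wider(names_from = "wavelength_nm",
                       values_from = c("mua", "musp", "sd_mua", "sd_musp"))
  dcs_times <- sort(unique(stream$dcs$time_s))
  bfi_rows <- purrr::map_dfr(seq_along(dcs_times), function(i) {
    cc <- stream$dcs[stream$dcs$time_s == dcs_times[i], ]
    k <- step_of_row[i]
    w <- wide[wide$step == k, ]
    props <- optical_properties(config$geom$dcs_wavelength_nm,
                                mean(c(w$mua_730, w$mua_830)),
                                mean(c(w$musp_730, w$musp_830)))
    fit <- invert_dcs(correlation_curve(cc$tau_s, cc$g2), props,
                      config$geom, config$medium, beta = beta)
    tibble(step = k, bfi_one = fit$bfi_cm2s)
  })
  bfi_by_step <- bfi_rows |>
    group_by(.data$step) |>
    summarise(bfi = mean(.data$bfi_one), sd_bfi = sd(.data$bfi_one),
              .groups = "drop")
  out <- wide |>
    left_join(bfi_by_step, by = "step") |>
    mutate(titration = protocol$kind,
           rpm = truth$rpm[match(.data$step, truth$step)])
  select(out, "titration", "step", "rpm", "mua_730", "mua_830",
         "musp_730", "musp_830", "bfi",
         dplyr::starts_with("sd_"))
}

#' Write / read the canonical CSV layouts
#'
#' Long trace CSV: `time_s`, `parameter`, `value`, `units`,
#' `subject_id`, `condition`.  Feature CSV: `subject_id`, `condition`,
#' `parameter`, `region`, `offset_s`, `percent_change`, `polarity`,
#' `found`.
#'
#' @param params Wide processed tibble ([process_stream()] output).
#' @param path File path.
#' @param subject_id,condition Identifiers stamped into the file.
#' @return `path` invisibly (writers); tibble (readers).
#' @export
write_trace_csv <- function(params, path, subject_id = "S01",
                            condition = "moderate") {
  units <- c(oxy_um = "uM", deoxy_um = "uM", total_um = "uM",
             sto2_pct = "percent", bfi_cm2s = "cm^2/s",
             mro2 = "mol_Hb*cm^2/(dL*s)")
  long <- params |>
    select("time_s", dplyr::all_of(names(units))) |>
    tidyr::pivot_longer(-"time_s", names_to = "parameter",
                        values_to = "value") |>
    mutate(units = units[.data$parameter],
           subject_id = subject_id, condition = condition)
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("time_s", "parameter", "value")
  if (!all(need %in% names(df)))
    abort(paste("malformed trace CSV; need columns:",
                paste(need, collapse = ", ")))
  df
}

#' @rdname write_trace_csv
#' @param features Feature tibble from [analyze_session()].
#' @export
write_feature_csv <- function(features, path, subject_id = "S01",
                              condition = "moderate") {
  out <- features |>
    mutate(subject_id = subject_id, condition = condition) |>
    select("subject_id", "condition", "parameter", "region", "offset_s",
           "percent_change", "polarity", "found")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Identity calibration record
#'
#' Gain 1 and phase offset 0 for both wavelengths: the instrument-free
#' calibration used when processing already-calibrated or synthetic
#' model-scale streams.
#'
#' @return A `calibration_factors` tibble.
#' @export
identity_calibration <- function() {
  cal <- tibble(wavelength_nm = c(730, 830), gain = c(1, 1),
                phase_offset_rad = c(0, 0))
  class(cal) <- c("calibration_factors", class(cal))
  cal
}
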