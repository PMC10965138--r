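# local seeded evaluation that restores the caller's RNG state
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Measurement noise specification
#'
#' Instrument-grade noise levels for the simulators: multiplicative
#' amplitude noise and additive phase noise on the frequency-domain
#' channels, and a correlation-noise scale for g2 curves following a
#' simplified multi-tau Koppel structure, `sd(tau_j) = scale *
#' sqrt(1 + beta * g1(tau_j)^2) / sqrt(j)` (later lag bins carry more
#' intra-correlator averaging).
#'
#' @param amplitude_sd_frac Multiplicative amplitude noise SD (fraction).
#' @param phase_sd_rad Additive phase noise SD, radians.
#' @param g2_scale Koppel-type g2 noise scale at the first lag bin.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(amplitude_sd_frac = 0.005, phase_sd_rad = 0.001,
                       g2_scale = 0.002) {
  if (amplitude_sd_frac < 0 || phase_sd_rad < 0 || g2_scale < 0)
    abort("noise SDs must be >= 0")
  structure(list(amplitude_sd_frac = amplitude_sd_frac,
                 phase_sd_rad = phase_sd_rad, g2_scale = g2_scale),
            class = "noise_spec")
}

#' Liquid-phantom titration protocol
#'
#' The three instrument-validation titrations on Intralipid/nigrosin
#' liquid phantoms: absorption (replace 0.48 mL of the batch with 1.5 g/L
#' nigrosin in matched 0.5% Intralipid per step), scattering (replace
#' 2 mL with 20% Intralipid stock, from a 0.39% batch), and flow
#' (constant 0.35% batch stirred at 64 rpm, +7 rpm per step).  Fill
#' volume defaults to 1.0 L.  Optical constants of the dye and emulsion
#' are package defaults chosen to land per-step changes in the
#' few-hundred-percent range such instruments are validated over.
#'
#' @param kind "absorption", "scattering" or "flow".
#' @param n_steps Titration steps after baseline (>= 3).
#' @param fill_volume_l Batch volume, litres.
#' @param replacement_ml Replacement volume per step, mL.
#' @param baseline_lipid_pct Baseline Intralipid concentration, percent.
#' @param nigrosin_stock_g_l Nigrosin stock concentration, g/L.
#' @param lipid_stock_pct Intralipid stock concentration, percent.
#' @param rpm_start,rpm_step Stirrer speeds for the flow titration.
#' @param bfi_at_start_cm2s Flow index at the starting stirrer speed
#'   (BFi is modeled linear in rpm); also the Brownian BFi of the
#'   unstirred titrations.
#' @param nigrosin_mua_mm_per_g_l Specific absorption of nigrosin at
#'   (730, 830) nm, 1/mm per g/L.
#' @param lipid_musp_mm_per_pct Reduced scattering per percent lipid at
#'   (730, 830) nm, 1/mm.
#' @return A `titration_protocol` list.
#' @export
titration_protocol <- function(kind = c("absorption", "scattering", "flow"),
                               n_steps = NULL,
                               fill_volume_l = 1.0,
                               replacement_ml = NULL,
                               baseline_lipid_pct = NULL,
                               nigrosin_stock_g_l = 1.5,
                               lipid_stock_pct = 20,
                               rpm_start = 64, rpm_step = 7,
                               bfi_at_start_cm2s = 1e-8,
                               nigrosin_mua_mm_per_g_l = c(0.7, 0.4),
                               lipid_musp_mm_per_pct = c(1.8, 1.5)) {
  kind <- match.arg(kind)
  if (is.null(n_steps))
    n_steps <- switch(kind, absorption = 20, scattering = 10, flow = 10)
  if (n_steps < 3) abort("need at least 3 titration steps")
  if (is.null(replacement_ml))
    replacement_ml <- switch(kind, absorption = 0.48, scattering = 2,
                             flow = 0)
  if (is.null(baseline_lipid_pct))
    baseline_lipid_pct <- switch(kind, absorption = 0.5, scattering = 0.39,
                                 flow = 0.35)
  if (fill_volume_l <= 0) abort("fill volume must be positive")
  if (replacement_ml < 0) abort("replacement volume must be >= 0")
  structure(list(kind = kind, n_steps = n_steps,
                 fill_volume_l = fill_volume_l,
                 replacement_ml = replacement_ml,
                 baseline_lipid_pct = baseline_lipid_pct,
                 nigrosin_stock_g_l = nigrosin_stock_g_l,
                 lipid_stock_pct = lipid_stock_pct,
                 rpm_start = rpm_start, rpm_step = rpm_step,
                 bfi_at_start_cm2s = bfi_at_start_cm2s,
                 nigrosin_mua_mm_per_g_l = nigrosin_mua_mm_per_g_l,
                 lipid_musp_mm_per_pct = lipid_musp_mm_per_pct),
            class = "titration_protocol")
}

# optical properties of the phantom composition at both FD wavelengths
phantom_optics <- function(protocol, lipid_pct, nigrosin_g_l,
                           basis = chromophore_basis()) {
  lipid_frac <- lipid_pct / 100
  water_frac <- 1 - lipid_frac
  mua <- water_frac * basis$mua_water_cm / 10 +
    lipid_frac * basis$mua_lipid_cm / 10 +
    nigrosin_g_l * protocol$nigrosin_mua_mm_per_g_l
  musp <- lipid_pct * protocol$lipid_musp_mm_per_pct
  list(mua_730 = mua[1], mua_830 = mua[2],
       musp_730 = musp[1], musp_830 = musp[2])
}

#' True per-step phantom parameters along a titration
#'
#' Applies the serial-replacement recursion
#' `C_{k+1} = C_k (1 - v/V) + C_stock (v/V)` to the titrated constituent
#' (equivalently the closed form
#' `C_k = C_0 (1-v/V)^k + C_stock (1 - (1-v/V)^k)`), maps composition to
#' optical properties via the packaged dye/emulsion constants, and maps
#' stirrer speed linearly to BFi for the flow titration.
#'
#' @param protocol A [titration_protocol()].
#' @return Tibble: `step`, `rpm`, `lipid_pct`, `nigrosin_g_l`,
#'   `mua_730`, `mua_830`, `musp_730`, `musp_830`, `bfi` (cm^2/s).
#' @export
titration_truth <- function(protocol) {
  k <- 0:protocol$n_steps
  f <- protocol$replacement_ml / (protocol$fill_volume_l * 1000)
  keep <- (1 - f)^k
  lipid <- rep(protocol$baseline_lipid_pct, length(k))
  nig <- rep(0, length(k))
  rpm <- rep(NA_real_, length(k))
  bfi <- rep(protocol$bfi_at_start_cm2s, length(k))
  if (protocol$kind == "absorption") {
    nig <- protocol$nigrosin_stock_g_l * (1 - keep)
  } else if (protocol$kind == "scattering") {
    lipid <- protocol$baseline_lipid_pct * keep +
      protocol$lipid_stock_pct * (1 - keep)
  } else {
    rpm <- protocol$rpm_start + protocol$rpm_step * k
    bfi <- protocol$bfi_at_start_cm2s * rpm / protocol$rpm_start
  }
  opt <- purrr::map2_dfr(lipid, nig,
                         ~ as_tibble(phantom_optics(protocol, .x, .y)))
  out <- tibble(step = k, rpm = rpm, lipid_pct = lipid, nigrosin_g_l = nig)
  out <- dplyr::bind_cols(out, opt)
  out$bfi <- bfi
  out
}

# default correlator lag grid, seconds
default_tau_grid <- function(n = 50) exp(seq(log(1e-7), log(1e-2),
                                             length.out = n))

# Koppel-style per-bin g2 noise SD
g2_noise_sd <- function(g1_vals, beta, scale) {
  scale * sqrt(1 + beta * g1_vals^2) / sqrt(seq_along(g1_vals))
}

#' Simulate a raw measurement stream from a truth timeline
#'
#' Evaluates the forward models at each timepoint of a truth timeline
#' (per-timepoint `mua_730`, `mua_830`, `musp_730`, `musp_830`, `bfi`),
#' applies an instrument distortion (per-wavelength amplitude gain and
#' phase offset), adds measurement noise, and returns the raw
#' frequency-domain stream together with the g2 curve stream.
#' Deterministic under a fixed seed.
#'
#' @param truth Tibble with one row per timepoint (columns above; an
#'   optional `time_s` column is kept, otherwise timepoints are placed at
#'   `rate_hz`).
#' @param geom,medium Geometry and medium assumptions.
#' @param gain Named amplitude gains, e.g. `c(nm730 = 1, nm830 = 1)`.
#' @param phase_offset_rad Named phase offsets, radians.
#' @param noise A [noise_spec()].
#' @param beta Coherence factor of the synthesized g2 curves.
#' @param tau_s Correlator lag grid.
#' @param rate_hz Sampling rate (default 2 Hz).
#' @param seed Integer seed.
#' @return List with `fd` (tibble `time_s`, `wavelength_nm`, `amplitude`,
#'   `phase`) and `dcs` (long tibble `time_s`, `tau_s`, `g2`).
#' @export
simulate_stream <- function(truth, geom = probe_geometry(),
                            medium = medium_assumptions(),
                            gain = c(nm730 = 1, nm830 = 1),
                            phase_offset_rad = c(nm730 = 0, nm830 = 0),
                            noise = noise_spec(), beta = 0.5,
                            tau_s = default_tau_grid(), rate_hz = 2,
                            seed = 1) {
  n <- nrow(truth)
  time_s <- if ("time_s" %in% names(truth)) truth$time_s
            else (seq_len(n) - 1) / rate_hz
  with_seed_local(seed, {
    fd <- purrr::map_dfr(c(730, 830), function(wl) {
      chn <- paste0("nm", wl)
      mua <- truth[[paste0("mua_", wl)]]
      musp <- truth[[paste0("musp_", wl)]]
      rc <- diffusion_reflectance_complex(
        mua, musp, geom$source_detector_separation_mm,
        2 * pi * modulation_frequency(geom, wl) * 1e6, medium)
      amp <- Mod(rc) * gain[[chn]] *
        (1 + stats::rnorm(n, 0, noise$amplitude_sd_frac))
      ph <- -Arg(rc) + phase_offset_rad[[chn]] +
        stats::rnorm(n, 0, noise$phase_sd_rad)
      tibble(time_s = time_s, wavelength_nm = wl,
             amplitude = amp, phase = ph)
    })
    dcs <- purrr::map_dfr(seq_len(n), function(i) {
      props <- optical_properties(geom$dcs_wavelength_nm,
                                  mean(c(truth$mua_730[i], truth$mua_830[i])),
                                  mean(c(truth$musp_730[i], truth$musp_830[i])))
      fl <- flow_model(truth$bfi[i], beta = beta,
                       dcs_wavelength_nm = geom$dcs_wavelength_nm,
                       refractive_index = medium$refractive_index)
      g1v <- g1_semi_infinite(props, fl, geom, tau_s, medium)
      g2v <- 1 + beta * g1v^2 +
        stats::rnorm(length(tau_s), 0,
                     g2_noise_sd(g1v, beta, noise$g2_scale))
      tibble(time_s = time_s[i], tau_s = tau_s, g2 = g2v)
    })
    list(fd = fd, dcs = dcs)
  })
}

# smooth gamma-shaped bump, unit peak at t = peak_s, onset rise scale
# width_s (peak sits width_s after onset), shape exponent kappa
gamma_bump <- function(t, peak_s, width_s, kappa = 3) {
  t0 <- peak_s - width_s
  x <- pmax(t - t0, 0) / width_s
  x^kappa * exp(kappa * (1 - x))
}

#' Subject scenario for a loading session
#'
#' Defines the ground truth of one synthetic sternocleidomastoid loading
#' session: baseline physiology, the double-hump activation response
#' (two events inside the 240 s window after load onset at 60 s; deoxy
#' responds negatively, oxy and flow positively), breathing, and noise.
#'
#' @param sex "female" or "male" (sets the metabolic HGB default).
#' @param oxy_baseline_um,deoxy_baseline_um Baseline concentrations, uM.
#' @param bfi_baseline_cm2s Baseline flow index.
#' @param musp_730,musp_830 Constant reduced scattering, 1/mm.
#' @param event_peaks_s Peak times of the two activation events, s.
#' @param event_widths_s Rise scales of the two events, s.
#' @param oxy_amp_pct,deoxy_amp_pct,bfi_amp_pct Event amplitudes as
#'   percent of baseline (two per parameter; deoxy must be negative).
#' @param breathing_hz Breathing frequency (0.2-0.3 Hz band).
#' @param breathing_depth Fractional amplitude modulation on the raw
#'   730 nm channel (830 nm gets half, BFi gets twice, mirroring where
#'   respiration shows up in the raw signals).
#' @param beta Coherence factor.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return A `subject_scenario` list.
#' @export
subject_scenario <- function(sex = c("female", "male"),
                             oxy_baseline_um = 60, deoxy_baseline_um = 30,
                             bfi_baseline_cm2s = 1e-8,
                             musp_730 = 0.9, musp_830 = 0.8,
                             event_peaks_s = c(100, 210),
                             event_widths_s = c(25, 40),
                             oxy_amp_pct = c(8, 6),
                             deoxy_amp_pct = c(-10, -8),
                             bfi_amp_pct = c(120, 90),
                             breathing_hz = 0.25,
                             breathing_depth = 0.01,
                             beta = 0.5,
                             noise = noise_spec(),
                             seed = 1) {
  sex <- match.arg(sex)
  if (any(event_peaks_s < 60) || any(event_peaks_s > 300))
    abort("event peaks must lie within 240 s after load onset (60-300 s)")
  if (any(deoxy_amp_pct >= 0)) abort("deoxy amplitudes must be negative")
  if (breathing_hz < 0.05 || breathing_hz > 1)
    abort("implausible breathing frequency")
  structure(list(sex = sex, oxy_baseline_um = oxy_baseline_um,
                 deoxy_baseline_um = deoxy_baseline_um,
                 bfi_baseline_cm2s = bfi_baseline_cm2s,
                 musp_730 = musp_730, musp_830 = musp_830,
                 event_peaks_s = event_peaks_s,
                 event_widths_s = event_widths_s,
                 oxy_amp_pct = oxy_amp_pct,
                 deoxy_amp_pct = deoxy_amp_pct,
                 bfi_amp_pct = bfi_amp_pct,
                 breathing_hz = breathing_hz,
                 breathing_depth = breathing_depth,
                 beta = beta, noise = noise, seed = seed),
            class = "subject_scenario")
}

#' Simulate a full loading session
#'
#' Generates the 480 s (8 min) session at 2 Hz: true parameter traces
#' (oxy, deoxy, total \[Hb+Mb\], StO2, BFi, MRO2, internally consistent —
#' total is the sum, StO2 the ratio, MRO2 the Fick expression), and the
#' raw measurement streams synthesized from the implied (mua, musp, BFi)
#' path with breathing oscillations on the raw observables and
#' measurement noise.
#'
#' @param scenario A [subject_scenario()].
#' @param geom,medium,basis,composition Forward-model assumptions.
#' @param gain,phase_offset_rad Instrument distortion for the raw stream.
#' @param duration_s,rate_hz Session length and rate.
#' @return List: `truth` (wide tibble of the six true traces plus the
#'   underlying mua/musp path), `fd`, `dcs` (raw streams), `scenario`,
#'   `assume` (the [metabolic_assumptions()] used).
#' @export
simulate_scm_session <- function(scenario = subject_scenario(),
                                 geom = probe_geometry(),
                                 medium = medium_assumptions(),
                                 basis = chromophore_basis(),
                                 composition = tissue_composition(),
                                 gain = c(nm730 = 1, nm830 = 1),
                                 phase_offset_rad = c(nm730 = 0, nm830 = 0),
                                 duration_s = 480, rate_hz = 2) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  bump2 <- function(amps_pct) {
    gamma_bump(t, scenario$event_peaks_s[1], scenario$event_widths_s[1]) *
      amps_pct[1] / 100 +
      gamma_bump(t, scenario$event_peaks_s[2], scenario$event_widths_s[2]) *
      amps_pct[2] / 100
  }
  oxy <- scenario$oxy_baseline_um * (1 + bump2(scenario$oxy_amp_pct))
  deoxy <- scenario$deoxy_baseline_um * (1 + bump2(scenario$deoxy_amp_pct))
  bfi <- scenario$bfi_baseline_cm2s * (1 + bump2(scenario$bfi_amp_pct))
  total <- oxy + deoxy
  sto2_t <- 100 * oxy / total
  assume <- metabolic_assumptions(scenario$sex)
  mro2_t <- as.numeric(mro2(bfi, sto2_t, assume))
  mua <- mua_from_chromophores(oxy, deoxy, basis, composition)
  truth <- tibble(time_s = t,
                  oxy_um = oxy, deoxy_um = deoxy, total_um = total,
                  sto2_pct = sto2_t, bfi_cm2s = bfi, mro2 = mro2_t,
                  mua_730 = mua$mua_730, mua_830 = mua$mua_830,
                  musp_730 = scenario$musp_730,
                  musp_830 = scenario$musp_830)
  breath <- sin(2 * pi * scenario$breathing_hz * t)
  stream_truth <- tibble(time_s = t,
                         mua_730 = truth$mua_730, mua_830 = truth$mua_830,
                         musp_730 = truth$musp_730,
                         musp_830 = truth$musp_830,
                         bfi = bfi * (1 + 2 * scenario$breathing_depth * breath))
  raw <- simulate_stream(stream_truth, geom, medium, gain, phase_offset_rad,
                         noise = scenario$noise, beta = scenario$beta,
                         rate_hz = rate_hz, seed = scenario$seed)
  # multiplicative breathing on the raw FD amplitudes (strongest at 730 nm)
  depth <- c(nm730 = scenario$breathing_depth,
             nm830 = scenario$breathing_depth / 2)
  raw$fd <- raw$fd |>
    mutate(amplitude = .data$amplitude *
             (1 + depth[paste0("nm", .data$wavelength_nm)] *
                sin(2 * pi * scenario$breathing_hz * .data$time_s)))
  list(truth = truth, fd = raw$fd, dcs = raw$dcs,
       scenario = scenario, assume = assume)
}
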