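#' Fresnel angular moments and effective boundary reflection
#'
#' Integrates the unpolarized internal Fresnel reflectance over the fluence
#' and flux angular weightings to obtain the partial-current boundary
#' coefficients and the effective reflection coefficient
#' `Reff = (R_phi + R_j) / (2 - R_phi + R_j)` used by the extrapolated
#' boundary condition.
#'
#' @param n_rel Relative index of refraction (inside / outside).
#' @return List with `r_phi`, `r_j`, `r_eff`.
#' @export
fresnel_moments <- function(n_rel) {
  rf <- function(theta) {
    ci <- cos(theta)
    st2 <- n_rel^2 * sin(theta)^2
    r <- rep(1, length(theta))
    ok <- st2 < 1
    ct <- sqrt(pmax(1 - st2[ok], 0))
    rs <- (n_rel * ci[ok] - ct) / (n_rel * ci[ok] + ct)
    rp <- (n_rel * ct - ci[ok]) / (n_rel * ct + ci[ok])
    r[ok] <- 0.5 * (rs^2 + rp^2)
    r
  }
  r_phi <- stats::integrate(function(th) 2 * sin(th) * cos(th) * rf(th),
                            0, pi / 2, rel.tol = 1e-10)$value
  r_j <- stats::integrate(function(th) 3 * sin(th) * cos(th)^2 * rf(th),
                          0, pi / 2, rel.tol = 1e-10)$value
  list(r_phi = r_phi, r_j = r_j,
       r_eff = (r_phi + r_j) / (2 - r_phi + r_j))
}

# Complex diffusion reflectance at radii rho (mm) for angular modulation
# frequency omega (rad/s).  Extrapolated-boundary dipole with the hybrid
# fluence + flux exit current.  Units: per injected photon per mm^2.
diffusion_reflectance_complex <- function(mua, musp, rho, omega, medium) {
  mut <- mua + musp
  D <- 1 / (3 * mut)
  z0 <- 1 / mut
  zb <- 2 * D * (1 + medium$effective_reflection) /
    (1 - medium$effective_reflection)
  v <- speed_of_light_mm_s / medium$refractive_index # mm/s
  k <- sqrt(complex(real = mua, imaginary = omega / v) / D)
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  phi <- (exp(-k * r1) / r1 - exp(-k * r2) / r2) / (4 * pi * D)
  jz <- (z0 * (k + 1 / r1) * exp(-k * r1) / r1^2 +
           (z0 + 2 * zb) * (k + 1 / r2) * exp(-k * r2) / r2^2) / (4 * pi)
  c_phi <- (1 - medium$r_phi) / 4
  c_j <- (1 - medium$r_j) / 2
  c_phi * phi + c_j * jz
}

#' Frequency-domain diffuse reflectance (diffusion theory)
#'
#' Amplitude and phase of the intensity-modulated diffuse reflectance of a
#' semi-infinite homogeneous medium, evaluated with the extrapolated-boundary
#' photon-diffusion Green's function at the probe's source-detector
#' separation.  This is the continuous-model forward engine behind the
#' default lookup tables; the Monte Carlo engine ([mc_time_resolved()])
#' provides the transport-level cross-check.
#'
#' Phase convention: the returned `phase` is the phase *lag* of the detected
#' photon-density wave, reported positive and increasing with separation and
#' modulation frequency.  At zero modulation frequency the lag is exactly 0.
#'
#' @param props An [optical_properties()] record (scalar `mua`, `musp`).
#' @param medium A [medium_assumptions()] record.
#' @param geom A [probe_geometry()] record.
#' @param f_mod_mhz Modulation frequency, MHz (>= 0).
#' @param rho_mm Optional separation override, mm (defaults to the probe's).
#' @return A tibble with columns `amplitude` (per photon per mm^2) and
#'   `phase` (radians, lag-positive).
#' @export
#' @examples
#' fd_reflectance(optical_properties(730, 0.01, 1.0),
#'                medium_assumptions(), probe_geometry(), 139)
fd_reflectance <- function(props, medium = medium_assumptions(),
                           geom = probe_geometry(), f_mod_mhz,
                           rho_mm = geom$source_detector_separation_mm) {
  if (any(props$mua <= 0) || any(props$musp <= 0))
    abort("optical properties must be positive")
  if (any(f_mod_mhz < 0)) abort("`f_mod_mhz` must be >= 0")
  omega <- 2 * pi * f_mod_mhz * 1e6
  rc <- diffusion_reflectance_complex(props$mua, props$musp, rho_mm,
                                      omega, medium)
  tibble(amplitude = Mod(rc), phase = -Arg(rc))
}

# Annulus-averaged complex diffusion reflectance over [rho_min, rho_max]
# with 2*pi*rho weighting; used to compare against the Monte Carlo band
# tally, across which R(rho) varies substantially.
diffusion_reflectance_annulus <- function(mua, musp, rho_min, rho_max,
                                          omega, medium, n_quad = 64) {
  rho <- seq(rho_min, rho_max, length.out = n_quad)
  wts <- rho
  rc <- diffusion_reflectance_complex(mua, musp, rho, omega, medium)
  sum(rc * wts) / sum(wts)
}

#' Time-resolved Monte Carlo diffuse reflectance
#'
#' Photon random walk in a semi-infinite homogeneous medium with
#' Henyey-Greenstein scattering, continuous absorption weight attenuation
#' with survival roulette, and Fresnel partial reflection at the tissue-air
#' boundary.  Escaping weight is tallied into an annular band around the
#' source-detector separation, time-resolved by total path length; the
#' histogram is Fourier-transformed at the modulation frequency to the
#' complex frequency-domain reflectance.  The walk is driven by a
#' self-contained seeded generator, so identical seeds give bit-identical
#' histograms.
#'
#' @inheritParams fd_reflectance
#' @param n_photons Photons to launch (>= 1e5 advisable for usable
#'   statistics at 25 mm).
#' @param seed Integer seed for the transport random walk.
#' @param annulus_halfwidth_mm Detector band half-width around the
#'   separation (default 2 mm).
#' @param bin_ps Time bin width, picoseconds (default 10).
#' @param t_max_ns Last time-of-flight tallied, ns (default 10).
#' @param vthr_rel Importance-window threshold relative to the launch
#'   value; smaller is slower but lower-variance.
#' @param roulette_threshold,roulette_survive Classic low-weight
#'   survival roulette settings.
#' @return A list of class `mc_reflectance`: `histogram` (tibble
#'   `t_bin_start_ps`, `reflectance_weight`), the derived `amplitude`
#'   (per photon per mm^2) and `phase` (lag-positive radians) at
#'   `f_mod_mhz`, detected statistics including the relative standard
#'   error of the detected weight, and metadata (seed, photon count,
#'   geometry) sufficient to rebuild it.
#' @export
mc_time_resolved <- function(props, medium = medium_assumptions(),
                             geom = probe_geometry(), f_mod_mhz,
                             n_photons = 1e6, seed = 1,
                             annulus_halfwidth_mm = 2,
                             bin_ps = 10, t_max_ns = 10,
                             vthr_rel = 1e-3,
                             roulette_threshold = 1e-3,
                             roulette_survive = 0.1) {
  if (any(props$mua <= 0) || any(props$musp <= 0))
    abort("optical properties must be positive")
  rho <- geom$source_detector_separation_mm
  res <- mc_transport_cpp(props$mua, props$musp, medium$anisotropy_g,
                          medium$refractive_index / medium$n_outside,
                          rho - annulus_halfwidth_mm,
                          rho + annulus_halfwidth_mm,
                          bin_ps * 1e-3, t_max_ns,
                          n_photons, seed, vthr_rel, 0.5, 2L,
                          roulette_threshold)
  if (res$det <= 0)
    abort("no photons detected in the annulus: degenerate output",
          class = "nirsdcs_degenerate")
  area <- pi * ((rho + annulus_halfwidth_mm)^2 -
                  (rho - annulus_halfwidth_mm)^2)
  nb <- length(res$hist)
  bin_ns <- bin_ps * 1e-3
  t_ns <- (seq_len(nb) - 0.5) * bin_ns
  omega_per_ns <- 2 * pi * f_mod_mhz * 1e6 * 1e-9
  ft <- sum(res$hist * exp(complex(imaginary = -omega_per_ns * t_ns))) /
    (n_photons * area)
  structure(
    list(histogram = tibble(t_bin_start_ps = (seq_len(nb) - 1) * bin_ps,
                            reflectance_weight = res$hist),
         amplitude = Mod(ft), phase = -Arg(ft),
         f_mod_mhz = f_mod_mhz,
         detected_weight = res$det,
         n_detected_events = res$nev,
         relative_se = sqrt(res$sumsq) / res$det,
         total_escaped_weight = res$totesc,
         steps = res$steps,
         meta = list(mua = props$mua, musp = props$musp,
                     g = medium$anisotropy_g,
                     n = medium$refractive_index,
                     rho_mm = rho, annulus_halfwidth_mm = annulus_halfwidth_mm,
                     bin_ps = bin_ps, t_max_ns = t_max_ns,
                     vthr_rel = vthr_rel,
                     roulette_threshold = roulette_threshold,
                     n_photons = n_photons, seed = seed)),
    class = "mc_reflectance")
}

#' @export
print.mc_reflectance <- function(x, ...) {
  cat(sprintf(
    "<mc_reflectance> %g photons, %.0f detected events\n amplitude %.4g /mm^2, phase lag %.4f rad @ %g MHz\n",
    x$meta$n_photons, x$n_detected_events, x$amplitude, x$phase, x$f_mod_mhz))
  invisible(x)
}

#' Field autocorrelation of a semi-infinite medium with Brownian dynamics
#'
#' Solution of the correlation diffusion equation for a point source on a
#' semi-infinite homogeneous medium with the extrapolated boundary
#' condition.  Brownian motion of the scatterers adds a dynamic absorption
#' term `2 * musp * k0^2 * Db * tau` to the static `mua`, where `Db` is the
#' blood flow index and `k0` the in-medium optical wavenumber; the
#' normalized field autocorrelation is the ratio of the Green's function at
#' lag `tau` to its `tau = 0` value, so `g1(0) = 1` and g1 decreases
#' strictly in both `tau` and `Db`.
#'
#' @param props [optical_properties()] at the flow-channel wavelength.
#' @param flow A [flow_model()] (uses `bfi_cm2s` and `k0_mm`).
#' @param geom A [probe_geometry()].
#' @param tau_s Positive ascending lag grid, seconds.
#' @param medium A [medium_assumptions()].
#' @return Numeric vector of g1 values on `tau_s`.
#' @export
g1_semi_infinite <- function(props, flow, geom, tau_s,
                             medium = medium_assumptions()) {
  if (flow$bfi_cm2s < 0) abort("`bfi_cm2s` must be >= 0")
  if (any(tau_s < 0) || is.unsorted(tau_s, strictly = FALSE))
    abort("`tau_s` must be non-negative ascending")
  db_mm2s <- flow$bfi_cm2s * 100 # cm^2/s -> mm^2/s
  mut <- props$mua + props$musp
  D <- 1 / (3 * mut)
  z0 <- 1 / mut
  zb <- 2 * D * (1 + medium$effective_reflection) /
    (1 - medium$effective_reflection)
  rho <- geom$source_detector_separation_mm
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  kd <- function(tau) {
    # dynamic absorption 2 * musp * k0^2 * Db * tau added to the static mua,
    # scaled by the same D as the boundary terms for internal consistency
    sqrt((props$mua + 2 * props$musp * flow$k0_mm^2 * db_mm2s * tau) / D)
  }
  green <- function(tau) {
    k <- kd(tau)
    exp(-k * r1) / r1 - exp(-k * r2) / r2
  }
  green(tau_s) / green(0)
}

#' Siegert relation
#'
#' Links the normalized field autocorrelation to the measured intensity
#' autocorrelation: `g2(tau) = 1 + beta * g1(tau)^2`, with the coherence
#' factor `beta` set by the detection optics.
#'
#' @param g1_values Field autocorrelation values.
#' @param beta Coherence factor in (0, 1].
#' @param tau_s Optional lag grid; if supplied a [correlation_curve()] is
#'   returned, otherwise a bare numeric vector of g2 values.
#' @return g2 values or a `correlation_curve`.
#' @export
#' @examples
#' siegert(1, 0.5) # 1.5
siegert <- function(g1_values, beta, tau_s = NULL) {
  if (!is.numeric(beta) || beta <= 0 || beta > 1)
    abort("`beta` must lie in (0, 1].")
  g2 <- 1 + beta * g1_values^2
  if (is.null(tau_s)) return(g2)
  correlation_curve(tau_s, g2, beta = beta)
}
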