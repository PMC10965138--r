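#' Optical and geometric parameter objects
#'
#' Lightweight validated parameter records used across the forward models,
#' lookup tables and simulators.  All are plain named lists with a class
#' attribute so they print compactly and travel well inside tibble
#' list-columns.
#'
#' @name parameter-objects
NULL

speed_of_light_mm_s <- 2.99792458e11 # mm / s

#' Medium assumptions for photon transport
#'
#' Bulk-tissue assumptions shared by the diffusion and Monte Carlo engines:
#' index of refraction (default 1.37, typical soft tissue), scattering
#' anisotropy g (default 0.9), and the effective boundary reflection
#' coefficient derived from the index mismatch via the Fresnel angular
#' moments.
#'
#' @param refractive_index Index of refraction of the medium (>= 1).
#' @param anisotropy_g Henyey-Greenstein anisotropy, in [0, 1).
#' @param n_outside Index of the non-scattering half-space (air, 1.0).
#' @return A `medium_assumptions` list with fields `refractive_index`,
#'   `anisotropy_g`, `n_outside`, `effective_reflection`, and the Fresnel
#'   moments `r_phi`, `r_j` used by the partial-current boundary condition.
#' @export
#' @examples
#' medium_assumptions()$effective_reflection
medium_assumptions <- function(refractive_index = 1.37, anisotropy_g = 0.9,
                               n_outside = 1.0) {
  if (!is.numeric(refractive_index) || refractive_index < 1)
    abort("`refractive_index` must be a number >= 1.")
  if (!is.numeric(anisotropy_g) || anisotropy_g < 0 || anisotropy_g >= 1)
    abort("`anisotropy_g` must lie in [0, 1).")
  fm <- fresnel_moments(refractive_index / n_outside)
  structure(
    list(refractive_index = refractive_index,
         anisotropy_g = anisotropy_g,
         n_outside = n_outside,
         r_phi = fm$r_phi, r_j = fm$r_j,
         effective_reflection = fm$r_eff),
    class = "medium_assumptions")
}

#' Probe geometry and modulation settings
#'
#' Source-detector separation and per-channel modulation frequencies of the
#' combined probe: 25 mm separation, 139 MHz at 730 nm and 149 MHz at
#' 830 nm for the frequency-domain channels, 852 nm for the flow channel.
#'
#' @param source_detector_separation_mm Separation, mm (> 0).
#' @param modulation_frequency_730_mhz,modulation_frequency_830_mhz
#'   Modulation frequencies, MHz.
#' @param dcs_wavelength_nm Flow-channel laser wavelength, nm.
#' @return A `probe_geometry` list.
#' @export
probe_geometry <- function(source_detector_separation_mm = 25,
                           modulation_frequency_730_mhz = 139,
                           modulation_frequency_830_mhz = 149,
                           dcs_wavelength_nm = 852) {
  stopifnot(source_detector_separation_mm > 0,
            modulation_frequency_730_mhz > 0,
            modulation_frequency_830_mhz > 0,
            dcs_wavelength_nm > 0)
  structure(
    list(source_detector_separation_mm = source_detector_separation_mm,
         modulation_frequency_730_mhz = modulation_frequency_730_mhz,
         modulation_frequency_830_mhz = modulation_frequency_830_mhz,
         dcs_wavelength_nm = dcs_wavelength_nm),
    class = "probe_geometry")
}

#' Modulation frequency (MHz) for a wavelength channel
#' @param geom A [probe_geometry()].
#' @param wavelength_nm 730 or 830.
#' @return Frequency in MHz.
#' @export
modulation_frequency <- function(geom, wavelength_nm) {
  ifelse(wavelength_nm < 780,
         geom$modulation_frequency_730_mhz,
         geom$modulation_frequency_830_mhz)
}

#' Optical properties at one wavelength
#'
#' @param wavelength_nm Wavelength, nm.
#' @param mua Absorption coefficient, 1/mm (> 0).
#' @param musp Reduced scattering coefficient, 1/mm (> 0).
#' @return An `optical_properties` list.  If `musp <= mua` the diffusion
#'   approximation is dubious; the object is returned with
#'   `diffusion_valid = FALSE` and a warning rather than an error.
#' @export
optical_properties <- function(wavelength_nm, mua, musp) {
  if (!is.numeric(mua) || any(mua <= 0))
    abort("`mua` must be positive.")
  if (!is.numeric(musp) || any(musp <= 0))
    abort("`musp` must be positive.")
  ok <- musp > mua
  if (!all(ok))
    warn("musp <= mua: outside the diffusion regime; results are flagged.")
  structure(list(wavelength_nm = wavelength_nm, mua = mua, musp = musp,
                 diffusion_valid = all(ok)),
            class = "optical_properties")
}

#' Brownian flow model for the correlation channel
#'
#' @param bfi_cm2s Blood flow index (effective Brownian diffusion
#'   coefficient, alpha-Db), cm^2/s, >= 0.
#' @param beta Coherence factor in (0, 1].
#' @param dcs_wavelength_nm Laser wavelength, nm.
#' @param refractive_index Medium index used for the in-medium wavenumber.
#' @return A `flow_model` list including the in-medium wavenumber
#'   `k0_mm` (1/mm).
#' @export
flow_model <- function(bfi_cm2s, beta = 0.5, dcs_wavelength_nm = 852,
                       refractive_index = 1.37) {
  if (!is.numeric(bfi_cm2s) || any(bfi_cm2s < 0))
    abort("`bfi_cm2s` must be >= 0.")
  if (!is.numeric(beta) || beta <= 0 || beta > 1)
    abort("`beta` must lie in (0, 1].")
  k0 <- 2 * pi * refractive_index / (dcs_wavelength_nm * 1e-6) # 1/mm
  structure(list(bfi_cm2s = bfi_cm2s, beta = beta,
                 dcs_wavelength_nm = dcs_wavelength_nm,
                 refractive_index = refractive_index, k0_mm = k0),
            class = "flow_model")
}

#' Intensity autocorrelation curve
#'
#' @param tau_s Lag grid, seconds, strictly increasing and positive.
#' @param g2 Intensity autocorrelation values.
#' @param beta Optional known coherence factor.
#' @return A `correlation_curve` tibble with columns `tau_s`, `g2` and a
#'   `beta` attribute.
#' @export
correlation_curve <- function(tau_s, g2, beta = NA_real_) {
  if (any(tau_s <= 0) || any(diff(tau_s) <= 0))
    abort("`tau_s` must be positive and strictly increasing.")
  if (length(tau_s) != length(g2))
    abort("`tau_s` and `g2` lengths differ.")
  out <- tibble(tau_s = as.numeric(tau_s), g2 = as.numeric(g2))
  attr(out, "beta") <- beta
  class(out) <- c("correlation_curve", class(out))
  out
}

#' @export
print.medium_assumptions <- function(x, ...) {
  cat(sprintf("<medium> n = %.3f, g = %.2f, Reff = %.4f\n",
              x$refractive_index, x$anisotropy_g, x$effective_reflection))
  invisible(x)
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("<probe> rho = %g mm, f = %g/%g MHz, DCS %g nm\n",
              x$source_detector_separation_mm,
              x$modulation_frequency_730_mhz, x$modulation_frequency_830_mhz,
              x$dcs_wavelength_nm))
  invisible(x)
}
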