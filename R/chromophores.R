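#' Chromophore extinction basis for the 730/830 nm pair
#'
#' Decadic molar extinction coefficients of oxy- and deoxy-hemoglobin (the
#' myoglobin pool is spectrally inseparable in this band and is carried
#' jointly as \[Hb+Mb\]) and background absorption spectra of water and
#' lipid.  Values are packaged constants taken from the standard published
#' compilations (Prahl's hemoglobin tabulation; Segelstein-type water;
#' van Veen-type lipid) at the two laser lines; they are approximate
#' single-wavelength reads of those curves.
#'
#' @param wavelengths_nm The two wavelengths, default `c(730, 830)`.
#' @param eps_oxy,eps_deoxy Molar extinction, 1/(mM cm), one per wavelength.
#' @param mua_water,mua_lipid Absorption of pure water / pure lipid,
#'   1/cm, one per wavelength (scaled by volume fraction when used).
#' @return A `chromophore_basis` list; includes the 2x2 extinction matrix
#'   `E` (rows = wavelengths, cols = oxy, deoxy) and its condition number.
#' @export
#' @examples
#' chromophore_basis()$condition
chromophore_basis <- function(wavelengths_nm = c(730, 830),
                              eps_oxy = c(0.390, 0.974),
                              eps_deoxy = c(1.1022, 0.693),
                              mua_water = c(0.0204, 0.0292),
                              mua_lipid = c(0.0042, 0.0082)) {
  if (any(eps_oxy <= 0) || any(eps_deoxy <= 0))
    abort("extinction coefficients must be positive")
  E <- cbind(oxy = eps_oxy, deoxy = eps_deoxy)
  rownames(E) <- paste0("nm", wavelengths_nm)
  d <- det(E)
  if (abs(d) < 1e-12) abort("singular extinction basis")
  structure(
    list(wavelengths_nm = wavelengths_nm, E = E,
         mua_water_cm = mua_water, mua_lipid_cm = mua_lipid,
         condition = kappa(E, exact = TRUE),
         source = paste("compiled hemoglobin/water/lipid spectra",
                        "(standard published compilations, approximate)")),
    class = "chromophore_basis")
}

#' Tissue background composition
#'
#' Fixed water and lipid volume fractions assumed for muscle when
#' subtracting the background absorption before hemoglobin unmixing:
#' 62.5% water and 20% lipid.
#'
#' @param water_fraction,lipid_fraction Volume fractions in \[0, 1\],
#'   summing to at most 1.
#' @return A `tissue_composition` list.
#' @export
tissue_composition <- function(water_fraction = 0.625, lipid_fraction = 0.20) {
  if (water_fraction < 0 || water_fraction > 1 ||
      lipid_fraction < 0 || lipid_fraction > 1 ||
      water_fraction + lipid_fraction > 1)
    abort("fractions must lie in [0,1] and sum to <= 1")
  structure(list(water_fraction = water_fraction,
                 lipid_fraction = lipid_fraction),
            class = "tissue_composition")
}

#' Metabolic model assumptions
#'
#' Literature-based constants entering the Fick-principle metabolic rate:
#' blood hemoglobin concentration (14 g/dL female, 16 g/dL male), arterial
#' saturation 98%, venous fraction of the probed blood volume 0.75, and
#' hemoglobin molecular weight 64,500 g/mol.
#'
#' @param sex "female" or "male"; sets the default `hgb_g_dl`.
#' @param hgb_g_dl Blood hemoglobin concentration, g/dL.
#' @param spo2 Peripheral arterial oxygen saturation, fraction in (0, 1].
#' @param venous_ratio Venous fraction of probed blood volume, (0, 1].
#' @param mw_hb_g_mol Hemoglobin molecular weight, g/mol.
#' @return A `metabolic_assumptions` list.
#' @export
metabolic_assumptions <- function(sex = c("female", "male"),
                                  hgb_g_dl = NULL,
                                  spo2 = 0.98,
                                  venous_ratio = 0.75,
                                  mw_hb_g_mol = 64500) {
  sex <- match.arg(sex)
  if (is.null(hgb_g_dl)) hgb_g_dl <- if (sex == "male") 16 else 14
  if (spo2 <= 0 || spo2 > 1) abort("`spo2` must lie in (0, 1]")
  if (venous_ratio <= 0 || venous_ratio > 1)
    abort("`venous_ratio` must lie in (0, 1]")
  if (hgb_g_dl <= 0 || mw_hb_g_mol <= 0)
    abort("`hgb_g_dl` and `mw_hb_g_mol` must be positive")
  structure(list(sex = sex, hgb_g_dl = hgb_g_dl, spo2 = spo2,
                 venous_ratio = venous_ratio, mw_hb_g_mol = mw_hb_g_mol),
            class = "metabolic_assumptions")
}

#' Unmix per-wavelength absorption into oxy/deoxy \[Hb+Mb\]
#'
#' Subtracts the water and lipid background from the measured absorption at
#' 730 and 830 nm, then solves Beer's law
#' `mua_residual = ln(10) * E %*% C` for the concentration pair
#' `C = (oxy, deoxy)` in mM, reported in uM together with total and tissue
#' saturation.  Negative concentrations are carried through and flagged,
#' never clipped: they are diagnostic of calibration or model errors.
#'
#' @param data A data frame with columns `mua_730` and `mua_830` (1/mm);
#'   or a single pair given as `mua_730`/`mua_830` numeric arguments.
#' @param basis A [chromophore_basis()].
#' @param composition A [tissue_composition()].
#' @return The input tibble with columns `oxy_um`, `deoxy_um`, `total_um`,
#'   `sto2_pct`, and `chromophore_flag` (TRUE where any concentration or
#'   residual absorption is negative).
#' @export
#' @examples
#' unmix(tibble::tibble(mua_730 = 0.0144, mua_830 = 0.0202))
unmix <- function(data, basis = chromophore_basis(),
                  composition = tissue_composition()) {
  if (!is.data.frame(data))
    abort("`data` must be a data frame with columns mua_730, mua_830")
  need <- c("mua_730", "mua_830")
  if (!all(need %in% names(data)))
    abort("`data` must contain columns mua_730 and mua_830")
  # mm^-1 -> cm^-1, background subtraction
  bg <- composition$water_fraction * basis$mua_water_cm +
    composition$lipid_fraction * basis$mua_lipid_cm
  res_730 <- unname(data$mua_730 * 10 - bg[1])
  res_830 <- unname(data$mua_830 * 10 - bg[2])
  Einv <- solve(log(10) * basis$E)
  oxy_mM <- Einv[1, 1] * res_730 + Einv[1, 2] * res_830
  deoxy_mM <- Einv[2, 1] * res_730 + Einv[2, 2] * res_830
  oxy <- oxy_mM * 1e3
  deoxy <- deoxy_mM * 1e3
  total <- oxy + deoxy
  out <- as_tibble(data)
  out$oxy_um <- oxy
  out$deoxy_um <- deoxy
  out$total_um <- total
  out$sto2_pct <- ifelse(total > 0, 100 * oxy / total, NA_real_)
  out$chromophore_flag <- res_730 < 0 | res_830 < 0 | oxy < 0 | deoxy < 0
  if (any(out$chromophore_flag))
    warn(sprintf("%d timepoint(s) with negative residual absorption or concentration (flagged)",
                 sum(out$chromophore_flag)))
  out
}

# forward construction: mua (1/mm) per wavelength from concentrations (uM)
# plus water/lipid background; inverse of unmix() by design
mua_from_chromophores <- function(oxy_um, deoxy_um,
                                  basis = chromophore_basis(),
                                  composition = tissue_composition()) {
  bg <- composition$water_fraction * basis$mua_water_cm +
    composition$lipid_fraction * basis$mua_lipid_cm
  C <- rbind(oxy_um, deoxy_um) * 1e-3 # mM
  mua_cm <- log(10) * (basis$E %*% C) + bg
  tibble(mua_730 = unname(mua_cm[1, ] / 10),
         mua_830 = unname(mua_cm[2, ] / 10))
}

#' Tissue oxygen saturation
#'
#' `StO2 = 100 * oxy / total`, in percent.
#'
#' @param oxy_um Oxy \[Hb+Mb\], uM.
#' @param total_um Total \[Hb+Mb\], uM (> 0).
#' @return Saturation in percent.
#' @export
#' @examples
#' sto2(40, 100) # 40
sto2 <- function(oxy_um, total_um) {
  if (any(total_um <= 0)) abort("`total_um` must be positive: saturation undefined")
  100 * oxy_um / total_um
}

#' Metabolic rate of oxygen via Fick's principle
#'
#' Combines oxygen delivery (blood flow index scaled by blood hemoglobin
#' content) with oxygen extraction (arterial minus tissue saturation,
#' referred to the venous compartment):
#'
#' `MRO2 = HGB * BFi * (SpO2 - StO2) / (venous_ratio * mw_Hb)`
#'
#' Units are tracked explicitly: g/dL x cm^2/s / (g/mol) = mol Hb cm^2
#' dL^-1 s^-1; the returned attribute `units` records the bookkeeping.
#' The one-line printed form of this equation is typographically ambiguous
#' about whether the venous ratio divides the saturation difference or
#' only StO2; both groupings are implemented and selected by `grouping`.
#'
#' @param bfi_cm2s Blood flow index, cm^2/s.
#' @param sto2_pct Tissue saturation, percent (0-100 scale; values are
#'   converted to fractions internally, and passing an apparent fraction
#'   <= 1 raises a scale-mismatch error).
#' @param assume A [metabolic_assumptions()].
#' @param grouping `"venous_scales_difference"` (default): the venous ratio
#'   and molecular weight divide the whole extraction term;
#'   `"venous_scales_sto2"`: only StO2 is referred to the venous
#'   compartment, `MRO2 = HGB * BFi * (SpO2 - StO2/venous_ratio) / mw_Hb`.
#' @return Numeric MRO2 (mol Hb cm^2 dL^-1 s^-1) with a `units` attribute.
#' @export
#' @examples
#' mro2(5e-8, 70, metabolic_assumptions("male"))
mro2 <- function(bfi_cm2s, sto2_pct, assume = metabolic_assumptions(),
                 grouping = c("venous_scales_difference", "venous_scales_sto2")) {
  grouping <- match.arg(grouping)
  if (any(sto2_pct <= 1 & sto2_pct != 0, na.rm = TRUE))
    abort("`sto2_pct` looks like a fraction; pass percent (0-100 scale)")
  sto2_frac <- sto2_pct / 100
  num <- switch(grouping,
    venous_scales_difference =
      assume$hgb_g_dl * bfi_cm2s * (assume$spo2 - sto2_frac) /
        (assume$venous_ratio * assume$mw_hb_g_mol),
    venous_scales_sto2 =
      assume$hgb_g_dl * bfi_cm2s * (assume$spo2 - sto2_frac / assume$venous_ratio) /
        assume$mw_hb_g_mol)
  structure(num, units = "mol_Hb * cm^2 / (dL * s)")
}
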