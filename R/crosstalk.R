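#' Percent change from baseline along a titration
#'
#' `100 * (value_k - value_0) / value_0` per titration step, step 0 being
#' the baseline.
#'
#' @param values Per-step values, baseline first.
#' @return Percent changes, one per step (first is 0).
#' @export
#' @examples
#' percent_change_from_baseline(c(2, 3, 4)) # 0, 50, 100
percent_change_from_baseline <- function(values) {
  if (length(values) < 1 || !is.finite(values[1]) || values[1] == 0)
    abort("baseline value must be nonzero")
  100 * (values - values[1]) / values[1]
}

#' Crosstalk between a desired and an undesired parameter, in decibels
#'
#' The ratio of the baseline-normalized change of the undesired parameter
#' to that of the desired (titrated) parameter, expressed in decibels:
#' `10 * log10(|undesired| / |desired|)` by default.  Negative values mean
#' the undesired channel moved less than the titrated one (attenuated
#' crosstalk); 0 dB means equal change, so a parameter's crosstalk with
#' itself is 0 dB.  A zero undesired change returns `-Inf` as a sentinel.
#' The amplitude-style `20 * log10` convention is available via
#' `convention`.
#'
#' @param desired_change_pct Percent change of the titrated parameter
#'   (nonzero).
#' @param undesired_change_pct Percent change of the other parameter.
#' @param convention `"power"` (10 log10, default) or `"amplitude"`
#'   (20 log10).
#' @return Crosstalk in dB (vectorized).
#' @export
#' @examples
#' crosstalk_db(286, 19) # ~ -11.8 dB
crosstalk_db <- function(desired_change_pct, undesired_change_pct,
                         convention = c("power", "amplitude")) {
  convention <- match.arg(convention)
  if (any(desired_change_pct == 0))
    abort("zero desired change: crosstalk undefined")
  fac <- if (convention == "power") 10 else 20
  fac * log10(abs(undesired_change_pct) / abs(desired_change_pct))
}

#' Mean percent change across the two wavelengths
#'
#' Signed arithmetic mean of the 730 and 830 nm percent changes, the
#' per-titration summary quoted for the absorption and scattering
#' channels.
#'
#' @param change_730_pct,change_830_pct Percent changes per wavelength.
#' @return Mean percent change.
#' @export
#' @examples
#' titration_summary(544, 286) # 415
titration_summary <- function(change_730_pct, change_830_pct) {
  (change_730_pct + change_830_pct) / 2
}

#' Ordinary least-squares line through titration steps
#'
#' Best linear fit of recovered values against step index (or stirrer
#' speed), with slope, intercept and R-squared, used to verify that each
#' titrated parameter responds linearly.
#'
#' @param x Step index or stirrer speed (>= 3 points).
#' @param values Recovered parameter values.
#' @return A `titration_fit` object wrapping the `lm` fit.
#' @export
linear_fit <- function(x, values) {
  if (length(x) < 3) abort("need at least 3 points for a trend fit")
  fit <- lm(values ~ x, data = data.frame(x = x, values = values))
  # noise-free titrations fit exactly; summary.lm's perfect-fit warning
  # is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(fit = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> slope %.4g, intercept %.4g, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
tidy.titration_fit <- function(x, ...) tidy(x$fit, ...)

#' @export
glance.titration_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared)
}

# canonical long layout for a titration series of recovered parameters
titration_parameters <- c("mua_730", "mua_830", "musp_730", "musp_830", "bfi")

#' Published per-wavelength titration changes
#'
#' The packaged table of per-wavelength percent changes reported for the
#' three instrument-validation titrations (final change from baseline per
#' parameter), used to recompute the summary means and the crosstalk
#' bound.
#'
#' @return Tibble: `titration`, `parameter` ("mua", "musp", "bfi"),
#'   `wavelength_nm` (NA for bfi), `change_pct`.
#' @export
published_titration_changes <- function() {
  path <- system.file("extdata", "titration_published_changes.csv",
                      package = "nirsdcs")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Crosstalk pairs from a table of final percent changes
#'
#' Computes crosstalk in dB for every (desired, undesired) channel pair of
#' each titration from final-step percent changes alone (the layout of
#' [published_titration_changes()]).  Spectral desired channels are paired
#' per wavelength; the worst (least attenuated) pair bounds the system.
#' Zero undesired changes give the `-Inf` sentinel.
#'
#' @param changes Tibble: `titration`, `parameter`, `wavelength_nm`,
#'   `change_pct`.
#' @param convention See [crosstalk_db()].
#' @return Tibble of pairs with `crosstalk_db`, plus attribute none;
#'   rows ordered by decreasing crosstalk.
#' @export
crosstalk_from_changes <- function(changes,
                                   convention = c("power", "amplitude")) {
  convention <- match.arg(convention)
  desired_param <- c(absorption = "mua", scattering = "musp", flow = "bfi")
  out <- purrr::map_dfr(unique(changes$titration), function(tt) {
    ch <- filter(changes, .data$titration == tt)
    dp <- desired_param[[tt]]
    des <- filter(ch, .data$parameter == dp)
    und <- filter(ch, .data$parameter != dp)
    purrr::map_dfr(seq_len(nrow(und)), function(i) {
      purrr::map_dfr(seq_len(nrow(des)), function(j) {
        u <- und$change_pct[i]; d <- des$change_pct[j]
        tibble(titration = tt,
               desired = dp, desired_wavelength_nm = des$wavelength_nm[j],
               undesired = und$parameter[i],
               undesired_wavelength_nm = und$wavelength_nm[i],
               desired_change_pct = d, undesired_change_pct = u,
               crosstalk_db = if (u == 0) -Inf
                              else crosstalk_db(d, u, convention))
      })
    })
  })
  arrange(out, dplyr::desc(.data$crosstalk_db))
}

#' Algorithmic crosstalk floor against the known truth
#'
#' Separates algorithm-induced crosstalk from real co-variation in the
#' phantom: for each undesired parameter the metric is the *excess*
#' recovered change (recovered minus true percent change at the final
#' step) referred to the desired parameter's change, in dB.  In a
#' physically coupled titration (e.g. Intralipid displacing water and
#' slightly lowering absorption) the raw recovered-value crosstalk
#' contains that genuine coupling; the excess isolates what the
#' inversion chain itself adds.
#'
#' @param recovered Per-step recovered parameters ([recover_titration()]
#'   layout: `titration`, `step`, parameter columns).
#' @param truth Matching per-step truth ([titration_truth()] layout with
#'   a `titration` column, or the same layout as `recovered`).
#' @param convention See [crosstalk_db()].
#' @return Tibble of (desired, undesired) pairs with
#'   `excess_change_pct` and `crosstalk_db` (`-Inf` when the excess is
#'   exactly zero).
#' @export
crosstalk_floor <- function(recovered, truth,
                            convention = c("power", "amplitude")) {
  convention <- match.arg(convention)
  desired_map <- list(absorption = c("mua_730", "mua_830"),
                      scattering = c("musp_730", "musp_830"),
                      flow = "bfi")
  purrr::map_dfr(unique(recovered$titration), function(tt) {
    r <- arrange(filter(recovered, .data$titration == tt), .data$step)
    tr <- arrange(filter(truth, .data$titration == tt), .data$step)
    if (nrow(r) != nrow(tr)) abort("recovered/truth step mismatch")
    des <- desired_map[[tt]]
    und <- setdiff(titration_parameters, des)
    purrr::map_dfr(und, function(u) {
      purrr::map_dfr(des, function(dd) {
        dch <- dplyr::last(percent_change_from_baseline(r[[dd]]))
        excess <- dplyr::last(percent_change_from_baseline(r[[u]])) -
          dplyr::last(percent_change_from_baseline(tr[[u]]))
        tibble(titration = tt, desired = dd, undesired = u,
               desired_change_pct = dch, excess_change_pct = excess,
               crosstalk_db = if (excess == 0) -Inf
                              else crosstalk_db(dch, excess, convention))
      })
    })
  })
}

#' Crosstalk report for a set of titrations
#'
#' Takes per-step recovered parameters for one or more titrations and
#' produces, per (titration, undesired parameter) pair: the percent change
#' of each channel at the final step, the crosstalk in dB against the
#' titrated channel (per wavelength where the titrated quantity is
#' spectral, e.g. BFi change is referred to each of mua_730/mua_830 in an
#' absorption titration and the worst pair is what bounds the system), the
#' linear-trend slope ratio alternative, and trend goodness of fit.
#'
#' @param data Tibble with columns `titration` (one of "absorption",
#'   "scattering", "flow"), `step` (0-based, 0 = baseline), and recovered
#'   parameter columns `mua_730`, `mua_830`, `musp_730`, `musp_830`,
#'   `bfi`.  An optional `rpm` column is used as the trend abscissa for
#'   the flow titration.
#' @param convention dB convention, see [crosstalk_db()].
#' @return A `crosstalk_report`: list with `pairs` (tibble of desired /
#'   undesired percent changes and crosstalk dB, endpoint and slope-ratio
#'   definitions), `changes` (per-parameter percent change and trend fit
#'   per titration), and `worst` (the least attenuated pair).
#' @export
validate_crosstalk <- function(data, convention = c("power", "amplitude")) {
  convention <- match.arg(convention)
  need <- c("titration", "step", titration_parameters)
  if (!all(need %in% names(data)))
    abort(paste("missing columns:",
                paste(setdiff(need, names(data)), collapse = ", ")))
  desired_map <- list(absorption = c("mua_730", "mua_830"),
                      scattering = c("musp_730", "musp_830"),
                      flow = "bfi")
  changes <- purrr::map_dfr(split(data, data$titration), function(d) {
    if (nrow(d) < 3) abort("titration needs at least 3 steps")
    d <- arrange(d, .data$step)
    xx <- if ("rpm" %in% names(d) && d$titration[1] == "flow" &&
              !anyNA(d$rpm)) d$rpm else d$step
    purrr::map_dfr(titration_parameters, function(p) {
      pc <- percent_change_from_baseline(d[[p]])
      fit <- linear_fit(xx, d[[p]])
      tibble(titration = d$titration[1], parameter = p,
             final_change_pct = pc[length(pc)],
             slope = fit$slope, r_squared = fit$r_squared)
    })
  })
  pairs <- purrr::map_dfr(unique(changes$titration), function(tt) {
    ch <- filter(changes, .data$titration == tt)
    des <- desired_map[[tt]]
    und <- setdiff(titration_parameters, des)
    purrr::map_dfr(und, function(u) {
      purrr::map_dfr(des, function(dd) {
        dch <- ch$final_change_pct[ch$parameter == dd]
        uch <- ch$final_change_pct[ch$parameter == u]
        dsl <- ch$slope[ch$parameter == dd]
        usl <- ch$slope[ch$parameter == u]
        tibble(titration = tt, desired = dd, undesired = u,
               desired_change_pct = dch, undesired_change_pct = uch,
               crosstalk_db = if (uch == 0) -Inf
                              else crosstalk_db(dch, uch, convention),
               crosstalk_slope_db = if (usl == 0) -Inf
                                    else 10 * log10(abs(usl) / abs(dsl)) *
                                      (if (convention == "power") 1 else 2))
      })
    })
  })
  worst <- pairs[which.max(pairs$crosstalk_db), ]
  structure(list(pairs = pairs, changes = changes, worst = worst,
                 convention = convention),
            class = "crosstalk_report")
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat("<crosstalk_report>\n")
  cat(sprintf("  convention: %s (%s log10)\n", x$convention,
              if (x$convention == "power") "10" else "20"))
  cat(sprintf("  worst pair: %s -> %s in %s titration, %.1f dB\n",
              x$worst$desired, x$worst$undesired, x$worst$titration,
              x$worst$crosstalk_db))
  print(x$pairs, n = 20)
  invisible(x)
}

#' @export
tidy.crosstalk_report <- function(x, ...) x$pairs

#' @export
glance.crosstalk_report <- function(x, ...) {
  tibble(worst_crosstalk_db = x$worst$crosstalk_db,
         worst_pair = paste0(x$worst$desired, "->", x$worst$undesired),
         worst_titration = x$worst$titration,
         n_pairs = nrow(x$pairs),
         convention = x$convention)
}
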