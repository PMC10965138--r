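#' Build a frequency-domain lookup table
#'
#' Tabulates the forward amplitude/phase response over a (mua, musp) grid
#' for both wavelength channels (730 nm at its modulation frequency and
#' 830 nm at its own), from either the diffusion-theory engine or the
#' Monte Carlo engine.  The default grid brackets muscle and phantom
#' ranges with margin: mua log-spaced on \[0.002, 0.05\] 1/mm, musp linear
#' on \[0.3, 2.5\] 1/mm, 60 x 60 nodes.  An invertibility check (sign
#' consistency of the Jacobian of (log amplitude, phase) with respect to
#' (mua, musp) across the grid) is performed and reported in the metadata.
#'
#' @param mua_grid,musp_grid Strictly increasing node vectors, 1/mm.
#' @param engine `"diffusion"` or `"monte_carlo"`.
#' @param medium A [medium_assumptions()].
#' @param geom A [probe_geometry()].
#' @param wavelengths_nm Channels to tabulate (default both).
#' @param n_photons,seed Monte Carlo settings (per node) when
#'   `engine = "monte_carlo"`.
#' @return An `fd_lut` object: per-channel amplitude and phase surfaces
#'   (matrices indexed \[mua, musp\]), the grids, and metadata sufficient
#'   to rebuild the table bit-identically (engine, geometry, medium,
#'   seed).
#' @export
build_fd_lut <- function(mua_grid = exp(seq(log(0.002), log(0.05),
                                            length.out = 60)),
                         musp_grid = seq(0.3, 2.5, length.out = 60),
                         engine = c("diffusion", "monte_carlo"),
                         medium = medium_assumptions(),
                         geom = probe_geometry(),
                         wavelengths_nm = c(730, 830),
                         n_photons = 2e5, seed = 1) {
  engine <- match.arg(engine)
  if (any(diff(mua_grid) <= 0) || any(diff(musp_grid) <= 0))
    abort("grids must be strictly increasing")
  if (length(mua_grid) < 2 || length(musp_grid) < 2)
    abort("grids need at least 2 nodes each")
  channels <- list()
  for (wl in wavelengths_nm) {
    f_mod <- modulation_frequency(geom, wl)
    amp <- phase <- matrix(NA_real_, length(mua_grid), length(musp_grid))
    if (engine == "diffusion") {
      omega <- 2 * pi * f_mod * 1e6
      for (j in seq_along(musp_grid)) {
        rc <- diffusion_reflectance_complex(
          mua_grid, musp_grid[j], geom$source_detector_separation_mm,
          omega, medium)
        amp[, j] <- Mod(rc)
        phase[, j] <- -Arg(rc)
      }
    } else {
      for (j in seq_along(musp_grid)) for (i in seq_along(mua_grid)) {
        node_seed <- seed + 7919 * (match(wl, wavelengths_nm) - 1) +
          104729 * (j - 1) + i
        mc <- tryCatch(
          mc_time_resolved(optical_properties(wl, mua_grid[i], musp_grid[j]),
                           medium, geom, f_mod,
                           n_photons = n_photons, seed = node_seed),
          error = function(e)
            abort(sprintf("engine failure at node (mua=%.4g, musp=%.4g): %s",
                          mua_grid[i], musp_grid[j], conditionMessage(e))))
        amp[i, j] <- mc$amplitude
        phase[i, j] <- mc$phase
      }
    }
    if (!all(is.finite(amp)) || !all(is.finite(phase)))
      abort("non-finite response surface; engine failed")
    channels[[paste0("nm", wl)]] <-
      list(wavelength_nm = wl, f_mod_mhz = f_mod,
           amplitude = amp, phase = phase)
  }
  jac <- lut_jacobian_check(channels, mua_grid, musp_grid)
  structure(
    list(mua_grid = mua_grid, musp_grid = musp_grid, channels = channels,
         engine = engine, medium = medium, geom = geom,
         meta = list(n_photons = if (engine == "monte_carlo") n_photons else NA,
                     seed = if (engine == "monte_carlo") seed else NA,
                     jacobian_consistent_fraction = jac,
                     built = "nirsdcs::build_fd_lut")),
    class = "fd_lut")
}

# sign consistency of det d(logA, phase)/d(mua, musp) across the grid
lut_jacobian_check <- function(channels, mua_grid, musp_grid) {
  fr <- vapply(channels, function(ch) {
    la <- log(ch$amplitude)
    ph <- ch$phase
    dla_dmua <- apply(la, 2, diff) / diff(mua_grid)
    dph_dmua <- apply(ph, 2, diff) / diff(mua_grid)
    dla_dmusp <- t(apply(la, 1, diff)) / rep(diff(musp_grid),
                                             each = nrow(la))
    dph_dmusp <- t(apply(ph, 1, diff)) / rep(diff(musp_grid),
                                             each = nrow(ph))
    nI <- length(mua_grid) - 1
    nJ <- length(musp_grid) - 1
    dets <- dla_dmua[, 1:nJ] * dph_dmusp[1:nI, ] -
      dph_dmua[, 1:nJ] * dla_dmusp[1:nI, ]
    s <- sign(dets)
    max(mean(s > 0), mean(s < 0))
  }, numeric(1))
  min(fr)
}

#' @export
print.fd_lut <- function(x, ...) {
  cat(sprintf("<fd_lut> %s engine, %d x %d grid, channels: %s\n",
              x$engine, length(x$mua_grid), length(x$musp_grid),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  mua [%.4g, %.4g] 1/mm, musp [%.3g, %.3g] 1/mm\n",
              min(x$mua_grid), max(x$mua_grid),
              min(x$musp_grid), max(x$musp_grid)))
  cat(sprintf("  Jacobian sign consistency: %.3f\n",
              x$meta$jacobian_consistent_fraction))
  invisible(x)
}

#' @export
glance.fd_lut <- function(x, ...) {
  tibble(engine = x$engine,
         n_mua = length(x$mua_grid), n_musp = length(x$musp_grid),
         mua_min = min(x$mua_grid), mua_max = max(x$mua_grid),
         musp_min = min(x$musp_grid), musp_max = max(x$musp_grid),
         jacobian_consistent_fraction = x$meta$jacobian_consistent_fraction)
}

# bilinear interpolation of a channel surface at (mua, musp), vectorized;
# returns value and the cell-local gradient
lut_bilinear <- function(grid1, grid2, surf, q1, q2) {
  i <- pmin.int(pmax.int(findInterval(q1, grid1), 1L), length(grid1) - 1L)
  j <- pmin.int(pmax.int(findInterval(q2, grid2), 1L), length(grid2) - 1L)
  x1 <- grid1[i]; x2 <- grid1[i + 1L]
  y1 <- grid2[j]; y2 <- grid2[j + 1L]
  tx <- (q1 - x1) / (x2 - x1)
  ty <- (q2 - y1) / (y2 - y1)
  f11 <- surf[cbind(i, j)]; f21 <- surf[cbind(i + 1L, j)]
  f12 <- surf[cbind(i, j + 1L)]; f22 <- surf[cbind(i + 1L, j + 1L)]
  val <- (1 - tx) * (1 - ty) * f11 + tx * (1 - ty) * f21 +
    (1 - tx) * ty * f12 + tx * ty * f22
  d1 <- ((1 - ty) * (f21 - f11) + ty * (f22 - f12)) / (x2 - x1)
  d2 <- ((1 - tx) * (f12 - f11) + tx * (f22 - f21)) / (y2 - y1)
  list(value = val, d_mua = d1, d_musp = d2)
}

# vectorized Newton on the (log amplitude, phase) residual against either
# the bilinear LUT surfaces or the continuous diffusion engine
invert_channel <- function(lut, channel, amplitude, phase,
                           refine_engine = TRUE, max_iter = 30,
                           tol = 1e-10) {
  ch <- lut$channels[[channel]]
  n <- length(amplitude)
  la_target <- log(amplitude)
  ph_target <- phase
  la_surf <- log(ch$amplitude)
  ph_surf <- ch$phase
  g1 <- lut$mua_grid; g2 <- lut$musp_grid
  # nearest node on a coarse subsample as initialization (full grid when
  # the table is small)
  s1 <- max(1L, floor(length(g1) / 16))
  s2 <- max(1L, floor(length(g2) / 16))
  ii <- unique(c(seq(1, length(g1), by = s1), length(g1)))
  jj <- unique(c(seq(1, length(g2), by = s2), length(g2)))
  sub_la <- la_surf[ii, jj, drop = FALSE]
  sub_ph <- ph_surf[ii, jj, drop = FALSE]
  sc_la <- stats::sd(sub_la); sc_ph <- stats::sd(sub_ph)
  best_i <- integer(n); best_j <- integer(n)
  flat_la <- as.vector(sub_la); flat_ph <- as.vector(sub_ph)
  for (k in seq_len(n)) {
    d <- ((flat_la - la_target[k]) / sc_la)^2 +
      ((flat_ph - ph_target[k]) / sc_ph)^2
    w <- which.min(d)
    best_i[k] <- ii[(w - 1L) %% length(ii) + 1L]
    best_j[k] <- jj[(w - 1L) %/% length(ii) + 1L]
  }
  mua <- g1[best_i]; musp <- g2[best_j]
  lo1 <- min(g1); hi1 <- max(g1); lo2 <- min(g2); hi2 <- max(g2)
  # Newton on the bilinear surfaces
  for (it in seq_len(max_iter)) {
    bla <- lut_bilinear(g1, g2, la_surf, mua, musp)
    bph <- lut_bilinear(g1, g2, ph_surf, mua, musp)
    r1 <- bla$value - la_target
    r2 <- bph$value - ph_target
    detj <- bla$d_mua * bph$d_musp - bla$d_musp * bph$d_mua
    detj[abs(detj) < 1e-300] <- 1e-300
    dmua <- (r1 * bph$d_musp - r2 * bla$d_musp) / detj
    dmusp <- (r2 * bla$d_mua - r1 * bph$d_mua) / detj
    step_cap <- 0.25
    dmua <- pmin(pmax(dmua, -step_cap * mua), step_cap * mua)
    dmusp <- pmin(pmax(dmusp, -step_cap * musp), step_cap * musp)
    mua <- pmin(pmax(mua - dmua, lo1), hi1)
    musp <- pmin(pmax(musp - dmusp, lo2), hi2)
    if (max(abs(r1)) < tol && max(abs(r2)) < tol) break
  }
  clamped <- mua <= lo1 | mua >= hi1 | musp <= lo2 | musp >= hi2
  # polish on the continuous engine when available
  if (refine_engine && lut$engine == "diffusion") {
    omega <- 2 * pi * ch$f_mod_mhz * 1e6
    rho <- lut$geom$source_detector_separation_mm
    fwd <- function(m, s) {
      rc <- diffusion_reflectance_complex(m, s, rho, omega, lut$medium)
      list(la = log(Mod(rc)), ph = -Arg(rc))
    }
    for (it in 1:12) {
      f0 <- fwd(mua, musp)
      r1 <- f0$la - la_target; r2 <- f0$ph - ph_target
      if (max(abs(r1), abs(r2)) < 1e-12) break
      h1 <- mua * 1e-6; h2 <- musp * 1e-6
      fa <- fwd(mua + h1, musp)
      fb <- fwd(mua, musp + h2)
      j11 <- (fa$la - f0$la) / h1; j21 <- (fa$ph - f0$ph) / h1
      j12 <- (fb$la - f0$la) / h2; j22 <- (fb$ph - f0$ph) / h2
      detj <- j11 * j22 - j12 * j21
      detj[abs(detj) < 1e-300] <- 1e-300
      dmua <- (r1 * j22 - r2 * j12) / detj
      dmusp <- (r2 * j11 - r1 * j21) / detj
      dmua <- pmin(pmax(dmua, -0.5 * mua), 0.5 * mua)
      dmusp <- pmin(pmax(dmusp, -0.5 * musp), 0.5 * musp)
      mua <- mua - dmua
      musp <- musp - dmusp
    }
    # engine polish may step slightly outside the table; keep positivity
    mua <- pmax(mua, 1e-6)
    musp <- pmax(musp, 1e-6)
  }
  list(mua = mua, musp = musp, clamped = clamped)
}

#' Invert calibrated FD measurements to optical properties
#'
#' Interpolated inverse lookup of (amplitude, phase) to (mua, musp) per
#' wavelength channel: nearest-node initialization, Newton iteration on
#' the bilinearly interpolated response surfaces, and (for tables whose
#' forward engine has a continuous evaluation, i.e. diffusion) a final
#' Newton polish against the engine itself.  Queries outside the table are
#' clamped to its boundary and flagged; with `strict = TRUE` they raise an
#' error instead.
#'
#' @param data Tibble of calibrated measurements with columns
#'   `wavelength_nm`, `amplitude`, `phase` (and any others, carried
#'   through, e.g. `time_s`).
#' @param lut An [build_fd_lut()] table.
#' @param refine_engine Polish against the continuous engine (default
#'   TRUE; ignored for Monte Carlo tables).
#' @param strict Raise on out-of-range queries instead of clamp+flag.
#' @return Input tibble with `mua`, `musp`, `lut_clamped` columns.
#' @export
invert_fd <- function(data, lut, refine_engine = TRUE, strict = FALSE) {
  need <- c("wavelength_nm", "amplitude", "phase")
  if (!all(need %in% names(data))) abort("missing measurement columns")
  if (any(data$amplitude <= 0)) abort("non-positive amplitude")
  out <- as_tibble(data)
  out$mua <- out$musp <- NA_real_
  out$lut_clamped <- FALSE
  for (wl in unique(out$wavelength_nm)) {
    chn <- paste0("nm", wl)
    if (!chn %in% names(lut$channels))
      abort(sprintf("no LUT channel for %g nm", wl))
    sel <- out$wavelength_nm == wl
    res <- invert_channel(lut, chn, out$amplitude[sel], out$phase[sel],
                          refine_engine = refine_engine)
    if (strict && any(res$clamped))
      abort("query outside LUT range (strict mode)", class = "nirsdcs_range")
    out$mua[sel] <- res$mua
    out$musp[sel] <- res$musp
    out$lut_clamped[sel] <- res$clamped
  }
  if (any(out$lut_clamped))
    warn(sprintf("%d measurement(s) clamped to the LUT boundary",
                 sum(out$lut_clamped)))
  out
}

#' Calibrate against a reference phantom
#'
#' Determines the per-wavelength instrument response (amplitude gain and
#' phase offset) by comparing a raw measurement of a phantom of known
#' optical properties with the forward model's prediction, so that
#' applying the returned factors to that measurement reproduces the model
#' exactly.
#'
#' @param raw Tibble of raw phantom measurements: columns `wavelength_nm`,
#'   `amplitude`, `phase` (replicates are averaged per wavelength:
#'   amplitude geometrically, phase arithmetically).
#' @param phantom_truth Tibble with columns `wavelength_nm`, `mua`,
#'   `musp`: the phantom's known properties per wavelength.
#' @param medium,geom Model assumptions used for the prediction.
#' @return A `calibration_factors` tibble: `wavelength_nm`, `gain`,
#'   `phase_offset_rad`, plus the phantom truth used, carried as an
#'   attribute.
#' @export
calibrate <- function(raw, phantom_truth, medium = medium_assumptions(),
                      geom = probe_geometry()) {
  if (any(raw$amplitude <= 0)) abort("non-positive raw amplitude")
  cal <- purrr::map_dfr(unique(raw$wavelength_nm), function(wl) {
    rsel <- raw[raw$wavelength_nm == wl, ]
    tsel <- phantom_truth[phantom_truth$wavelength_nm == wl, ]
    if (nrow(tsel) != 1)
      abort(sprintf("phantom truth must have one row for %g nm", wl))
    pred <- fd_reflectance(optical_properties(wl, tsel$mua, tsel$musp),
                           medium, geom, modulation_frequency(geom, wl))
    tibble(wavelength_nm = wl,
           gain = exp(mean(log(rsel$amplitude))) / pred$amplitude,
           phase_offset_rad = mean(rsel$phase) - pred$phase)
  })
  if (any(cal$gain <= 0)) abort("calibration produced non-positive gain")
  attr(cal, "phantom_truth") <- phantom_truth
  class(cal) <- c("calibration_factors", class(cal))
  cal
}

#' Apply calibration factors to a raw stream
#'
#' Divides amplitudes by the per-wavelength gain and subtracts the phase
#' offset, removing the instrument response so measurements live on the
#' forward model's scale.  Calibrating with an identity record
#' (gain 1, offset 0) returns the stream unchanged.
#'
#' @param data Raw tibble: `wavelength_nm`, `amplitude`, `phase`, ...
#' @param cal A [calibrate()] result.
#' @return Calibrated tibble, same shape.
#' @export
apply_calibration <- function(data, cal) {
  out <- as_tibble(data)
  idx <- match(out$wavelength_nm, cal$wavelength_nm)
  if (anyNA(idx)) abort("calibration missing for some wavelength")
  out$amplitude <- out$amplitude / cal$gain[idx]
  out$phase <- out$phase - cal$phase_offset_rad[idx]
  out
}

#' Direct least-squares inversion of a calibrated FD measurement
#'
#' Independent nonlinear least-squares oracle for the LUT inversion path:
#' minimizes the (log amplitude, phase) residual against the diffusion
#' forward model over (log mua, log musp) with `stats::optim` (BFGS).
#'
#' @param amplitude,phase Calibrated measurement.
#' @param wavelength_nm Channel wavelength.
#' @param medium,geom Model assumptions.
#' @param init Initial `(mua, musp)` guess, 1/mm.
#' @return List: `mua`, `musp`, `converged`, `objective`, `counts`.
#' @export
fit_direct_fd <- function(amplitude, phase, wavelength_nm,
                          medium = medium_assumptions(),
                          geom = probe_geometry(),
                          init = c(mua = 0.01, musp = 1.0)) {
  omega <- 2 * pi * modulation_frequency(geom, wavelength_nm) * 1e6
  rho <- geom$source_detector_separation_mm
  obj <- function(p) {
    rc <- diffusion_reflectance_complex(exp(p[1]), exp(p[2]), rho, omega,
                                        medium)
    (log(Mod(rc)) - log(amplitude))^2 + (-Arg(rc) - phase)^2
  }
  # coarse scan of its own (independent of any lookup table) so the
  # gradient descent starts in the right basin, then Newton-quality BFGS
  # with a simplex polish if it stalls
  cand <- expand.grid(lm = log(seq(0.003, 0.045, length.out = 9)),
                      ls = log(seq(0.35, 2.4, length.out = 9)))
  cand_val <- vapply(seq_len(nrow(cand)),
                     function(i) obj(c(cand$lm[i], cand$ls[i])), numeric(1))
  best <- which.min(c(min(cand_val), obj(log(init))))
  start <- if (best == 1) {
    k <- which.min(cand_val)
    c(cand$lm[k], cand$ls[k])
  } else log(init)
  fit <- optim(start, obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  if (fit$value > 1e-16) {
    fit2 <- optim(fit$par, obj, control = list(reltol = 1e-15, maxit = 2000))
    if (fit2$value < fit$value) fit <- fit2
  }
  if (fit$convergence != 0)
    warn(sprintf("fit_direct_fd did not fully converge (code %d, value %.3g)",
                 fit$convergence, fit$value))
  list(mua = unname(exp(fit$par[1])), musp = unname(exp(fit$par[2])),
       converged = fit$convergence == 0, objective = fit$value,
       counts = fit$counts)
}

# model g2 on a tau grid for given properties / flow (internal)
model_g2 <- function(tau_s, props, geom, medium, bfi_cm2s, beta) {
  fl <- flow_model(bfi_cm2s, beta = max(min(beta, 1), 1e-6),
                   dcs_wavelength_nm = geom$dcs_wavelength_nm,
                   refractive_index = medium$refractive_index)
  1 + beta * g1_semi_infinite(props, fl, geom, tau_s, medium)^2
}

#' Invert a correlation curve for the blood flow index
#'
#' Estimates the coherence factor from the small-lag plateau (mean of
#' `g2 - 1` over the first 5 lag bins), then fits the Brownian
#' correlation-diffusion model conditioned on the supplied optical
#' properties for the blood flow index by a grid lookup over the default
#' BFi range (80 log-spaced nodes on \[1e-9, 1e-5\] cm^2/s) refined with
#' a 1-D optimizer.  Because the finite first lag makes the raw plateau
#' estimate droop slightly, the plateau is re-estimated against the
#' fitted decay and the pair is iterated to convergence.
#'
#' @param curve A [correlation_curve()] (or tibble with `tau_s`, `g2`).
#' @param props [optical_properties()] at the flow wavelength.
#' @param geom,medium Geometry and medium assumptions.
#' @param bfi_grid Lookup/bracket grid, cm^2/s.
#' @param beta Optional known coherence factor (skips estimation).
#' @param bfi_init Optional warm start (e.g. the previous timepoint's
#'   fit); replaces the initial grid scan with a local bracket.
#' @return A `dcs_fit` list: `bfi_cm2s`, `beta`, `residual_rms`,
#'   `tau_span_ok`, `n_iter`.
#' @export
invert_dcs <- function(curve, props, geom = probe_geometry(),
                       medium = medium_assumptions(),
                       bfi_grid = exp(seq(log(1e-9), log(1e-5),
                                          length.out = 80)),
                       beta = NULL, bfi_init = NULL) {
  tau <- curve$tau_s
  g2 <- curve$g2
  if (length(tau) < 8) abort("curve too short")
  intercept <- mean(g2[1:5] - 1)
  tail_level <- mean(g2[pmax(1, length(g2) - 2):length(g2)] - 1)
  if (intercept <= 0 || (intercept - tail_level) < 0.01 * abs(intercept))
    abort("flat correlation curve: no decay to fit",
          class = "nirsdcs_degenerate")
  tau_span_ok <- tail_level < 0.01 * intercept
  beta_known <- !is.null(beta)
  fit_bfi_given_beta <- function(beta_est, bfi_prev = NA_real_) {
    if (!is.finite(bfi_prev) && !is.null(bfi_init)) bfi_prev <- bfi_init
    grid_bracket <- function() {
      sse_grid <- vapply(bfi_grid, function(b)
        sum((model_g2(tau, props, geom, medium, b, beta_est) - g2)^2),
        numeric(1))
      k <- which.min(sse_grid)
      c(bfi_grid[max(1, k - 1)], bfi_grid[min(length(bfi_grid), k + 1)])
    }
    br <- if (is.finite(bfi_prev)) c(bfi_prev / 3, bfi_prev * 3)
          else grid_bracket()
    solve_in <- function(br) {
      op <- optimize(function(lb)
        sum((model_g2(tau, props, geom, medium, exp(lb), beta_est) - g2)^2),
        lower = log(br[1]), upper = log(br[2]), tol = 1e-12)
      exp(op$minimum)
    }
    out <- solve_in(br)
    # a warm-start bracket that pinned the solution at its edge was wrong
    if (is.finite(bfi_prev) &&
        (out / br[1] < 1.02 || br[2] / out < 1.02))
      out <- solve_in(grid_bracket())
    out
  }
  descend <- function(beta_start) {
    beta_est <- beta_start
    bfi <- NA_real_
    n_rounds <- 1L
    for (r in 1:12) {
      n_rounds <- r
      bfi_new <- fit_bfi_given_beta(beta_est, bfi)
      # conditional least-squares coherence factor given the fitted decay
      fl <- flow_model(bfi_new, beta = 0.5,
                       dcs_wavelength_nm = geom$dcs_wavelength_nm,
                       refractive_index = medium$refractive_index)
      g1f <- g1_semi_infinite(props, fl, geom, tau, medium)
      beta_new <- sum((g2 - 1) * g1f^2) / sum(g1f^4)
      if (beta_new <= 0 || beta_new > 1.5) return(NULL)
      converged <- is.finite(bfi) &&
        abs(bfi_new / bfi - 1) < 1e-9 && abs(beta_new / beta_est - 1) < 1e-9
      beta_est <- beta_new
      bfi <- bfi_new
      if (converged) break
    }
    sse <- sum((model_g2(tau, props, geom, medium, bfi, beta_est) - g2)^2)
    list(bfi = bfi, beta = beta_est, sse = sse, n_rounds = n_rounds)
  }
  if (beta_known) {
    beta_est <- beta
    bfi <- fit_bfi_given_beta(beta_est)
    round <- 1L
  } else {
    # plateau initialization, with fallback starts for curves whose first
    # lags are already off the plateau (fast decays)
    starts <- unique(c(min(intercept, 1), 0.5))
    cands <- purrr::compact(purrr::map(starts, descend))
    if (length(cands) == 0)
      abort("implausible coherence factor estimate")
    best <- cands[[which.min(purrr::map_dbl(cands, "sse"))]]
    bfi <- best$bfi
    beta_est <- best$beta
    round <- best$n_rounds
  }
  resid <- model_g2(tau, props, geom, medium, bfi, beta_est) - g2
  structure(list(bfi_cm2s = bfi, beta = min(beta_est, 1),
                 residual_rms = sqrt(mean(resid^2)),
                 tau_span_ok = tau_span_ok, n_iter = round),
            class = "dcs_fit")
}

#' @export
print.dcs_fit <- function(x, ...) {
  cat(sprintf("<dcs_fit> BFi %.3g cm^2/s, beta %.3f, residual RMS %.2g\n",
              x$bfi_cm2s, x$beta, x$residual_rms))
  invisible(x)
}

#' @export
tidy.dcs_fit <- function(x, ...) {
  tibble(term = c("bfi_cm2s", "beta"),
         estimate = c(x$bfi_cm2s, x$beta))
}

#' @export
glance.dcs_fit <- function(x, ...) {
  tibble(bfi_cm2s = x$bfi_cm2s, beta = x$beta,
         residual_rms = x$residual_rms, tau_span_ok = x$tau_span_ok,
         n_iter = x$n_iter)
}

#' Direct joint least-squares fit of a correlation curve
#'
#' Independent oracle for [invert_dcs()]: fits coherence factor and BFi
#' jointly by Nelder-Mead on `(logit-free beta, log bfi)`.
#'
#' @inheritParams invert_dcs
#' @param init Initial `(beta, bfi_cm2s)`.
#' @return List: `bfi_cm2s`, `beta`, `converged`, `objective`.
#' @export
fit_direct_dcs <- function(curve, props, geom = probe_geometry(),
                           medium = medium_assumptions(),
                           init = c(beta = 0.4, bfi_cm2s = 1e-7)) {
  tau <- curve$tau_s; g2 <- curve$g2
  obj <- function(p) {
    beta <- p[1]; bfi <- exp(p[2])
    if (beta <= 0 || beta > 1) return(1e6)
    sum((model_g2(tau, props, geom, medium, bfi, beta) - g2)^2)
  }
  fit <- optim(c(init[1], log(init[2])), obj,
               control = list(reltol = 1e-15, maxit = 2000))
  list(bfi_cm2s = unname(exp(fit$par[2])), beta = unname(fit$par[1]),
       converged = fit$convergence == 0, objective = fit$value)
}

#' Export a lookup table to CSV (long format, audit-friendly)
#'
#' One row per (channel, mua node, musp node) with amplitude and phase;
#' grid/engine metadata in commented header lines.
#'
#' @param lut An `fd_lut`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
lut_to_csv <- function(lut, path) {
  rows <- purrr::map_dfr(lut$channels, function(ch) {
    grid <- expand.grid(i = seq_along(lut$mua_grid),
                        j = seq_along(lut$musp_grid))
    tibble(wavelength_nm = ch$wavelength_nm,
           f_mod_mhz = ch$f_mod_mhz,
           mua = lut$mua_grid[grid$i], musp = lut$musp_grid[grid$j],
           amplitude = ch$amplitude[cbind(grid$i, grid$j)],
           phase = ch$phase[cbind(grid$i, grid$j)])
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# nirsdcs fd_lut engine=%s", lut$engine),
               sprintf("# rho_mm=%g n=%g g=%g seed=%s",
                       lut$geom$source_detector_separation_mm,
                       lut$medium$refractive_index,
                       lut$medium$anisotropy_g,
                       as.character(lut$meta$seed))), con)
  write.csv(rows, con, row.names = FALSE)
  invisible(path)
}
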