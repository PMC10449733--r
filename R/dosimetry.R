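#' Nuclide data for dosimetry
#'
#' Physical decay constant and mean electron energy per decay, used for
#' time-integrated activity and the local-deposition S-value approximation.
#' The lutetium-177 defaults (half-life 6.647 days; mean electron energy
#' about 147.9 keV per decay) come from standard decay tables and are plain
#' configuration fields, overridable per call.
#'
#' @param half_life_h physical half-life (h).
#' @param delta_j mean electron energy per decay (J).
#' @return Object of class `nuclide_data`: list with `lambda_phys` (1/h),
#'   `half_life_h` and `delta_j`.
#' @export
nuclide_lu177 <- function(half_life_h = 159.53, delta_j = 2.37e-14) {
  stopifnot(half_life_h > 0, delta_j > 0)
  structure(list(lambda_phys = log(2) / half_life_h,
                 half_life_h = half_life_h, delta_j = delta_j),
            class = "nuclide_data")
}

# Integrate y(t) over [0, t_last] from grid samples via a natural cubic
# spline (exact enough that a very fine trapezoid agrees to < 0.01%).
.grid_integral <- function(t, y, t_last) {
  f <- splinefun(t, y, method = "natural")
  integrate(f, 0, t_last, subdivisions = 2000L,
            rel.tol = 1e-10, abs.tol = 0)$value
}

#' Model AUC of a compartment concentration curve
#'
#' Numerical integral of the simulated decay-corrected concentration from 0
#' to the time of the last measurement.
#'
#' @param profile a `sim_profile`.
#' @param region compartment label.
#' @param t_last upper integration limit (h); must lie within the profile
#'   grid.
#' @return AUC in microgram h/L.
#' @export
auc_model <- function(profile, region, t_last = max(profile$times)) {
  if (t_last > max(profile$times) || t_last < min(profile$times)) {
    stop("t_last outside the simulated span", call. = FALSE)
  }
  .grid_integral(profile$times, profile_conc(profile, region), t_last)
}

#' Observed AUC by the trapezoidal rule
#'
#' Linear trapezoid over the non-excluded observation times of one region,
#' from the first to the last observation; no extrapolation to t = 0 or
#' beyond the last point.
#'
#' @param obs observation table.
#' @param region compartment label.
#' @return AUC in microgram h/L over the observed interval.
#' @export
auc_observed <- function(obs, region) {
  use <- obs$CMT == region & obs$EXCL == 0 & !is.na(obs$DV)
  t <- obs$TIME[use]; y <- obs$DV[use]
  if (length(t) < 2) {
    stop("need at least 2 non-excluded observations for region ", region,
         call. = FALSE)
  }
  o <- order(t)
  t <- t[o]; y <- y[o]
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Time-integrated activity of a region
#'
#' Converts the (decay-corrected) peptide amount curve of a region back to
#' activity using the injected specific activity and the physical decay of
#' the nuclide, integrates it to the end of the simulated/observed window,
#' and extrapolates to infinite time using the terminal log-linear slope of
#' the peptide curve: the tail is
#' `A(t_last) * SA * exp(-lambda_phys t_last) / (lambda_z + lambda_phys)`.
#'
#' @param profile a `sim_profile`.
#' @param region compartment label.
#' @param specific_activity injected specific activity (MBq per microgram),
#'   total administered activity over total administered peptide.
#' @param nuclide a [nuclide_lu177()]-style object.
#' @param t_last end of the integrated window (h).
#' @param slope_window length (h) of the terminal stretch of the model
#'   curve used for the log-linear slope fit.
#' @return List with `tia` (MBq h), `lambda_z` (1/h, peptide terminal
#'   slope), `tail_fraction` (share of the TIA from extrapolation, in
#'   `[0, 1)`).
#' @export
tia <- function(profile, region, specific_activity, nuclide = nuclide_lu177(),
                t_last = max(profile$times), slope_window = 24) {
  mw <- profile$params$mw
  amt_ug <- profile$amounts[, .region_index(region)] * mw / 1000
  t <- profile$times
  lp <- nuclide$lambda_phys

  core <- .grid_integral(t, amt_ug * exp(-lp * t), t_last) * specific_activity

  sel <- t >= max(t) - slope_window & amt_ug > 0
  if (sum(sel) < 3) stop("too few points for terminal slope", call. = FALSE)
  fit <- lm(log(amt_ug[sel]) ~ t[sel])
  lambda_z <- -coef(fit)[[2]]
  if (lambda_z <= 0) {
    stop("non-positive terminal slope; tail extrapolation undefined",
         call. = FALSE)
  }
  a_last <- approx(t, amt_ug, xout = t_last)$y
  tail_tia <- a_last * specific_activity * exp(-lp * t_last) /
    (lambda_z + lp)
  total <- core + tail_tia
  list(tia = total, lambda_z = lambda_z, tail_fraction = tail_tia / total)
}

#' Time-integrated activity from observed concentrations
#'
#' Observed-trapezoid counterpart of [tia()]: converts non-excluded
#' observed concentrations of a region to activity, integrates by linear
#' trapezoid over the observation window, and extrapolates beyond the last
#' observation using the terminal slope fitted to the last points of the
#' observed peptide curve.
#'
#' @param obs observation table.
#' @param region compartment label.
#' @param volume_l region volume (L) converting concentration to amount.
#' @param specific_activity injected specific activity (MBq per microgram).
#' @param nuclide a `nuclide_data` object.
#' @param n_tail number of trailing observations for the slope fit.
#' @return List with `tia` (MBq h), `lambda_z`, `tail_fraction`.
#' @export
tia_observed <- function(obs, region, volume_l, specific_activity,
                         nuclide = nuclide_lu177(), n_tail = 3) {
  use <- obs$CMT == region & obs$EXCL == 0 & !is.na(obs$DV) & obs$DV > 0
  t <- obs$TIME[use]; y <- obs$DV[use] * volume_l   # microgram
  if (length(t) < 2) stop("need at least 2 observations", call. = FALSE)
  o <- order(t); t <- t[o]; y <- y[o]
  act <- y * specific_activity * exp(-nuclide$lambda_phys * t)
  core <- sum(diff(t) * (head(act, -1) + tail(act, -1)) / 2)
  k <- min(n_tail, length(t))
  ts <- tail(t, k); ys <- tail(y, k)
  lambda_z <- if (k >= 2) -coef(lm(log(ys) ~ ts))[[2]] else NA_real_
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    stop("non-positive terminal slope in observed curve", call. = FALSE)
  }
  tail_tia <- tail(act, 1) / (lambda_z + nuclide$lambda_phys)
  total <- core + tail_tia
  list(tia = total, lambda_z = lambda_z, tail_fraction = tail_tia / total)
}

#' Local-deposition sphere S value
#'
#' Absorbed dose per unit time-integrated activity assuming all electron
#' energy is absorbed locally: `S = delta * 3.6e9 / mass`
#' (1 MBq h = 3.6e9 decays). A configuration-supplied S value (from organ
#' dosimetry tables) bypasses the approximation.
#'
#' @param mass_kg region mass (kg); for tumors, volume times a tissue
#'   density of 1.05 g/cm^3.
#' @param nuclide a `nuclide_data` object.
#' @param s_value optional externally supplied S value (Gy per MBq h);
#'   returned unchanged if given.
#' @return S value in Gy per MBq h.
#' @export
sphere_s_value <- function(mass_kg, nuclide = nuclide_lu177(),
                           s_value = NULL) {
  if (!is.null(s_value)) return(s_value)
  if (mass_kg <= 0) stop("mass must be positive", call. = FALSE)
  nuclide$delta_j * 3.6e9 / mass_kg
}

#' Tumor mass from volume
#'
#' @param volume_ml tumor volume (mL).
#' @param density_g_cm3 tissue density (g/cm^3).
#' @return Mass in kg.
#' @export
tumor_mass_kg <- function(volume_ml, density_g_cm3 = 1.05) {
  volume_ml * density_g_cm3 / 1000
}

#' Absorbed dose (MIRD self-dose)
#'
#' @param tia_mbqh time-integrated activity (MBq h).
#' @param s_value S value (Gy per MBq h).
#' @return Absorbed dose (Gy).
#' @export
absorbed_dose <- function(tia_mbqh, s_value) {
  stopifnot(tia_mbqh >= 0, s_value >= 0)
  tia_mbqh * s_value
}

#' Per-region dose report for a simulated profile
#'
#' Convenience wrapper combining [auc_model()], [tia()], [sphere_s_value()]
#' and [absorbed_dose()] for one region.
#'
#' @inheritParams tia
#' @param mass_kg region mass for the S value (ignored when `s_value`
#'   given).
#' @param s_value optional externally supplied S value.
#' @return data.frame with `region`, `auc_0_tlast`, `tia_mbqh`,
#'   `tail_fraction`, `s_value`, `dose_gy`.
#' @export
dose_report <- function(profile, region, specific_activity, mass_kg = NULL,
                        nuclide = nuclide_lu177(), s_value = NULL,
                        t_last = max(profile$times)) {
  a <- auc_model(profile, region, t_last)
  ti <- tia(profile, region, specific_activity, nuclide, t_last)
  s <- sphere_s_value(mass_kg, nuclide, s_value)
  data.frame(region = region, auc_0_tlast = a, tia_mbqh = ti$tia,
             tail_fraction = ti$tail_fraction, s_value = s,
             dose_gy = absorbed_dose(ti$tia, s))
}
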