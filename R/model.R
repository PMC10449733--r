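# State layout shared with the compiled right-hand side
.STATES <- c("A1", "A2", "A3", "A4", "A5", "A6", "excreted", "degraded")

# Assemble the parameter vector passed to the compiled derivatives:
# covariate effects fold into k12 (tumor sink) and k14 (tumor-volume power),
# etas are applied first, and bmax concentrations become binding amounts
# through the compartment volumes (V4 is patient-specific, mL -> L).
.cparms <- function(params, patient, eta = NULL,
                    infusion_rate = 0, infusion_dur = 0, saturable = TRUE) {
  p <- apply_iiv(params, eta)
  k12e <- p$k12 * tumor_sink_factor(p, patient)
  k14e <- p$k14 * tumor_volume_effect(p, patient)
  v4_l <- patient$v4_ml / 1000
  B <- c(p$bmax[["cmt2"]] * p$V[["V2"]],
         p$bmax[["cmt3"]] * p$V[["V3"]],
         p$bmax[["cmt4"]] * v4_l,
         p$bmax[["cmt5"]] * p$V[["V5"]])
  if (!saturable) B <- rep(Inf, 4)
  c(p$k10, k12e, p$k13, k14e, p$k15, p$k16,
    unname(p$kdeg), p$fu, B, infusion_rate, infusion_dur)
}

# Low-level adaptive solve at the requested times (must include 0).
.solve_amounts <- function(cp, dose_nmol, times, rtol = 1e-8, atol = 1e-10) {
  dur <- cp[18]
  y0 <- numeric(8)
  if (dur <= 0) y0[1] <- dose_nmol
  out <- deSolve::lsoda(y = y0, times = times, func = "theranopk_derivs",
                        parms = cp, dllname = "theranopk",
                        initfunc = "theranopk_initmod",
                        rtol = rtol, atol = atol)
  if (nrow(out) < length(times)) {
    stop("ODE solver failed to reach the requested times", call. = FALSE)
  }
  m <- unname(out[, -1, drop = FALSE])
  colnames(m) <- .STATES
  m
}

#' Model right-hand side (reference R implementation)
#'
#' Time derivatives of the six compartment amounts and the two mass-balance
#' ledgers (cumulative renal excretion and cumulative degradation), in nmol/h.
#' Uptake into the receptor-expressing compartments (spleen, kidney, tumor,
#' other SSTR organs) is saturable: the flux from blood scales with the free
#' fraction of binding sites `1 - A_x / B_x`; the rest compartment is
#' non-saturable. Only unbound peptide (`fu`) is available for tissue uptake.
#' Degradation (`kx0`) removes material from the system; there is no
#' tissue-to-blood redistribution. This R implementation mirrors the compiled
#' code used by [simulate_profile()] and exists for direct inspection and
#' as one arm of the solver cross-check.
#'
#' @param state numeric vector of length 8 (`A1`..`A6`, `excreted`,
#'   `degraded`), in nmol.
#' @param time time (h); only relevant while an infusion is running.
#' @param params `agent_params` (population values).
#' @param patient `patient_record` (tumor volumes).
#' @param eta optional named random-effect vector.
#' @param infusion_rate infusion rate (nmol/h) active while
#'   `time < infusion_dur`.
#' @param infusion_dur infusion duration (h).
#' @param saturable set `FALSE` to disable receptor saturation (linear model).
#' @return Named numeric vector of derivatives (nmol/h).
#' @export
model_rhs <- function(state, time, params, patient, eta = NULL,
                      infusion_rate = 0, infusion_dur = 0, saturable = TRUE) {
  cp <- .cparms(params, patient, eta, infusion_rate, infusion_dur, saturable)
  a1 <- state[1]
  frees <- 1 - state[2:5] / cp[13:16]
  frees[!is.finite(cp[13:16])] <- 1
  fu <- cp[12]
  upt <- fu * cp[2:5] * a1 * frees        # k12e, k13, k14e, k15
  u6 <- fu * cp[6] * a1                   # k16, non-saturable
  inf <- if (infusion_dur > 0 && time < infusion_dur) infusion_rate else 0
  kdeg <- cp[7:11]
  d <- c(inf - cp[1] * a1 - sum(upt) - u6,
         upt - kdeg[1:4] * state[2:5],
         u6 - kdeg[5] * state[6],
         cp[1] * a1,
         sum(kdeg * state[2:6]))
  names(d) <- .STATES
  d
}

#' Simulate a concentration-time profile
#'
#' Solves the six-compartment saturable system for one patient and agent
#' with a stiff-capable adaptive integrator, from administration (bolus at
#' t = 0 by default, or a zero-order infusion if the patient's dosing record
#' has `dur_h > 0`) over a dense output grid. Internal amounts are in nmol;
#' the injected peptide mass (micrograms) is converted through the molecular
#' weight in `params$mw`.
#'
#' @param params `agent_params` for the agent being dosed.
#' @param patient `patient_record`; supplies the dose (unless overridden) and
#'   the tumor volumes.
#' @param eta optional named random-effect vector (see [apply_iiv()]).
#' @param times output time grid (h), sorted, starting at or after 0.
#' @param dose_ug optional dose override (micrograms); defaults to the
#'   patient's dosing record for `params$agent`.
#' @param saturable set `FALSE` to disable receptor saturation.
#' @param rtol,atol solver tolerances (relative; absolute, nmol).
#' @return Object of class `sim_profile`: list with `times`, `amounts`
#'   (matrix, nmol, columns `A1`..`A6`, `excreted`, `degraded`), `conc`
#'   (matrix, microgram/L, columns `blood`..`rest`), `occupancy` (matrix,
#'   fraction of binding sites occupied, columns `spleen`, `kidney`,
#'   `tumor`, `sstr_other`), `dose_nmol`, `mass_defect` (largest relative
#'   mass-balance violation after infusion end), plus the inputs.
#' @export
simulate_profile <- function(params, patient, eta = NULL,
                             times = seq(0, 96, by = 0.1), dose_ug = NULL,
                             saturable = TRUE, rtol = 1e-8, atol = 1e-10) {
  if (is.unsorted(times, strictly = TRUE)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  if (times[1] < 0) stop("time grid must start at or after 0", call. = FALSE)
  dosing <- patient$dosing[[params$agent]]
  if (is.null(dose_ug)) {
    if (is.null(dosing)) stop("patient has no dosing record for agent ",
                              params$agent, call. = FALSE)
    dose_ug <- dosing$peptide_ug
  }
  dur <- if (!is.null(dosing) && !is.null(dosing$dur_h)) dosing$dur_h else 0
  dose_nmol <- dose_ug * 1000 / params$mw
  rate <- if (dur > 0) dose_nmol / dur else 0

  solve_times <- times
  drop0 <- FALSE
  if (solve_times[1] > 0) {
    solve_times <- c(0, solve_times)
    drop0 <- TRUE
  }
  # stop exactly at infusion end so the discontinuity falls on a mesh point
  if (dur > 0 && !(dur %in% solve_times) && dur < max(solve_times)) {
    solve_times <- sort(c(solve_times, dur))
  }
  cp <- .cparms(params, patient, eta, rate, dur, saturable)
  amounts <- .solve_amounts(cp, dose_nmol, solve_times, rtol, atol)
  keep <- solve_times %in% times
  if (drop0) keep[1] <- FALSE
  amounts <- amounts[keep, , drop = FALSE]
  amounts[amounts < 0 & amounts > -atol * 10] <- 0

  p_i <- apply_iiv(params, eta)
  vols <- c(p_i$V[["V1"]], p_i$V[["V2"]], p_i$V[["V3"]],
            patient$v4_ml / 1000, p_i$V[["V5"]], p_i$V[["V6"]])
  conc <- sweep(amounts[, 1:6, drop = FALSE] * params$mw / 1000, 2, vols, "/")
  colnames(conc) <- names(.REGIONS)

  Bamt <- cp[13:16]
  occ <- sweep(amounts[, 2:5, drop = FALSE], 2, Bamt, "/")
  occ[, !is.finite(Bamt)] <- NA_real_
  colnames(occ) <- names(.REGIONS)[2:5]

  defect <- if (dose_nmol > 0) {
    after <- times >= dur
    max(abs(rowSums(amounts[after, , drop = FALSE]) - dose_nmol)) / dose_nmol
  } else 0

  structure(list(times = times, amounts = amounts, conc = conc,
                 occupancy = occ, dose_nmol = dose_nmol,
                 mass_defect = defect, params = params, eta = eta,
                 patient = patient, agent = params$agent),
            class = "sim_profile")
}

#' @export
print.sim_profile <- function(x, ...) {
  cat("<sim_profile>", x$agent, "agent, patient", x$patient$id, "\n")
  cat(sprintf("  %d time points over %.3g-%.3g h, dose %.4g nmol\n",
              length(x$times), min(x$times), max(x$times), x$dose_nmol))
  cat(sprintf("  mass-balance defect %.2e (relative)\n", x$mass_defect))
  invisible(x)
}

#' Concentration accessor for a simulated profile
#'
#' Decay-corrected peptide concentration (microgram/L) in one compartment,
#' linearly interpolated to arbitrary times within the simulated span.
#'
#' @param profile a `sim_profile`.
#' @param region compartment label (`blood`, `spleen`, `kidney`, `tumor`,
#'   `sstr_other`, `rest`).
#' @param times times (h); defaults to the profile grid.
#' @return Numeric vector of concentrations.
#' @export
profile_conc <- function(profile, region, times = NULL) {
  region <- match.arg(region, names(.REGIONS))
  y <- profile$conc[, region]
  if (is.null(times)) return(y)
  if (any(times < min(profile$times) | times > max(profile$times))) {
    stop("requested times outside the simulated span", call. = FALSE)
  }
  approx(profile$times, y, xout = times)$y
}

#' Maximum receptor occupancy per compartment
#'
#' The peak fraction of occupied binding sites over the simulated grid for
#' each receptor-expressing compartment.
#'
#' @param profile a `sim_profile`.
#' @return Named numeric vector (`spleen`, `kidney`, `tumor`, `sstr_other`),
#'   each in `[0, 1]`.
#' @export
max_occupancy <- function(profile) {
  apply(profile$occupancy, 2, max)
}

#' Fixed-step fourth-order simulation (cross-check integrator)
#'
#' Classical Runge-Kutta integration of the same system at a fixed step,
#' independent of the adaptive compiled-code path. Intended for verifying
#' the adaptive solver; slow by design.
#'
#' @inheritParams simulate_profile
#' @param dt fixed step size (h).
#' @return Matrix of amounts (nmol) at `times`, columns as in
#'   [simulate_profile()].
#' @export
simulate_fixed_step <- function(params, patient, eta = NULL,
                                times = seq(0, 96, by = 1), dt = 0.001,
                                dose_ug = NULL, saturable = TRUE) {
  dosing <- patient$dosing[[params$agent]]
  if (is.null(dose_ug)) dose_ug <- dosing$peptide_ug
  dur <- if (!is.null(dosing) && !is.null(dosing$dur_h)) dosing$dur_h else 0
  dose_nmol <- dose_ug * 1000 / params$mw
  rate <- if (dur > 0) dose_nmol / dur else 0
  cp <- .cparms(params, patient, eta, rate, dur, saturable)
  k10 <- cp[1]; kin <- cp[2:6]; kdeg <- cp[7:11]; fu <- cp[12]; B <- cp[13:16]
  sat <- is.finite(B)

  rhs <- function(t, y) {
    a1 <- y[1]
    fr <- rep(1, 4)
    fr[sat] <- 1 - y[2:5][sat] / B[sat]
    upt <- fu * kin[1:4] * a1 * fr
    u6 <- fu * kin[5] * a1
    inf <- if (dur > 0 && t < dur) rate else 0
    c(inf - k10 * a1 - sum(upt) - u6,
      upt - kdeg[1:4] * y[2:5],
      u6 - kdeg[5] * y[6],
      k10 * a1,
      sum(kdeg * y[2:6]))
  }

  y <- numeric(8)
  if (dur <= 0) y[1] <- dose_nmol
  out <- matrix(NA_real_, length(times), 8,
                dimnames = list(NULL, .STATES))
  t <- 0
  j <- 1
  while (j <= length(times) && times[j] <= t) { out[j, ] <- y; j <- j + 1 }
  while (j <= length(times)) {
    h <- min(dt, times[j] - t)
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2)
    k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    while (j <= length(times) && times[j] <= t + 1e-12) {
      out[j, ] <- y
      j <- j + 1
    }
  }
  out
}
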