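#' Virtual cohort configuration
#'
#' Describes the population and design a virtual cohort is drawn from:
#' tumor volumes (lognormal, parameterized by the printed median, truncated
#' to the printed range), injected peptide amounts and radioactivity per
#' agent (uniform over the printed ranges), the imaging schedule (one
#' diagnostic scan at 0.75 h; therapeutic scans at 0.5, 4, 24 and 72 h),
#' the observed regions, the proportional residual variance, and whether a
#' patient's therapeutic random effects are the translation of their
#' diagnostic ones (`eta_mode = "shared"`, one latent physiology per
#' patient) or drawn independently.
#'
#' @param n_patients number of virtual patients.
#' @param sigma2 proportional residual variance (0.1 corresponds to a
#'   residual CV of about 31.6%).
#' @param eta_mode `"shared"` or `"independent"`.
#' @param v4,vtot lists with `median` (mL), `range` (mL) and `sdlog` for the
#'   tumor compartment volume and the total tumor volume.
#' @param dosing per-agent lists with `peptide_range` (micrograms) and
#'   `activity_range` (MBq).
#' @param schedule per-agent observation times (h).
#' @param regions observed compartment labels.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 9,
                          sigma2 = 0.1,
                          eta_mode = c("shared", "independent"),
                          v4 = list(median = 80.0, range = c(7.81, 212),
                                    sdlog = 0.5),
                          vtot = list(median = 283, range = c(22.4, 644),
                                      sdlog = 0.45),
                          dosing = list(
                            diagnostic = list(peptide_range = c(3.01, 9.64),
                                              activity_range = c(75.6, 102)),
                            therapeutic = list(peptide_range = c(132, 178),
                                               activity_range = c(7176, 7613))),
                          schedule = list(diagnostic = 0.75,
                                          therapeutic = c(0.5, 4, 24, 72)),
                          regions = c("spleen", "kidney", "tumor")) {
  eta_mode <- match.arg(eta_mode)
  stopifnot(n_patients >= 1, sigma2 >= 0,
            all(v4$range > 0), all(vtot$range > 0),
            v4$range[1] < v4$range[2], vtot$range[1] < vtot$range[2])
  structure(list(n_patients = n_patients, sigma2 = sigma2,
                 eta_mode = eta_mode, v4 = v4, vtot = vtot,
                 dosing = dosing, schedule = schedule, regions = regions),
            class = "cohort_config")
}

# Range-truncated lognormal draw (rejection; the truncation mass is small
# by construction so this terminates quickly).
.rlnorm_trunc <- function(n, median, sdlog, range, lower = NULL) {
  lo <- if (is.null(lower)) range[1] else pmax(range[1], lower)
  if (any(lo > range[2])) stop("infeasible truncation bounds", call. = FALSE)
  if (length(lo) == 1) lo <- rep(lo, n)
  out <- numeric(n)
  todo <- seq_len(n)
  for (i in 1:1000) {
    draw <- rlnorm(length(todo), meanlog = log(median), sdlog = sdlog)
    ok <- draw >= lo[todo] & draw <= range[2]
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(out)
  }
  stop("truncated sampling failed to converge", call. = FALSE)
}

#' Sample a virtual cohort
#'
#' Draws patient covariates, dosing, and true random-effect vectors for both
#' agents. In `"shared"` mode the therapeutic eta vector is the translation
#' of the diagnostic one (see [map_etas_ga_to_lu()]), so each patient has a
#' single latent physiology and individual prediction from diagnostic data
#' is testable against ground truth; in `"independent"` mode the two vectors
#' are unrelated.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the draw is fully reproducible given
#'   `config` + `seed`.
#' @return Object of class `cohort`: list with `patients` (list of
#'   [patient_record()]), `etas` (per patient, lists `diagnostic` and
#'   `therapeutic` of true etas) and `config`.
#' @export
sample_cohort <- function(config, seed = 1L) {
  set.seed(seed)
  n <- config$n_patients
  v4 <- .rlnorm_trunc(n, config$v4$median, config$v4$sdlog, config$v4$range)
  vtot <- .rlnorm_trunc(n, config$vtot$median, config$vtot$sdlog,
                        config$vtot$range, lower = v4)

  draw_dose <- function(spec) {
    list(peptide_ug = runif(n, spec$peptide_range[1], spec$peptide_range[2]),
         activity_mbq = runif(n, spec$activity_range[1], spec$activity_range[2]))
  }
  d_ga <- draw_dose(config$dosing$diagnostic)
  d_lu <- draw_dose(config$dosing$therapeutic)

  om_ga <- omega_default("diagnostic")
  om_lu <- omega_default("therapeutic")
  patients <- vector("list", n)
  etas <- vector("list", n)
  sched <- function(times, regions) {
    expand.grid(time = times, cmt = regions, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    eta_ga <- setNames(rnorm(length(om_ga), 0, sqrt(om_ga)), names(om_ga))
    eta_lu <- if (config$eta_mode == "shared") {
      map_etas_ga_to_lu(eta_ga)
    } else {
      setNames(rnorm(length(om_lu), 0, sqrt(om_lu)), names(om_lu))
    }
    patients[[i]] <- patient_record(
      id = sprintf("P%03d", i), v4_ml = v4[i], vtot_ml = vtot[i],
      dosing = list(
        diagnostic = list(peptide_ug = d_ga$peptide_ug[i],
                          activity_mbq = d_ga$activity_mbq[i], dur_h = 0),
        therapeutic = list(peptide_ug = d_lu$peptide_ug[i],
                           activity_mbq = d_lu$activity_mbq[i], dur_h = 0)),
      schedule = list(
        diagnostic = sched(config$schedule$diagnostic, config$regions),
        therapeutic = sched(config$schedule$therapeutic, config$regions)))
    etas[[i]] <- list(diagnostic = eta_ga, therapeutic = eta_lu)
  }
  structure(list(patients = patients, etas = etas, config = config,
                 seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  v4 <- vapply(x$patients, function(p) p$v4_ml, 0)
  cat("<cohort>", length(x$patients), "patients,", x$config$eta_mode,
      "etas, seed", x$seed, "\n")
  cat(sprintf("  tumor compartment volume median %.3g mL (range %.3g-%.3g)\n",
              median(v4), min(v4), max(v4)))
  invisible(x)
}

#' Simulate noisy observations from a profile
#'
#' Applies the proportional residual error model to model concentrations at
#' the scheduled observation times: each record is the model prediction
#' times `1 + eps` with `eps ~ Normal(0, sigma2)`. Draws below -1 (which
#' would give a negative concentration) are truncated at -1 with a warning;
#' at the default variance this affects well under 0.1% of records.
#'
#' @param profile a `sim_profile` covering the schedule times.
#' @param schedule data.frame with columns `time` (h) and `cmt`
#'   (region label).
#' @param sigma2 proportional residual variance.
#' @param id patient identifier for the output table.
#' @return Observation table: data.frame with columns `ID`, `AGENT`, `TIME`,
#'   `CMT`, `DV` (microgram/L), `EXCL` (0/1), `EXCL_REASON`.
#' @export
simulate_observations <- function(profile, schedule, sigma2,
                                  id = profile$patient$id) {
  if (any(schedule$time < min(profile$times) |
            schedule$time > max(profile$times))) {
    stop("schedule times outside the simulated span", call. = FALSE)
  }
  pred <- vapply(seq_len(nrow(schedule)), function(j) {
    profile_conc(profile, schedule$cmt[j], schedule$time[j])
  }, 0)
  eps <- if (sigma2 > 0) rnorm(nrow(schedule), 0, sqrt(sigma2)) else
    numeric(nrow(schedule))
  n_trunc <- sum(eps < -1)
  if (n_trunc > 0) {
    warning(n_trunc, " residual draw(s) truncated at -1 (concentration floor 0)")
    eps <- pmax(eps, -1)
  }
  data.frame(ID = id, AGENT = profile$agent, TIME = schedule$time,
             CMT = schedule$cmt, DV = pred * (1 + eps),
             EXCL = 0L, EXCL_REASON = "", stringsAsFactors = FALSE)
}

#' Simulate the full observation table for a cohort
#'
#' Runs the forward model for every patient under their true etas and
#' applies residual noise at the cohort's scheduled times.
#'
#' @param cohort a [sample_cohort()] result.
#' @param agent which agent to simulate.
#' @param params population parameters (defaults to [agent_params()] for
#'   the agent).
#' @param sigma2 residual variance; defaults to the cohort config.
#' @return Observation table (see [simulate_observations()]).
#' @export
simulate_cohort_observations <- function(cohort,
                                         agent = c("diagnostic", "therapeutic"),
                                         params = NULL, sigma2 = NULL) {
  agent <- match.arg(agent)
  if (is.null(params)) params <- agent_params(agent)
  if (is.null(sigma2)) sigma2 <- cohort$config$sigma2
  tabs <- lapply(seq_along(cohort$patients), function(i) {
    pat <- cohort$patients[[i]]
    sch <- pat$schedule[[agent]]
    tgrid <- sort(unique(c(0, sch$time)))
    prof <- simulate_profile(params, pat, eta = cohort$etas[[i]][[agent]],
                             times = tgrid)
    simulate_observations(prof, sch, sigma2)
  })
  do.call(rbind, tabs)
}

.OBS_COLS <- c("ID", "AGENT", "TIME", "CMT", "DV", "EXCL", "EXCL_REASON")

#' Write / read an observation table
#'
#' Long-format tab-delimited text with header columns `ID`, `AGENT`, `TIME`
#' (h), `CMT` (compartment label), `DV` (microgram/L), `EXCL` (0/1),
#' `EXCL_REASON`. Missing concentrations are written as `NA`.
#'
#' @param obs observation table (data.frame with the columns above).
#' @param path file path.
#' @return `read_observations` returns the table; malformed rows (negative
#'   `DV`, unknown `CMT`, missing columns) raise errors naming the offending
#'   line.
#' @export
write_observations <- function(obs, path) {
  stopifnot(all(.OBS_COLS %in% names(obs)))
  out <- obs[, .OBS_COLS]
  out$TIME <- formatC(out$TIME, digits = 10, format = "g")
  out$DV <- formatC(out$DV, digits = 10, format = "g")
  out$DV[is.na(obs$DV)] <- "NA"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(ID = "character", AGENT = "character",
                                   TIME = "numeric", CMT = "character",
                                   DV = "numeric", EXCL = "integer",
                                   EXCL_REASON = "character"))
  missing_cols <- setdiff(.OBS_COLS, names(obs))
  if (length(missing_cols)) {
    stop("observation file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs$EXCL_REASON[is.na(obs$EXCL_REASON)] <- ""
  # +1 for the header: report physical line numbers
  bad_dv <- which(!is.na(obs$DV) & obs$DV < 0)
  if (length(bad_dv)) {
    stop("negative DV at line ", paste(bad_dv + 1L, collapse = ", "),
         call. = FALSE)
  }
  bad_t <- which(obs$TIME < 0)
  if (length(bad_t)) {
    stop("negative TIME at line ", paste(bad_t + 1L, collapse = ", "),
         call. = FALSE)
  }
  bad_cmt <- which(!obs$CMT %in% names(.REGIONS))
  if (length(bad_cmt)) {
    stop("unknown CMT at line ", paste(bad_cmt + 1L, collapse = ", "),
         call. = FALSE)
  }
  obs
}

#' Write / read cohort covariates
#'
#' Companion tab-delimited file to the observation table: one row per
#' patient with columns `ID`, `V4_ML`, `VTOT_ML`, `PEP_UG_GA`, `PEP_UG_LU`,
#' `ACT_MBQ_GA`, `ACT_MBQ_LU`.
#'
#' @param cohort a `cohort` object.
#' @param path file path.
#' @return `read_cohort_covariates` returns a data.frame with the columns
#'   above.
#' @export
write_cohort_covariates <- function(cohort, path) {
  df <- do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(ID = p$id, V4_ML = p$v4_ml, VTOT_ML = p$vtot_ml,
               PEP_UG_GA = p$dosing$diagnostic$peptide_ug,
               PEP_UG_LU = p$dosing$therapeutic$peptide_ug,
               ACT_MBQ_GA = p$dosing$diagnostic$activity_mbq,
               ACT_MBQ_LU = p$dosing$therapeutic$activity_mbq)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_covariates
#' @export
read_cohort_covariates <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(ID = "character"))
}
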