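#' Default population parameters for one agent
#'
#' Returns the final population parameter set of the six-compartment
#' receptor-saturable model for the diagnostic (gallium-68 labelled) or the
#' therapeutic (lutetium-177 labelled) peptide. Rate constants `k1x` move
#' material from blood into compartment `x`; `kx0` are degradation rate
#' constants out of the system; `fu` is the unbound plasma fraction. Maximal
#' binding-site concentrations (`bmax`, nmol/L) are converted to binding
#' amounts by multiplication with the compartment volume, so a larger tumor
#' compartment carries proportionally more receptor. The tumor compartment
#' volume (V4) is patient-specific and therefore not part of this set.
#'
#' @param agent `"diagnostic"` or `"therapeutic"`.
#' @param ... named overrides for any field of the returned set
#'   (e.g. `mw = 1500`, `k14 = 0.2`, `bmax = c(...)`).
#'
#' @return An object of class `agent_params`: a list with elements
#'   `agent`, `k10`, `k12`, `k13`, `k14`, `k15`, `k16`,
#'   `kdeg` (named `k20`..`k60`, 1/h), `fu`,
#'   `bmax` (named `cmt2`..`cmt5`, nmol/L),
#'   `V` (named `V1`,`V2`,`V3`,`V5`,`V6`, litres),
#'   `sink_coeff` (1/L), `eff` (tumor-volume exponent),
#'   `v4_ref` (reference tumor compartment volume, mL) and
#'   `mw` (molecular weight, g/mol, for microgram/nanomole conversion).
#' @export
#' @examples
#' p <- agent_params("diagnostic")
#' p$k14           # 0.11 1/h
#' agent_params("therapeutic")$k10  # 0.575 1/h
agent_params <- function(agent = c("diagnostic", "therapeutic"), ...) {
  agent <- match.arg(agent)
  shared <- list(
    k15 = 2.5, k16 = 1,
    kdeg = c(k20 = 0.01, k30 = 0.01, k40 = 0.01, k50 = 0.01, k60 = 0.01),
    bmax = c(cmt2 = 16.7, cmt3 = 6.7, cmt4 = 30, cmt5 = 2.4),
    V = c(V1 = 4, V2 = 0.21, V3 = 0.3, V5 = 4, V6 = 50),
    sink_coeff = 0.4,
    v4_ref = 80.0,
    mw = 1435.6
  )
  specific <- if (agent == "diagnostic") {
    list(k10 = 0.25, k12 = 0.21, k13 = 0.22, k14 = 0.11, fu = 0.69, eff = 1)
  } else {
    list(k10 = 0.575, k12 = 0.0607, k13 = 0.107, k14 = 0.157, fu = 0.57,
         eff = 0.67)
  }
  p <- c(list(agent = agent), specific, shared)
  if (agent == "therapeutic") p$kdeg[["k40"]] <- 0.00375

  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(dots)) {
      if (nm %in% c("kdeg", "bmax", "V")) {
        v <- dots[[nm]]
        p[[nm]][names(v)] <- v
      } else {
        p[[nm]] <- dots[[nm]]
      }
    }
  }
  validate_agent_params(p)
  structure(p, class = "agent_params")
}

validate_agent_params <- function(p) {
  rates <- c(p$k10, p$k12, p$k13, p$k14, p$k15, p$k16, p$kdeg)
  if (any(rates < 0)) stop("rate constants must be non-negative", call. = FALSE)
  if (p$fu < 0 || p$fu > 1) stop("fu must lie in [0, 1]", call. = FALSE)
  if (any(p$V <= 0)) stop("compartment volumes must be positive", call. = FALSE)
  if (any(p$bmax < 0)) stop("bmax concentrations must be non-negative", call. = FALSE)
  if (p$v4_ref <= 0) stop("v4_ref must be positive", call. = FALSE)
  if (p$mw <= 0) stop("molecular weight must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params> agent:", x$agent, "\n")
  cat(sprintf("  k10 %.4g  k12 %.4g  k13 %.4g  k14 %.4g  k15 %.4g  k16 %.4g  (1/h)\n",
              x$k10, x$k12, x$k13, x$k14, x$k15, x$k16))
  cat("  kdeg:", paste(sprintf("%s=%.4g", names(x$kdeg), x$kdeg), collapse = " "), "\n")
  cat(sprintf("  fu %.3g  eff %.3g  sink_coeff %.3g 1/L  v4_ref %.4g mL  mw %.6g g/mol\n",
              x$fu, x$eff, x$sink_coeff, x$v4_ref, x$mw))
  cat("  bmax (nmol/L):", paste(sprintf("%s=%.3g", names(x$bmax), x$bmax), collapse = " "), "\n")
  cat("  V (L):", paste(sprintf("%s=%.3g", names(x$V), x$V), collapse = " "), "\n")
  invisible(x)
}

#' Default inter-individual variability specification
#'
#' Variances (omega-squared) of the lognormal random effects per agent. For
#' the diagnostic agent variability sits on the uptake rate constants and
#' renal excretion; for the therapeutic agent it sits on renal excretion and
#' the maximal binding-site concentrations (receptor expression), reflecting
#' that at the much higher therapeutic peptide amount uptake is driven by
#' receptor density rather than uptake rate. Coefficients of variation of
#' 31.6% and 50% correspond to variances 0.1 and 0.25.
#'
#' @param agent `"diagnostic"` or `"therapeutic"`.
#' @return Named numeric vector of variances; names are the eta keys
#'   (`k10`, `k12`, `k13`, `k14`, `k15` for diagnostic;
#'   `k10`, `bmax2`, `bmax3`, `bmax4`, `bmax5` for therapeutic).
#' @export
omega_default <- function(agent = c("diagnostic", "therapeutic")) {
  agent <- match.arg(agent)
  if (agent == "diagnostic") {
    c(k10 = 0.1, k12 = 0.25, k13 = 0.25, k14 = 0.25, k15 = 0.1)
  } else {
    c(k10 = 0.1, bmax2 = 0.25, bmax3 = 0.25, bmax4 = 0.25, bmax5 = 0.1)
  }
}

#' Eta keys carrying inter-individual variability for an agent
#' @param agent `"diagnostic"` or `"therapeutic"`.
#' @return Character vector of eta names.
#' @export
eta_keys <- function(agent = c("diagnostic", "therapeutic")) {
  names(omega_default(agent))
}

#' Patient covariate and dosing record
#'
#' @param id patient identifier.
#' @param v4_ml tumor compartment volume (mL): the sum of the segmented
#'   target-lesion volumes. Used both for the tumor binding amount and for
#'   converting tumor amounts to concentrations.
#' @param vtot_ml total tumor volume (mL), all lesions; drives the tumor
#'   sink effect. Must be at least `v4_ml`.
#' @param dosing named list with elements `diagnostic` and `therapeutic`,
#'   each a list `peptide_ug` (injected peptide, micrograms), `activity_mbq`
#'   (injected radioactivity, MBq) and optional `dur_h` (infusion duration,
#'   h; 0 means instantaneous bolus at t = 0).
#' @param schedule named list with elements `diagnostic` and `therapeutic`,
#'   each a data.frame with columns `time` (h) and `cmt` (region label).
#' @return Object of class `patient_record`.
#' @export
patient_record <- function(id, v4_ml, vtot_ml, dosing, schedule = NULL) {
  stopifnot(v4_ml > 0, vtot_ml >= 0)
  if (v4_ml > vtot_ml) {
    stop("tumor compartment volume exceeds total tumor volume", call. = FALSE)
  }
  for (ag in names(dosing)) {
    d <- dosing[[ag]]
    if (is.null(d$dur_h)) dosing[[ag]]$dur_h <- 0
    if (d$peptide_ug <= 0) stop("peptide amount must be positive", call. = FALSE)
    if (d$activity_mbq <= 0) stop("activity must be positive", call. = FALSE)
  }
  structure(list(id = id, v4_ml = v4_ml, vtot_ml = vtot_ml,
                 dosing = dosing, schedule = schedule),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$id,
      sprintf(" V4 %.3g mL, total tumor %.3g mL\n", x$v4_ml, x$vtot_ml))
  for (ag in names(x$dosing)) {
    d <- x$dosing[[ag]]
    cat(sprintf("  %s: %.3g ug / %.4g MBq\n", ag, d$peptide_ug, d$activity_mbq))
  }
  invisible(x)
}

#' Tumor sink factor on spleen uptake
#'
#' Multiplicative covariate effect of total tumor burden on the spleen
#' uptake rate constant `k12`: `exp(-sink_coeff * V_tumor_total)` with the
#' volume in litres, so a high burden of disease competes ligand away from
#' healthy tissue.
#'
#' @param params an `agent_params` object (supplies `sink_coeff`).
#' @param patient a `patient_record`, or a total tumor volume in mL.
#' @return Dimensionless factor in (0, 1].
#' @export
#' @examples
#' tumor_sink_factor(agent_params("diagnostic"), 283) # about 0.893
tumor_sink_factor <- function(params, patient) {
  vtot_ml <- if (inherits(patient, "patient_record")) patient$vtot_ml else patient
  if (vtot_ml < 0) stop("total tumor volume must be non-negative", call. = FALSE)
  exp(-params$sink_coeff * vtot_ml / 1000)
}

#' Tumor-volume effect on tumor uptake
#'
#' Power-function covariate effect of the tumor compartment volume on the
#' tumor uptake rate constant `k14`: `(v4 / v4_ref)^eff`, so patients with a
#' large segmented tumor volume take up proportionally more than the typical
#' patient at the reference (median) volume.
#'
#' @param params an `agent_params` object (supplies `eff` and `v4_ref`).
#' @param patient a `patient_record`, or a tumor compartment volume in mL.
#' @return Dimensionless positive factor.
#' @export
#' @examples
#' tumor_volume_effect(agent_params("therapeutic"), 160) # 2^0.67
tumor_volume_effect <- function(params, patient) {
  v4_ml <- if (inherits(patient, "patient_record")) patient$v4_ml else patient
  if (v4_ml <= 0) stop("tumor compartment volume must be positive", call. = FALSE)
  (v4_ml / params$v4_ref)^params$eff
}

#' Apply individual random effects to a parameter set
#'
#' Individual parameters are the population values times `exp(eta)`
#' (lognormal inter-individual variability). Placement differs per agent:
#' for the diagnostic agent etas multiply rate constants
#' (`k10`, `k12`, `k13`, `k14`, `k15`); for the therapeutic agent they
#' multiply renal excretion `k10` and the binding-site concentrations
#' (`bmax2`..`bmax5`).
#'
#' @param params an `agent_params` object.
#' @param eta named numeric vector of random effects; names must be a subset
#'   of [eta_keys()] for the agent. `NULL` or an empty vector returns the
#'   population set unchanged.
#' @return An individualized `agent_params` object.
#' @export
apply_iiv <- function(params, eta) {
  if (is.null(eta) || length(eta) == 0) return(params)
  if (any(!is.finite(eta))) stop("etas must be finite", call. = FALSE)
  keys <- eta_keys(params$agent)
  bad <- setdiff(names(eta), keys)
  if (length(bad)) {
    stop("eta key(s) not defined for ", params$agent, " agent: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(eta)) {
    f <- exp(eta[[nm]])
    if (nm %in% c("k10", "k12", "k13", "k14", "k15")) {
      params[[nm]] <- params[[nm]] * f
    } else {
      cmt <- paste0("cmt", substring(nm, 5))
      params$bmax[[cmt]] <- params$bmax[[cmt]] * f
    }
  }
  params
}
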