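#' Build the therapeutic population parameter set from the diagnostic one
#'
#' The therapeutic agent shares the structural model with the diagnostic
#' agent; its population parameters are the diagnostic values scaled by
#' fold differences on the uptake rates into spleen (`k12`), kidney (`k13`)
#' and tumor (`k14`) and on the tumor degradation rate (`k40`), with its
#' own tumor-volume exponent. Renal excretion `k10` and the plasma unbound
#' fraction `fu` are fixed from external knowledge: a published clearance of
#' 2.3 L/h over the 4 L blood volume gives `k10 = 0.575` per hour, and
#' `fu = 0.57`. All other parameters are copied.
#'
#' @param ga_params diagnostic `agent_params`.
#' @param folds a [fold_parameters()] object.
#' @param fixed_lu list with the fixed therapeutic `k10` and `fu`.
#' @return Therapeutic `agent_params`.
#' @export
#' @examples
#' lu <- translate_population(agent_params("diagnostic"), fold_parameters())
#' lu$k14   # 0.11 * 1.43
translate_population <- function(ga_params, folds,
                                 fixed_lu = list(k10 = 0.575, fu = 0.57)) {
  for (f in c("fold12", "fold13", "fold14", "fold40")) {
    if (is.null(folds[[f]])) stop("missing ", f, call. = FALSE)
  }
  p <- ga_params
  p$agent <- "therapeutic"
  p$k12 <- ga_params$k12 * folds$fold12
  p$k13 <- ga_params$k13 * folds$fold13
  p$k14 <- ga_params$k14 * folds$fold14
  p$kdeg[["k40"]] <- ga_params$kdeg[["k40"]] * folds$fold40
  p$eff <- folds$eff
  p$k10 <- fixed_lu$k10
  p$fu <- fixed_lu$fu
  validate_agent_params(p)
  structure(p, class = "agent_params")
}

#' Map diagnostic individual random effects to therapeutic ones
#'
#' Inter-individual variability sits on uptake rate constants for the
#' diagnostic agent but on receptor binding capacities for the therapeutic
#' agent (at the much larger therapeutic peptide amount, uptake is limited
#' by receptor density). Both placements express the same latent
#' receptor-driven physiology, so an individual's deviation transfers by
#' value: `k10 -> k10`, `k12 -> bmax2`, `k13 -> bmax3`, `k14 -> bmax4`,
#' `k15 -> bmax5`.
#'
#' @param ga_etas named diagnostic eta vector (keys from
#'   `eta_keys("diagnostic")`).
#' @return Named therapeutic eta vector.
#' @export
map_etas_ga_to_lu <- function(ga_etas) {
  keys_ga <- eta_keys("diagnostic")
  missing_k <- setdiff(keys_ga, names(ga_etas))
  if (length(missing_k)) {
    stop("missing diagnostic eta key(s): ", paste(missing_k, collapse = ", "),
         call. = FALSE)
  }
  setNames(as.numeric(ga_etas[keys_ga]), eta_keys("therapeutic"))
}

#' Predict an individual therapeutic profile from diagnostic estimates
#'
#' Runs the forward model under the translated therapeutic population
#' parameters, the patient's therapeutic dosing and covariates, and the
#' individual's diagnostic eta estimates mapped onto the therapeutic
#' placement. With all-zero etas this reduces to [population_predict()].
#'
#' @param patient `patient_record` with therapeutic dosing.
#' @param ga_etas named diagnostic eta vector (e.g. from [map_estimate()]).
#' @param folds [fold_parameters()].
#' @param times output grid (h).
#' @param ga_params diagnostic population parameters.
#' @param fixed_lu fixed therapeutic `k10` and `fu`.
#' @return A `sim_profile` for the therapeutic agent.
#' @export
predict_individual <- function(patient, ga_etas, folds = fold_parameters(),
                               times = seq(0, 96, by = 0.1),
                               ga_params = agent_params("diagnostic"),
                               fixed_lu = list(k10 = 0.575, fu = 0.57)) {
  lu <- translate_population(ga_params, folds, fixed_lu)
  simulate_profile(lu, patient, eta = map_etas_ga_to_lu(ga_etas),
                   times = times)
}

#' Predict a therapeutic profile from population parameters only
#'
#' The typical-value prediction: the translated therapeutic population
#' parameters with eta = 0 and the patient's own dosing and covariates.
#' Diagnostic observations play no role.
#'
#' @inheritParams predict_individual
#' @return A `sim_profile` for the therapeutic agent.
#' @export
population_predict <- function(patient, folds = fold_parameters(),
                               times = seq(0, 96, by = 0.1),
                               ga_params = agent_params("diagnostic"),
                               fixed_lu = list(k10 = 0.575, fu = 0.57)) {
  lu <- translate_population(ga_params, folds, fixed_lu)
  simulate_profile(lu, patient, eta = NULL, times = times)
}
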