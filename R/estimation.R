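#' Flag early kidney observations as excluded
#'
#' Kidney region-of-interest signal shortly after injection mainly reflects
#' radioactivity in urine rather than intracellular uptake, so kidney
#' records from the first imaging time point are excluded from estimation.
#' Implemented as: kidney records with `TIME <= window` are flagged with
#' reason `"urine signal"`; all other records are untouched. The rule is
#' idempotent.
#'
#' @param obs observation table.
#' @param window exclusion window (h); the default 2 h covers the scheduled
#'   0.5 h scan while retaining the 4 h one.
#' @return The observation table with updated `EXCL`/`EXCL_REASON`.
#' @export
exclude_early_kidney <- function(obs, window = 2) {
  hit <- obs$CMT == "kidney" & obs$TIME <= window
  obs$EXCL[hit] <- 1L
  obs$EXCL_REASON[hit] <- "urine signal"
  obs
}

## ---------------------------------------------------------------------
## Prediction context: everything the optimization loops need, assembled
## once per (parameter set, patient, observation design). Etas are applied
## directly to the compiled-parameter vector (k10 and either the uptake
## rates or the binding amounts are simple multiplicative entries), which
## keeps the per-solve R overhead out of the hot path.
## ---------------------------------------------------------------------

.ETA_CP_IDX <- list(diagnostic = c(1L, 2L, 3L, 4L, 5L),   # k10, k12..k15
                    therapeutic = c(1L, 13L, 14L, 15L, 16L)) # k10, B2..B5

.make_ctx <- function(params, patient, tvec, cmtvec) {
  dosing <- patient$dosing[[params$agent]]
  dose_ug <- dosing$peptide_ug
  dur <- if (!is.null(dosing$dur_h)) dosing$dur_h else 0
  dose_nmol <- dose_ug * 1000 / params$mw
  rate <- if (dur > 0) dose_nmol / dur else 0
  cp0 <- .cparms(params, patient, NULL, rate, dur)
  ut <- sort(unique(c(0, tvec)))
  vols <- c(params$V[["V1"]], params$V[["V2"]], params$V[["V3"]],
            patient$v4_ml / 1000, params$V[["V5"]], params$V[["V6"]])
  ic <- .region_index(cmtvec)
  list(cp0 = cp0, dose_nmol = dose_nmol, ut = ut,
       idx = cbind(match(tvec, ut), ic),
       convf = params$mw / 1000 / vols[ic],
       eta_idx = .ETA_CP_IDX[[params$agent]])
}

.ctx_pred <- function(ctx, eta) {
  cp <- ctx$cp0
  cp[ctx$eta_idx] <- cp[ctx$eta_idx] * exp(eta)
  am <- .solve_amounts(cp, ctx$dose_nmol, ctx$ut)
  am[ctx$idx] * ctx$convf
}

.ctx_jac <- function(ctx, eta, f0, h = 1e-4) {
  J <- matrix(0, length(f0), length(eta))
  for (k in seq_along(eta)) {
    ek <- eta; ek[k] <- ek[k] + h
    J[, k] <- (.ctx_pred(ctx, ek) - f0) / h
  }
  J
}

# joint -2 log density of (observations, eta), all constants kept
.ctx_g <- function(f, dv, eta, omega, sigma2) {
  sum((dv - f)^2 / (sigma2 * f^2) + log(2 * pi * sigma2 * f^2)) +
    sum(eta^2 / omega + log(2 * pi * omega))
}

# gradient of .ctx_g wrt eta given predictions and their Jacobian
.ctx_g_grad <- function(f, J, dv, eta, omega, sigma2) {
  r <- dv - f
  drop(crossprod(J, -2 * r / (sigma2 * f^2) - 2 * r^2 / (sigma2 * f^3) +
                      2 / f)) + 2 * eta / omega
}

# Minimize the joint -2 log density for one patient. The gradient is exact
# given the prediction Jacobian (refreshed each gradient call); nlminb's
# internal differencing would drown in adaptive-solver noise.
.ctx_mode <- function(ctx, dv, omega, sigma2, eta_start,
                      reltol = 1e-8, iter_max = 100) {
  if (!nrow(ctx$idx)) {
    return(list(eta = rep(0, length(omega)),
                objective = sum(log(2 * pi * omega)), converged = TRUE,
                n_eval = 0L))
  }
  gfun <- function(eta) .ctx_g(.ctx_pred(ctx, eta), dv, eta, omega, sigma2)
  grad <- function(eta) {
    f <- .ctx_pred(ctx, eta)
    .ctx_g_grad(f, .ctx_jac(ctx, eta, f), dv, eta, omega, sigma2)
  }
  bound <- 4 * sqrt(omega)   # keep the search inside physically sane territory
  fit <- nlminb(eta_start, gfun, gradient = grad,
                lower = -bound, upper = bound,
                control = list(rel.tol = reltol, iter.max = iter_max))
  list(eta = fit$par, objective = fit$objective,
       converged = fit$convergence == 0,
       n_eval = fit$evaluations[["function"]])
}

# Gauss-Newton Hessian of the joint density / 2 (i.e. of minus the log
# posterior), dropping second-order terms the way conditional-estimation
# methods do.
.ctx_hess <- function(f, J, omega, sigma2) {
  crossprod(J * sqrt(1 / (sigma2 * f^2))) + diag(1 / omega, length(omega))
}

# Laplace -2 log marginal likelihood contribution with eta frozen:
# joint -2 log density plus the log-determinant term.
.ctx_nll2 <- function(ctx, dv, omega, sigma2, eta, pieces = FALSE) {
  f0 <- .ctx_pred(ctx, eta)
  J <- .ctx_jac(ctx, eta, f0)
  H <- .ctx_hess(f0, J, omega, sigma2)
  ld <- 2 * sum(log(diag(chol(H))))
  nll2 <- .ctx_g(f0, dv, eta, omega, sigma2) - length(omega) * log(2 * pi) +
    ld
  if (!pieces) return(nll2)
  list(nll2 = nll2, f0 = f0, J = J, H = H, logdet = ld)
}

# Back-compatible flat-argument predictor used by the public objective and
# the prediction helpers elsewhere in the package.
.fast_pred <- function(params, patient, eta, tvec, cmtvec, dose_ug = NULL) {
  ctx <- .make_ctx(params, patient, tvec, cmtvec)
  if (!is.null(dose_ug)) ctx$dose_nmol <- dose_ug * 1000 / params$mw
  keys <- eta_keys(params$agent)
  ev <- setNames(numeric(length(keys)), keys)
  if (!is.null(eta) && length(eta)) ev[names(eta)] <- eta
  .ctx_pred(ctx, unname(ev))
}

#' MAP objective for individual random effects
#'
#' Minus twice the log-posterior (up to a constant) of an individual's eta
#' vector given their non-excluded observations under the proportional
#' residual error model and the lognormal population prior:
#' `sum_j [ (C_obs - C_pred)^2 / (sigma2 C_pred^2) + log(sigma2 C_pred^2) ]
#'  + sum_k eta_k^2 / omega2_k`,
#' with `C_pred` the model prediction under `eta`. The residual variance
#' scales with the prediction (interaction convention).
#'
#' @param eta numeric vector of random effects, in the order of
#'   `names(omega)` (names optional).
#' @param obs observation table (excluded rows are ignored).
#' @param params population `agent_params`.
#' @param patient `patient_record`.
#' @param omega named vector of prior variances (see [omega_default()]).
#' @param sigma2 proportional residual variance.
#' @return Scalar objective value (smaller is better).
#' @export
map_objective <- function(eta, obs, params, patient, omega, sigma2) {
  eta <- setNames(as.numeric(eta), names(omega))
  use <- obs$EXCL == 0 & !is.na(obs$DV)
  prior <- sum(eta^2 / omega)
  if (!any(use)) return(prior)
  f <- .fast_pred(params, patient, eta, obs$TIME[use], obs$CMT[use])
  if (any(f <= 0)) {
    stop("model prediction is zero at an observation time; objective undefined",
         call. = FALSE)
  }
  sum((obs$DV[use] - f)^2 / (sigma2 * f^2) + log(sigma2 * f^2)) + prior
}

#' MAP (posthoc) estimate of individual random effects
#'
#' Minimizes [map_objective()] by multi-start local optimization: a start at
#' eta = 0 (the prior mode) plus four deterministic perturbed starts, each
#' refined with a quasi-Newton run. With sparse data the estimates shrink
#' toward zero, as expected of a posterior mode under the population prior.
#'
#' @inheritParams map_objective
#' @param n_starts number of starts (1 = prior mode only; up to 5).
#' @param reltol relative convergence tolerance on the objective.
#' @return List with `eta` (named vector), `objective`, `converged`
#'   (logical), `n_eval` (function evaluations across starts) and
#'   `start_objectives`.
#' @export
map_estimate <- function(obs, params, patient, omega, sigma2,
                         n_starts = 5, reltol = 1e-6) {
  p <- length(omega)
  alt <- rep_len(c(1, -1), p)
  starts <- list(rep(0, p), rep(0.5, p), rep(-0.5, p), 0.5 * alt, -0.5 * alt)
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  use <- obs$EXCL == 0 & !is.na(obs$DV)
  ctx <- .make_ctx(params, patient, obs$TIME[use], obs$CMT[use])
  dv <- obs$DV[use]
  best <- NULL
  n_eval <- 0L
  objs <- rep(NA_real_, length(starts))
  for (s in seq_along(starts)) {
    fit <- tryCatch(
      .ctx_mode(ctx, dv, omega, sigma2, eta_start = starts[[s]],
                reltol = reltol * 1e-2, iter_max = 200),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_eval <- n_eval + fit$n_eval
    objs[s] <- fit$objective
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(list(eta = setNames(rep(0, p), names(omega)),
                objective = NA_real_, converged = FALSE, n_eval = n_eval,
                start_objectives = objs))
  }
  eta_hat <- setNames(best$eta, names(omega))
  list(eta = eta_hat,
       objective = map_objective(eta_hat, obs, params, patient, omega,
                                 sigma2),
       converged = best$converged,
       n_eval = n_eval, start_objectives = objs)
}

#' Estimate therapeutic fold-difference parameters
#'
#' Population estimation of the multiplicative differences between the
#' therapeutic and diagnostic agents: the uptake folds on `k12` (spleen),
#' `k13` (kidney) and `k14` (tumor), the fold on the tumor degradation rate
#' `k40`, and the therapeutic tumor-volume exponent `eff`. The marginal
#' likelihood over the individual random effects (on `k10` and the binding
#' capacities) is approximated by the Laplace method, with each patient's
#' eta mode profiled at every objective evaluation (warm-started across
#' evaluations) and a Gauss-Newton approximation to the joint-density
#' Hessian. Optimization is on the log scale with an analytically corrected
#' envelope gradient: the frozen-mode derivative plus the log-determinant's
#' reaction to the moving modes via the implicit-function theorem. Omega
#' and sigma2 are held fixed. Approximate standard errors come from the
#' observed information of the outer objective (delta method back to the
#' natural scale).
#'
#' @param obs therapeutic observation table; apply [exclude_early_kidney()]
#'   first.
#' @param cohort the cohort the observations belong to (covariates and
#'   dosing; the true etas are not used).
#' @param ga_params diagnostic population parameters the folds are relative
#'   to.
#' @param omega prior variances for the therapeutic random effects.
#' @param sigma2 proportional residual variance (fixed).
#' @param start named start values for `fold12`, `fold13`, `fold14`,
#'   `fold40`, `eff`.
#' @param fixed_lu therapeutic parameters fixed from external knowledge:
#'   renal excretion `k10` (from a published clearance) and plasma unbound
#'   fraction `fu`.
#' @param compute_se compute standard errors (adds a numerical Hessian of
#'   the outer objective; skip for speed).
#' @param control passed to the outer [stats::nlminb()].
#' @return Object of class `fold_fit`: list with `estimates` (named:
#'   `fold12`, `fold13`, `fold14`, `fold40`, `eff`), `se`, `objective`
#'   (-2 log marginal likelihood, Laplace), `converged`, `etas` (matrix of
#'   per-patient eta modes at the optimum), `n_outer_eval`.
#' @export
estimate_population_folds <- function(obs, cohort,
                                      ga_params = agent_params("diagnostic"),
                                      omega = omega_default("therapeutic"),
                                      sigma2 = 0.1,
                                      start = c(fold12 = 1, fold13 = 1,
                                                fold14 = 1, fold40 = 1,
                                                eff = 1),
                                      fixed_lu = list(k10 = 0.575, fu = 0.57),
                                      compute_se = TRUE,
                                      control = list(rel.tol = 1e-6,
                                                     iter.max = 150)) {
  ids <- vapply(cohort$patients, function(p) p$id, "")
  split_obs <- split(obs, obs$ID)
  use_pat <- which(ids %in% names(split_obs))
  if (length(use_pat) < 5) {
    stop("need therapeutic observations for at least 5 patients", call. = FALSE)
  }
  p_eta <- length(omega)
  nms <- c("fold12", "fold13", "fold14", "fold40", "eff")
  n_eval <- 0L

  pdata <- lapply(use_pat, function(i) {
    oi <- split_obs[[ids[i]]]
    u <- oi$EXCL == 0 & !is.na(oi$DV)
    list(patient = cohort$patients[[i]], t = oi$TIME[u], c = oi$CMT[u],
         y = oi$DV[u])
  })
  cache <- new.env(parent = emptyenv())
  cache$etas <- matrix(0, length(pdata), p_eta)

  theta_lu <- function(theta) {
    v <- exp(theta)
    translate_population(ga_params,
                         fold_parameters(fold12 = v[1], fold13 = v[2],
                                         fold14 = v[3], fold40 = v[4],
                                         eff = v[5]),
                         fixed_lu)
  }
  make_ctxs <- function(theta) {
    lu <- theta_lu(theta)
    lapply(pdata, function(d) .make_ctx(lu, d$patient, d$t, d$c))
  }

  # Profiled Laplace objective: warm-started inner modes, contributions
  # cached for the gradient.
  outer_obj <- function(theta) {
    n_eval <<- n_eval + 1L
    ctxs <- make_ctxs(theta)
    per <- numeric(length(pdata))
    for (j in seq_along(pdata)) {
      fit <- .ctx_mode(ctxs[[j]], pdata[[j]]$y, omega, sigma2,
                       eta_start = cache$etas[j, ])
      cache$etas[j, ] <- fit$eta
      per[j] <- .ctx_nll2(ctxs[[j]], pdata[[j]]$y, omega, sigma2, fit$eta)
    }
    cache$per <- per
    cache$theta <- theta
    sum(per)
  }

  # Gradient of the profiled objective by forward differences. Each side
  # evaluation re-profiles every patient's mode, warm-started from the
  # modes at the base point (without touching the cache), so it costs only
  # a couple of inner iterations per patient. The step is far above the
  # residual noise the inner optimizations leave in the objective;
  # nlminb's internal ~1e-8 differencing would drown in it.
  h_fd <- 1e-3
  profiled_at <- function(theta, etas0) {
    n_eval <<- n_eval + 1L
    ctxs <- make_ctxs(theta)
    tot <- 0
    for (j in seq_along(pdata)) {
      fitj <- .ctx_mode(ctxs[[j]], pdata[[j]]$y, omega, sigma2,
                        eta_start = etas0[j, ], reltol = 1e-9)
      tot <- tot + .ctx_nll2(ctxs[[j]], pdata[[j]]$y, omega, sigma2,
                             fitj$eta)
    }
    tot
  }
  outer_grad <- function(theta) {
    if (is.null(cache$theta) || !identical(cache$theta, theta)) {
      outer_obj(theta)
    }
    f0 <- sum(cache$per)
    etas0 <- cache$etas
    vapply(seq_along(theta), function(k) {
      tk <- theta
      tk[k] <- tk[k] + h_fd
      (profiled_at(tk, etas0) - f0) / h_fd
    }, 0)
  }

  theta0 <- log(unname(start[nms]))
  th_lo <- rep(log(0.01), 5)
  th_hi <- c(rep(log(50), 4), log(10))
  fit <- nlminb(theta0, outer_obj, gradient = outer_grad,
                lower = th_lo, upper = th_hi, control = control)
  for (r in seq_len(2)) {
    if (fit$convergence == 0) break
    refit <- nlminb(fit$par, outer_obj, gradient = outer_grad,
                    lower = th_lo, upper = th_hi, control = control)
    improved <- fit$objective - refit$objective
    fit <- refit
    if (improved < 1e-4 * abs(fit$objective)) break
  }
  est <- setNames(exp(fit$par), nms)

  se <- setNames(rep(NA_real_, 5), nms)
  vcov_log <- NULL
  if (compute_se) {
    Hout <- tryCatch(optimHess(fit$par, outer_obj), error = function(e) NULL)
    if (!is.null(Hout)) {
      # -2 log L Hessian: covariance of theta is 2 * H^(-1)
      vcov_log <- tryCatch(2 * solve(Hout), error = function(e) NULL)
      if (!is.null(vcov_log) && all(diag(vcov_log) > 0)) {
        se <- est * sqrt(diag(vcov_log))   # delta method, log scale
      } else {
        warning("observed information not positive definite; SEs unavailable")
      }
    } else {
      warning("outer Hessian computation failed; SEs unavailable")
    }
  }
  etas <- cache$etas
  dimnames(etas) <- list(ids[use_pat], names(omega))
  structure(list(estimates = est, se = se, objective = fit$objective,
                 converged = fit$convergence == 0, vcov_log = vcov_log,
                 etas = etas, n_outer_eval = n_eval,
                 n_patients = length(use_pat)),
            class = "fold_fit")
}

#' @export
print.fold_fit <- function(x, ...) {
  cat("<fold_fit>", x$n_patients, "patients, -2LL(Laplace) =",
      format(x$objective, digits = 8), "\n")
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 4))
  if (!x$converged) cat("  note: outer optimizer reported false convergence\n")
  invisible(x)
}

#' Container for fold-difference parameters
#'
#' @param fold12,fold13,fold14,fold40 multiplicative therapeutic/diagnostic
#'   differences on the spleen, kidney and tumor uptake rates and the tumor
#'   degradation rate.
#' @param eff therapeutic tumor-volume exponent on `k14`.
#' @param se optional named standard errors.
#' @return Object of class `fold_parameters` (a named list).
#' @export
fold_parameters <- function(fold12 = 0.29, fold13 = 0.49, fold14 = 1.43,
                            fold40 = 0.38, eff = 0.67, se = NULL) {
  f <- c(fold12 = fold12, fold13 = fold13, fold14 = fold14, fold40 = fold40)
  if (any(f <= 0)) stop("fold differences must be positive", call. = FALSE)
  structure(list(fold12 = fold12, fold13 = fold13, fold14 = fold14,
                 fold40 = fold40, eff = eff, se = se),
            class = "fold_parameters")
}
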