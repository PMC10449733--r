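test_that("the early-kidney exclusion rule is precise and idempotent", {
  obs <- data.frame(ID = "P1", AGENT = "therapeutic",
                    TIME = c(0.5, 4, 24, 72, 0.5, 0.5),
                    CMT = c("kidney", "kidney", "kidney", "kidney",
                            "spleen", "tumor"),
                    DV = 1:6, EXCL = 0L, EXCL_REASON = "",
                    stringsAsFactors = FALSE)
  out <- exclude_early_kidney(obs)
  expect_equal(out$EXCL, c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(out$EXCL_REASON[1], "urine signal")
  # non-kidney rows and later kidney rows untouched
  expect_identical(out[-1, c("DV", "TIME", "CMT")],
                   obs[-1, c("DV", "TIME", "CMT")])
  expect_identical(exclude_early_kidney(out), out)
})

test_that("the MAP objective is minimized at the prior mode without data", {
  om <- omega_default("diagnostic")
  empty <- data.frame(ID = character(), AGENT = character(),
                      TIME = numeric(), CMT = character(), DV = numeric(),
                      EXCL = integer(), EXCL_REASON = character())
  ga <- agent_params("diagnostic")
  pat <- test_patient()
  expect_equal(map_objective(rep(0, 5), empty, ga, pat, om, 0.1), 0)
  expect_gt(map_objective(rep(0.1, 5), empty, ga, pat, om, 0.1), 0)
  fit <- map_estimate(empty, ga, pat, om, 0.1, n_starts = 2)
  expect_equal(unname(fit$eta), rep(0, 5), tolerance = 1e-6)
})

test_that("an observation at the population prediction keeps eta small", {
  # With a single record equal to the population prediction the posterior
  # mode is close to, but not exactly at, zero: the interaction term
  # ln(sigma2 C_pred^2) of the objective rewards a slightly lower
  # prediction even at zero residual.
  ga <- agent_params("diagnostic")
  pat <- test_patient()
  prof <- simulate_profile(ga, pat, times = c(0, 0.75))
  obs <- data.frame(ID = "T1", AGENT = "diagnostic", TIME = 0.75,
                    CMT = "tumor", DV = profile_conc(prof, "tumor", 0.75),
                    EXCL = 0L, EXCL_REASON = "")
  om <- omega_default("diagnostic")
  fit <- map_estimate(obs, ga, pat, om, 0.1)
  expect_lt(max(abs(fit$eta)), 0.1)
  expect_lte(fit$objective, map_objective(rep(0, 5), obs, ga, pat, om, 0.1))
})

test_that("rich noiseless sampling recovers the true individual etas", {
  ga <- agent_params("diagnostic")
  pat <- test_patient()
  truth <- c(k10 = 0.2, k12 = -0.4, k13 = 0.5, k14 = -0.3, k15 = 0.25)
  obs <- noiseless_obs(ga, pat, truth, rich_schedule())
  fit <- map_estimate(obs, ga, pat, omega_default("diagnostic"),
                      sigma2 = 1e-4)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$eta - truth)), 0.05)
})

test_that("MAP estimates shrink toward zero as the prior tightens", {
  ga <- agent_params("diagnostic")
  pat <- test_patient()
  truth <- c(k10 = 0, k12 = -0.5, k13 = 0.6, k14 = -0.5, k15 = 0)
  sch <- pat$schedule$diagnostic      # single scan per region
  obs <- noiseless_obs(ga, pat, truth, sch)
  om <- omega_default("diagnostic")
  fit_wide <- map_estimate(obs, ga, pat, om, 0.1)
  fit_tight <- map_estimate(obs, ga, pat, om / 100, 0.1)
  expect_lt(sqrt(sum(fit_tight$eta^2)), sqrt(sum(fit_wide$eta^2)))
  expect_lt(max(abs(fit_tight$eta)), 0.05)
  # sparse-design estimates are shrunk relative to rich-design ones
  fit_rich <- map_estimate(noiseless_obs(ga, pat, truth, rich_schedule()),
                           ga, pat, om, 0.1)
  expect_lt(sqrt(sum(fit_wide$eta^2)), sqrt(sum(fit_rich$eta^2)) + 1e-8)
})

test_that("the joint objective prefers the truth over perturbed etas", {
  ga <- agent_params("diagnostic")
  om <- omega_default("diagnostic")
  set.seed(21)
  wins <- 0
  n <- 30
  for (i in 1:n) {
    truth <- setNames(rnorm(5, 0, sqrt(om)), names(om))
    pat <- test_patient(v4 = runif(1, 20, 200), vtot = runif(1, 210, 600))
    sch <- rich_schedule()
    tgrid <- sort(unique(c(0, sch$time)))
    prof <- simulate_profile(ga, pat, eta = truth, times = tgrid)
    obs <- simulate_observations(prof, sch, sigma2 = 0.05)
    pert <- truth + sqrt(om)
    o_true <- map_objective(truth, obs, ga, pat, om, 0.05)
    o_pert <- map_objective(pert, obs, ga, pat, om, 0.05)
    wins <- wins + (o_true < o_pert)
  }
  expect_gt(wins / n, 0.8)
})

test_that("the Laplace objective is lower at the true folds than at inflated ones", {
  cc <- cohort_config(n_patients = 25)
  co <- sample_cohort(cc, seed = 31)
  ga <- agent_params("diagnostic")
  lu <- translate_population(ga, fold_parameters())
  obs <- exclude_early_kidney(simulate_cohort_observations(co, "therapeutic",
                                                           lu))
  om <- omega_default("therapeutic")
  laplace_at <- function(folds) {
    lu2 <- translate_population(ga, folds)
    tot <- 0
    for (i in seq_along(co$patients)) {
      oi <- obs[obs$ID == co$patients[[i]]$id, ]
      u <- oi$EXCL == 0
      ctx <- theranopk:::.make_ctx(lu2, co$patients[[i]], oi$TIME[u],
                                   oi$CMT[u])
      m <- theranopk:::.ctx_mode(ctx, oi$DV[u], om, 0.1, rep(0, 5))
      tot <- tot + theranopk:::.ctx_nll2(ctx, oi$DV[u], om, 0.1, m$eta)
    }
    tot
  }
  at_truth <- laplace_at(fold_parameters())
  expect_lt(at_truth, laplace_at(fold_parameters(fold12 = 0.29 * 2)))
  expect_lt(at_truth, laplace_at(fold_parameters(fold14 = 1.43 * 2)))
  expect_lt(at_truth, laplace_at(fold_parameters(fold13 = 0.49 / 2)))
  expect_lt(at_truth, laplace_at(fold_parameters(fold40 = 0.38 * 2.5)))
})

test_that("fold estimation validates its inputs", {
  co <- sample_cohort(cohort_config(n_patients = 3), seed = 1)
  obs <- simulate_cohort_observations(co, "therapeutic")
  expect_error(estimate_population_folds(obs, co), "at least 5")
  expect_error(fold_parameters(fold12 = -1), "positive")
})
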