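test_that("mass balance holds across random parameter and dose draws", {
  set.seed(42)
  for (i in 1:6) {
    agent <- sample(c("diagnostic", "therapeutic"), 1)
    params <- agent_params(agent)
    keys <- eta_keys(agent)
    eta <- setNames(rnorm(5, 0, 0.4), keys)
    pat <- test_patient(v4 = runif(1, 10, 200), vtot = runif(1, 210, 640),
                        pep_ga = runif(1, 3, 9.6),
                        pep_lu = runif(1, 132, 178))
    prof <- simulate_profile(params, pat, eta = eta,
                             times = seq(0, 96, by = 0.5))
    expect_lt(prof$mass_defect, 1e-6)
    expect_true(all(prof$occupancy >= 0 - 1e-9))
    expect_true(all(prof$occupancy <= 1 + 1e-9))
    expect_true(all(prof$conc >= 0))
  }
})

test_that("zero dose gives an identically empty system", {
  prof <- simulate_profile(agent_params("therapeutic"), test_patient(),
                           dose_ug = 0, times = seq(0, 24, by = 1))
  expect_true(all(prof$amounts == 0))
  expect_equal(unname(max_occupancy(prof)), rep(0, 4))
})

test_that("disabling saturation reproduces the closed-form linear kinetics", {
  for (agent in c("diagnostic", "therapeutic")) {
    params <- agent_params(agent)
    pat <- test_patient()
    prof <- simulate_profile(params, pat, saturable = FALSE,
                             times = seq(0, 96, by = 0.5))
    ktot <- linear_ktot(params, pat)
    t <- prof$times
    a1_ref <- linear_blood(t, prof$dose_nmol, ktot)
    expect_equal(prof$amounts[, "A1"], a1_ref, tolerance = 1e-6)

    sink <- tumor_sink_factor(params, pat)
    voleff <- tumor_volume_effect(params, pat)
    kin_eff <- c(params$k12 * sink, params$k13, params$k14 * voleff,
                 params$k15, params$k16)
    kdeg <- unname(params$kdeg)
    for (x in 1:5) {
      ref <- linear_tissue(t, prof$dose_nmol, kin_eff[x], kdeg[x], ktot,
                           params$fu)
      expect_equal(prof$amounts[-1, x + 1], ref[-1], tolerance = 1e-5)
    }
  }
})

test_that("adaptive solver matches the fixed-step integrator", {
  set.seed(7)
  out_times <- c(0.5, 2, 8, 24, 48, 72)
  for (i in 1:3) {
    agent <- sample(c("diagnostic", "therapeutic"), 1)
    params <- agent_params(agent)
    eta <- setNames(rnorm(5, 0, 0.3), eta_keys(agent))
    pat <- test_patient(v4 = runif(1, 20, 200), vtot = runif(1, 210, 600))
    prof <- simulate_profile(params, pat, eta = eta, times = out_times)
    rk4 <- simulate_fixed_step(params, pat, eta = eta, times = out_times,
                               dt = 0.005)
    scale <- pmax(abs(rk4), max(abs(rk4)) * 1e-6)
    expect_lt(max(abs(prof$amounts - rk4) / scale), 1e-3)
  }
})

test_that("the derivative field conserves mass and saturates uptake", {
  params <- agent_params("therapeutic")
  pat <- test_patient()
  B4 <- params$bmax[["cmt4"]] * pat$v4_ml / 1000
  state <- c(A1 = 10, A2 = 1, A3 = 0.5, A4 = B4, A5 = 2, A6 = 5,
             excreted = 3, degraded = 1)
  d <- model_rhs(state, 1, params, pat)
  # tumor is exactly full: uptake flux is zero, only degradation remains
  expect_equal(unname(d[["A4"]]), -params$kdeg[["k40"]] * B4)
  # all flows internal: net change is zero without infusion
  expect_equal(sum(d), 0, tolerance = 1e-12)

  # empty blood: tissues decay at their degradation rates
  state0 <- c(A1 = 0, A2 = 1, A3 = 1, A4 = 1, A5 = 1, A6 = 1,
              excreted = 0, degraded = 0)
  d0 <- model_rhs(state0, 1, params, pat)
  expect_equal(unname(d0[2:6]), -unname(params$kdeg) * 1)
  expect_equal(unname(d0[["A1"]]), 0)
  # infusion adds mass at exactly the infusion rate
  di <- model_rhs(state0, 0.5, params, pat, infusion_rate = 4,
                  infusion_dur = 1)
  expect_equal(sum(di), 4, tolerance = 1e-12)
})

test_that("occupancy peaks and then decreases for the therapeutic agent", {
  prof <- simulate_profile(agent_params("therapeutic"), test_patient())
  occ <- prof$occupancy
  for (rg in colnames(occ)) {
    pk <- which.max(occ[, rg])
    expect_true(all(diff(occ[pk:nrow(occ), rg]) <= 1e-9))
  }
  # doubling receptor capacity at fixed dose strictly lowers peak occupancy
  p2 <- agent_params("therapeutic",
                     bmax = c(cmt2 = 33.4, cmt3 = 13.4, cmt4 = 60,
                              cmt5 = 4.8))
  prof2 <- simulate_profile(p2, test_patient())
  expect_true(all(max_occupancy(prof2) < max_occupancy(prof)))
})

test_that("infusion administration conserves mass and delays uptake", {
  pat <- test_patient(dur_lu = 1)
  prof <- simulate_profile(agent_params("therapeutic"), pat,
                           times = seq(0, 48, by = 0.25))
  expect_lt(prof$mass_defect, 1e-6)
  # blood amount rises during the infusion
  expect_gt(prof$amounts[which(prof$times == 0.75), "A1"],
            prof$amounts[which(prof$times == 0.25), "A1"])
  bolus <- simulate_profile(agent_params("therapeutic"), test_patient(),
                            times = seq(0, 48, by = 0.25))
  expect_equal(unname(bolus$amounts[1, "A1"]), bolus$dose_nmol)
})

test_that("profile accessors interpolate and validate their inputs", {
  prof <- simulate_profile(agent_params("diagnostic"), test_patient(),
                           times = seq(0, 4, by = 0.5))
  expect_equal(profile_conc(prof, "kidney", c(0.5, 1)),
               prof$conc[c(2, 3), "kidney"])
  expect_error(profile_conc(prof, "kidney", 10), "outside")
  expect_error(profile_conc(prof, "femur"))
  expect_error(simulate_profile(agent_params("diagnostic"), test_patient(),
                                times = c(1, 0.5)), "increasing")
})
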