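# Shared fixtures and independent oracles for the test suite.

test_patient <- function(id = "T1", v4 = 80, vtot = 283,
                         pep_ga = 5.23, pep_lu = 151,
                         act_ga = 96, act_lu = 7271, dur_lu = 0) {
  patient_record(id, v4, vtot,
                 dosing = list(
                   diagnostic = list(peptide_ug = pep_ga,
                                     activity_mbq = act_ga, dur_h = 0),
                   therapeutic = list(peptide_ug = pep_lu,
                                      activity_mbq = act_lu,
                                      dur_h = dur_lu)),
                 schedule = list(
                   diagnostic = data.frame(
                     time = 0.75, cmt = c("spleen", "kidney", "tumor")),
                   therapeutic = expand.grid(
                     time = c(0.5, 4, 24, 72),
                     cmt = c("spleen", "kidney", "tumor"),
                     stringsAsFactors = FALSE)))
}

# Closed-form solutions of the linear (saturation-disabled) system:
# blood is mono-exponential, tissues are two-exponential Bateman curves.
linear_ktot <- function(params, patient, eta = NULL) {
  p <- apply_iiv(params, eta)
  sink <- tumor_sink_factor(p, patient)
  voleff <- tumor_volume_effect(p, patient)
  p$k10 + p$fu * (p$k12 * sink + p$k13 + p$k14 * voleff + p$k15 + p$k16)
}

linear_blood <- function(t, dose_nmol, ktot) dose_nmol * exp(-ktot * t)

linear_tissue <- function(t, dose_nmol, kin_eff, kdeg, ktot, fu) {
  fu * kin_eff * dose_nmol * (exp(-kdeg * t) - exp(-ktot * t)) /
    (ktot - kdeg)
}

# rich sampling design used for noiseless recovery checks: all regions,
# with blood restricted to the early phase (it is depleted within hours)
rich_schedule <- function() {
  tissue_t <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 8, 16, 24, 48, 72)
  rbind(expand.grid(time = tissue_t,
                    cmt = c("spleen", "kidney", "tumor"),
                    stringsAsFactors = FALSE),
        data.frame(time = c(0.25, 0.5, 1, 2, 4), cmt = "blood"))
}

# noise-free observation table from a profile at given schedule
noiseless_obs <- function(params, patient, eta, schedule) {
  tgrid <- sort(unique(c(0, schedule$time)))
  prof <- simulate_profile(params, patient, eta = eta, times = tgrid)
  withr_seed_irrelevant <- simulate_observations(prof, schedule, sigma2 = 0)
  withr_seed_irrelevant
}
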