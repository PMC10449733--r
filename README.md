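# theranopk

Semi-physiological population pharmacokinetics and dosimetry for a
theranostic somatostatin-receptor (SSTR) peptide pair.

Neuroendocrine-tumor patients are imaged with a gallium-68 labelled
SSTR-targeting peptide and later treated with its lutetium-177 labelled
analogue. The two agents share the patient's physiology but differ in
peptide amount, renal handling and protein binding, so the diagnostic image
cannot be extrapolated naively to predict the therapeutic dose.
`theranopk` implements that translation as a tested pipeline:

* a six-compartment receptor-saturable model (blood, spleen, kidney, tumor,
  other SSTR organs, rest) shared by both agents, with uptake

  dA_x/dt = k_1x · fu · A_blood · (1 − A_x/B_MAX,x) − k_x0 · A_x,

  lognormal inter-individual variability (P_i = P_pop·e^η), proportional
  residual error, a tumor-sink covariate on spleen uptake
  (k12 · e^(−0.4·V_tot)) and a tumor-volume power on tumor uptake
  (k14 · (V4/80)^eff);
* therapeutic population parameters expressed as fold differences against
  the diagnostic agent (0.29 / 0.49 / 1.43 on spleen/kidney/tumor uptake,
  0.38 on tumor degradation), estimated from sparse data by a
  Laplace-approximate marginal likelihood with profiled random effects;
* MAP ("posthoc") Bayesian estimation of an individual's random effects
  from a single diagnostic scan, translated onto the therapeutic agent's
  receptor capacities and combined with the patient's own dosing and tumor
  volumes to predict therapeutic concentration-time curves;
* MIRD-style dosimetry (time-integrated activity with terminal-slope
  extrapolation, sphere S values, absorbed dose) and relative
  prediction-error (RPE) evaluation of individual versus population
  predictions;
* a virtual-patient generator reproducing the study design (9-patient
  cohorts, one diagnostic scan at 0.75 h, therapeutic scans at
  0.5/4/24/72 h, printed tumor-volume and dose distributions), with a
  switch between shared and independent latent physiology across agents.

## Worked example

A typical patient (tumor compartment 80 mL, total tumor burden 283 mL,
151 µg / 7271 MBq therapeutic administration):

```r
library(theranopk)
pat <- patient_record("P001", v4_ml = 80, vtot_ml = 283,
  dosing = list(diagnostic  = list(peptide_ug = 5.23, activity_mbq = 96),
                therapeutic = list(peptide_ug = 151, activity_mbq = 7271)))
prof <- simulate_profile(agent_params("therapeutic"), pat)
round(max_occupancy(prof), 3)
#>     spleen     kidney      tumor sstr_other
#>      0.480      0.884      0.936      0.998

sa <- 7271 / 151                       # specific activity, MBq/ug
dose_report(prof, "tumor", sa, mass_kg = tumor_mass_kg(80), t_last = 72)
#>   region auc_0_tlast tia_mbqh tail_fraction  s_value dose_gy
#> 1  tumor        2569    19431          0.56 0.001016   19.74
```

The 151 µg administration saturates 94% of the tumor's binding sites at
its peak (spleen 48%, kidney 88% — inside the clinically reported ranges),
the tumor AUC to 72 h is 2.57 mg·h/L and the absorbed tumor dose 19.7 Gy,
both in the middle of the reported patient tables. The `tail_fraction`
column says 56% of the dose comes from extrapolation beyond the last scan —
a deliberate reminder of how extrapolation-sensitive absorbed doses are.

Individualization from a diagnostic scan and comparison against the
population prediction:

```r
cohort <- sample_cohort(cohort_config(n_patients = 9), seed = 1)
run <- run_pipeline(pipeline_config(), seed = 1)   # simulate -> fit ->
head(run$rpe)                                      # predict -> dose -> RPE
```

The worked-example table of observed/predicted tumor and kidney AUCs and
doses for a published nine-patient cohort ships with the package
(`example_predictions()`), and `rpe_reported()` reproduces its printed
integer RPEs, e.g. −11% for a tumor AUC of 2.95 predicted against
3.32 mg·h/L observed.

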