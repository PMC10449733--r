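#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end workflow: cohort generation,
#' population fold differences, fixed therapeutic parameters, estimation
#' settings, dosimetry constants and the simulation grid. Any block can be
#' overridden by a YAML file (see [read_pipeline_config()]).
#'
#' @return Nested list of configuration blocks.
#' @export
pipeline_config <- function() {
  list(
    cohort = list(n_patients = 9, sigma2 = 0.1, eta_mode = "shared"),
    folds = list(fold12 = 0.29, fold13 = 0.49, fold14 = 1.43,
                 fold40 = 0.38, eff = 0.67),
    fixed_lu = list(k10 = 0.575, fu = 0.57),
    estimation = list(n_starts = 5, sigma2 = 0.1),
    dosimetry = list(half_life_h = 159.53, delta_j = 2.37e-14,
                     density_g_cm3 = 1.05, kidney_mass_kg = 0.31),
    grid = list(t_end = 96, dt = 0.1)
  )
}

.REQUIRED_CONFIG <- c("cohort.n_patients", "cohort.sigma2", "cohort.eta_mode",
                      "folds.fold12", "folds.fold13", "folds.fold14",
                      "folds.fold40", "folds.eff")

#' Read and validate a pipeline configuration file
#'
#' YAML file mirroring [pipeline_config()]. Required fields (cohort sizes,
#' residual variance, eta mode, all fold differences) must be present;
#' missing fields raise an error naming the field. Optional blocks fall
#' back to the defaults.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in .REQUIRED_CONFIG) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (is.null(v)) stop("config is missing required field: ", key,
                         call. = FALSE)
  }
  if (!cfg$cohort$eta_mode %in% c("shared", "independent")) {
    stop("config field cohort.eta_mode must be 'shared' or 'independent'",
         call. = FALSE)
  }
  def <- pipeline_config()
  for (blk in names(def)) {
    if (is.null(cfg[[blk]])) cfg[[blk]] <- def[[blk]]
    else for (f in names(def[[blk]])) {
      if (is.null(cfg[[blk]][[f]])) cfg[[blk]][[f]] <- def[[blk]][[f]]
    }
  }
  cfg
}

.cfg_folds <- function(config) {
  fold_parameters(fold12 = config$folds$fold12, fold13 = config$folds$fold13,
                  fold14 = config$folds$fold14, fold40 = config$folds$fold40,
                  eff = config$folds$eff)
}

.cfg_nuclide <- function(config) {
  nuclide_lu177(half_life_h = config$dosimetry$half_life_h,
                delta_j = config$dosimetry$delta_j)
}

#' Run the full analysis workflow
#'
#' Chains the stages of the study workflow on a synthetic cohort:
#' simulate (cohort covariates, true etas, noisy diagnostic and therapeutic
#' observations), fit (MAP etas per patient from the diagnostic
#' observations), predict (individual and population therapeutic profiles),
#' dose (model-based and observed-trapezoid TIA and absorbed dose for
#' kidney and tumor), evaluate (AUC and dose RPE tables, the
#' individual-versus-population comparison, goodness-of-fit summaries).
#' All randomness derives from `seed`; a provenance file (config hash,
#' seed, package version) makes any run reproducible.
#'
#' @param config configuration list (see [pipeline_config()]).
#' @param seed integer seed.
#' @param outdir output directory (created if needed); all stage outputs
#'   are written there as tab-delimited text and JSON.
#' @return Invisibly, a list with the in-memory stage results: `cohort`,
#'   `obs_ga`, `obs_lu`, `map_fits`, `rpe` (data.frame), `comparison`,
#'   `gof`, `dose` (data.frame), `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         outdir = tempfile("theranopk_run_")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)

  ## --- simulate -----------------------------------------------------
  cc <- cohort_config(n_patients = config$cohort$n_patients,
                      sigma2 = config$cohort$sigma2,
                      eta_mode = config$cohort$eta_mode)
  cohort <- sample_cohort(cc, seed = seed)
  ga_params <- agent_params("diagnostic")
  folds <- .cfg_folds(config)
  lu_params <- translate_population(ga_params, folds, config$fixed_lu)
  obs_ga <- simulate_cohort_observations(cohort, "diagnostic", ga_params)
  obs_lu <- simulate_cohort_observations(cohort, "therapeutic", lu_params)
  obs_lu <- exclude_early_kidney(obs_lu)
  write_cohort_covariates(cohort, fp("covariates.tsv"))
  write_observations(obs_ga, fp("obs_diagnostic.tsv"))
  write_observations(obs_lu, fp("obs_therapeutic.tsv"))
  true_etas <- do.call(rbind, lapply(seq_along(cohort$patients), function(i) {
    data.frame(ID = cohort$patients[[i]]$id,
               t(cohort$etas[[i]]$diagnostic))
  }))
  write.table(true_etas, fp("true_etas_diagnostic.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## --- fit: MAP etas from diagnostic observations -------------------
  om_ga <- omega_default("diagnostic")
  map_fits <- lapply(seq_along(cohort$patients), function(i) {
    pat <- cohort$patients[[i]]
    map_estimate(obs_ga[obs_ga$ID == pat$id, ], ga_params, pat,
                 om_ga, config$estimation$sigma2,
                 n_starts = config$estimation$n_starts)
  })
  eta_hat <- do.call(rbind, lapply(map_fits, function(f) t(f$eta)))
  eta_tab <- data.frame(ID = vapply(cohort$patients, function(p) p$id, ""),
                        eta_hat,
                        converged = vapply(map_fits, function(f) f$converged,
                                           TRUE))
  write.table(eta_tab, fp("map_etas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## --- predict + dose + evaluate ------------------------------------
  tgrid <- seq(0, config$grid$t_end, by = config$grid$dt)
  nuc <- .cfg_nuclide(config)
  rpe_rows <- list(); dose_rows <- list(); pred_rows <- list()
  for (i in seq_along(cohort$patients)) {
    pat <- cohort$patients[[i]]
    obs_i <- obs_lu[obs_lu$ID == pat$id, ]
    prof_ind <- predict_individual(pat, map_fits[[i]]$eta, folds, tgrid,
                                   ga_params, config$fixed_lu)
    prof_pop <- population_predict(pat, folds, tgrid, ga_params,
                                   config$fixed_lu)
    sa <- pat$dosing$therapeutic$activity_mbq /
      pat$dosing$therapeutic$peptide_ug
    for (rg in unique(obs_i$CMT)) {
      o_rg <- obs_i[obs_i$CMT == rg & obs_i$EXCL == 0, ]
      if (nrow(o_rg) < 2) next
      t1 <- min(o_rg$TIME); t2 <- max(o_rg$TIME)
      a_obs <- auc_observed(obs_i, rg)
      a_ind <- auc_model(prof_ind, rg, t2) - auc_model(prof_ind, rg, t1)
      a_pop <- auc_model(prof_pop, rg, t2) - auc_model(prof_pop, rg, t1)
      row <- data.frame(id = pat$id, region = rg, quantity = "auc",
                        observed = a_obs, individual = a_ind,
                        population = a_pop,
                        rpe_individual = rpe(a_ind, a_obs),
                        rpe_population = rpe(a_pop, a_obs))
      rpe_rows[[length(rpe_rows) + 1]] <- row

      if (rg %in% c("kidney", "tumor")) {
        vol_l <- if (rg == "tumor") pat$v4_ml / 1000 else
          ga_params$V[["V3"]]
        mass <- if (rg == "tumor") {
          tumor_mass_kg(pat$v4_ml, config$dosimetry$density_g_cm3)
        } else config$dosimetry$kidney_mass_kg
        s <- sphere_s_value(mass, nuc)
        d_ind <- absorbed_dose(tia(prof_ind, rg, sa, nuc)$tia, s)
        d_pop <- absorbed_dose(tia(prof_pop, rg, sa, nuc)$tia, s)
        d_obs <- tryCatch(
          absorbed_dose(tia_observed(obs_i, rg, vol_l, sa, nuc)$tia, s),
          error = function(e) NA_real_)
        dose_rows[[length(dose_rows) + 1]] <-
          data.frame(id = pat$id, region = rg, s_value = s,
                     dose_obs_gy = d_obs, dose_ind_gy = d_ind,
                     dose_pop_gy = d_pop)
        if (is.finite(d_obs) && d_obs > 0) {
          rpe_rows[[length(rpe_rows) + 1]] <-
            data.frame(id = pat$id, region = rg, quantity = "dose",
                       observed = d_obs, individual = d_ind,
                       population = d_pop,
                       rpe_individual = rpe(d_ind, d_obs),
                       rpe_population = rpe(d_pop, d_obs))
        }
      }
    }
    pr <- obs_i
    pr$PRED_IND <- vapply(seq_len(nrow(pr)), function(j)
      profile_conc(prof_ind, pr$CMT[j], pr$TIME[j]), 0)
    pr$PRED_POP <- vapply(seq_len(nrow(pr)), function(j)
      profile_conc(prof_pop, pr$CMT[j], pr$TIME[j]), 0)
    pred_rows[[i]] <- pr
  }
  rpe_tab <- do.call(rbind, rpe_rows)
  dose_tab <- do.call(rbind, dose_rows)
  pred_tab <- do.call(rbind, pred_rows)
  write.table(rpe_tab, fp("rpe.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dose_tab, fp("dose.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pred_tab, fp("predictions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  auc_pairs <- rpe_tab[rpe_tab$quantity == "auc",
                       c("id", "region", "rpe_individual", "rpe_population")]
  comparison <- compare_individual_vs_population(auc_pairs)
  gof <- gof_summary(pred_tab, pred_tab$PRED_IND)
  write.table(comparison$comparison, fp("comparison.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gof, fp("gof.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## --- provenance ---------------------------------------------------
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_path <- fp("config.json")
  writeLines(cfg_json, cfg_path)
  prov <- list(seed = seed,
               config_md5 = unname(tools::md5sum(cfg_path)),
               package_version =
                 as.character(utils::packageVersion("theranopk")),
               n_patients = length(cohort$patients))
  jsonlite::write_json(prov, fp("provenance.json"), auto_unbox = TRUE)

  invisible(list(cohort = cohort, obs_ga = obs_ga, obs_lu = obs_lu,
                 map_fits = map_fits, rpe = rpe_tab,
                 comparison = comparison, gof = gof, dose = dose_tab,
                 files = list.files(outdir, full.names = TRUE),
                 outdir = outdir))
}
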