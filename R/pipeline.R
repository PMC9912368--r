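# End-to-end drivers: cohort assembly from module outputs, and a demo
# pipeline running simulate -> events -> biomarkers -> cohort -> covariates
# -> imputation -> pooled stepwise Cox -> risk prediction on synthetic data.

#' Assemble a refined cohort from module outputs
#'
#' Chains [build_initial_tte()], [refine_tte()] and
#' [apply_prospective_design()].
#'
#' @param dm_assignments,outcome_first_occurrence,censor_info,index_dates,has_primary_care
#'   see [build_initial_tte()].
#' @param exclusion_events see [refine_tte()].
#' @param external_outcome_ids see [apply_prospective_design()].
#' @param outcome one of [COHORT_OUTCOMES].
#' @param config a [cohort_config()].
#' @return the refined time-to-event `data.table`.
#' @export
build_cohort <- function(dm_assignments, outcome_first_occurrence,
                         exclusion_events, censor_info, index_dates,
                         has_primary_care, external_outcome_ids,
                         outcome, config = cohort_config(outcome)) {
  tte <- build_initial_tte(dm_assignments, outcome_first_occurrence,
                           censor_info, index_dates, outcome,
                           has_primary_care = has_primary_care)
  tte <- refine_tte(tte, exclusion_events)
  apply_prospective_design(tte, config,
                           external_outcome_ids = external_outcome_ids)
}

#' Run the full demo pipeline on synthetic data
#'
#' Generates a synthetic input bundle and runs every pipeline stage for one
#' complication outcome: event consolidation and date cleaning, diabetes
#' classification, outcome first occurrences, cohort construction with all
#' exclusion rules, incidence rate, landmark biomarker summaries, covariate
#' panel assembly, multiple imputation, pooled stepwise Cox selection and
#' 2:1 train/validation risk prediction. Deterministic given `seed`.
#'
#' @param n number of synthetic participants.
#' @param seed master seed; stage seeds are derived from it.
#' @param outcome one of [COHORT_OUTCOMES].
#' @param m number of imputed datasets.
#' @param config optional [sim_config()] override (its `n`/`seed` are set
#'   from the arguments).
#' @return list with `sim`, `cohort`, `exclusions`, `incidence`, `panel`,
#'   `imputation`, `selection`, `prediction`.
#' @export
run_demo_pipeline <- function(n = 600L, seed = 1L, outcome = "DKD", m = 3L,
                              config = NULL) {
  cfg <- config %||% sim_config()
  cfg$n <- as.integer(n)
  cfg$seed <- as.integer(seed)
  sim <- generate_cohort(cfg)

  ## events ---------------------------------------------------------------
  field_map <- data.table::data.table(
    code_field = "sr_illness_1", date_field = "sr_illness_1_date",
    source = "SELF_REPORT", system = "SELF_REPORT_ILLNESS",
    code = NA_character_)
  master <- build_master_event_table(sim$assessment, sim$hospital, sim$death,
                                     field_map)
  gp_ev <- as_event_records(sim$gp_clinical)
  births <- sim$assessment[, list(
    participant_id,
    birth_date = as.Date(sprintf("%04d-%02d-01", birth_year, birth_month)))]
  master <- clean_dates(master, births)
  gp_ev <- clean_dates(gp_ev, births)

  ## diabetes -------------------------------------------------------------
  dm_cl <- sim$codelists$DM
  dm_ev <- merge_outcome_events(extract_outcome_events(master, dm_cl),
                                extract_outcome_events(gp_ev, dm_cl))
  dm_assign <- classify_diabetes(dm_ev, fixture_dm_type_codes())

  ## outcome events -------------------------------------------------------
  oc_cl <- sim$codelists[[outcome]]
  oc_ev <- merge_outcome_events(
    extract_outcome_events(master, oc_cl, roles = "DEFINING"),
    extract_outcome_events(gp_ev, oc_cl, roles = "DEFINING"))
  oc_fo <- first_occurrence(oc_ev, outcome_id = outcome,
                            role_filter = "DEFINING")
  has_excl_roles <- any(oc_cl$role == "EXCLUSION")
  excl_ev <- if (has_excl_roles) {
    rbind(extract_outcome_events(master, oc_cl, roles = "EXCLUSION"),
          extract_outcome_events(gp_ev, oc_cl, roles = "EXCLUSION"))
  } else NULL
  external_ids <- unique(oc_ev[source %in% c("HOSPITAL", "DEATH"),
                               participant_id])

  ## censoring and linkage ------------------------------------------------
  death_dates <- if (nrow(sim$death)) {
    sim$death[, list(death_date = min(as_date_col(date))),
              by = "participant_id"]
  } else NULL
  censor_info <- sim$assessment[, list(participant_id,
                                       lost = lost_to_followup_date)]
  if (!is.null(death_dates)) {
    censor_info[death_dates, dd := i.death_date, on = "participant_id"]
  } else censor_info[, dd := as.Date(NA)]
  censor_info[, censor_date := compute_censor_date(
    lost, dd, rep(as.Date(cfg$admin_censor_date), .N))]
  censor_info <- censor_info[, list(participant_id, censor_date)]
  has_pc <- data.table::data.table(
    participant_id = sim$assessment$participant_id,
    has_primary_care = sim$assessment$participant_id %in%
      unique(sim$gp_clinical$participant_id))
  index_dates <- sim$assessment[, list(participant_id, index_date)]

  ## cohort ---------------------------------------------------------------
  cohort <- build_cohort(dm_assign, oc_fo, excl_ev, censor_info, index_dates,
                         has_pc, external_ids, outcome)
  rate <- incidence_rate(cohort)

  ## biomarkers over the landmark window ----------------------------------
  gp_vals <- sim$gp_clinical[!is.na(value)]
  traj <- extract_trajectories(gp_vals, NULL, fixture_biomarker_code_map(),
                               fixture_unit_rules())
  traj <- traj[biomarker %in% c("SBP", "DBP", "GLUCOSE", "HBA1C",
                                "TOTAL_CHOL", "HDL")]
  gp_first <- sim$gp_clinical[, list(gp_first = min(as_date_col(date))),
                              by = "participant_id"]
  windows <- merge(index_dates, gp_first, by = "participant_id", all.x = TRUE)
  windows[, window_start := data.table::fifelse(is.na(gp_first), index_date,
                                                pmin(gp_first, index_date))]
  windows[, window_end := index_date + SIX_MONTHS_DAYS]
  summaries <- summarize_landmark(traj,
                                  windows[, list(participant_id, window_start,
                                                 window_end)])

  ## covariate panel ------------------------------------------------------
  retained <- cohort[excluded == FALSE]
  cci <- compute_cci(sim$hospital, index_dates,
                     participants = retained$participant_id)
  a <- sim$assessment
  demographics <- a[, list(
    participant_id, sex, birth_year, birth_month, bmi, ever_smoked,
    smoking_pack_years, insulin, bp_med, chol_med,
    ethnicity = recode_ethnicity(ethnicity_code),
    met_hours_week = compute_met(walk_days, walk_min, moderate_days,
                                 moderate_min, vigorous_days, vigorous_min),
    isced_gt2 = compute_isced(qualification)$isced_gt2)]
  panel <- assemble_panel(retained, demographics,
                          covariate_pieces = list(cci = cci),
                          biomarker_summaries = summaries)

  ## analysis -------------------------------------------------------------
  model_cols <- c("participant_id", "time_years", "status", "age_at_index",
                  "sex", "bmi", "ever_smoked", "cci", "met_hours_week",
                  "mean_sbp", "mean_glucose", "cv_sbp")
  model_cols <- intersect(model_cols, names(panel))
  imp <- impute(panel[, model_cols, with = FALSE], m = m,
                seed = cfg$seed + 1L)
  candidates <- intersect(c("bmi", "ever_smoked", "cci", "met_hours_week",
                            "mean_sbp", "mean_glucose", "cv_sbp"), model_cols)
  std <- intersect(c("met_hours_week", "cv_sbp"), candidates)
  selection <- pooled_stepwise_select(imp, forced = c("age_at_index", "sex"),
                                      candidates = candidates,
                                      standardize = std)
  prediction <- run_risk_prediction(imp, forced = c("age_at_index", "sex"),
                                    candidates = candidates,
                                    split_seed = cfg$seed + 2L,
                                    standardize = std)
  list(sim = sim, cohort = cohort, exclusions = exclusion_summary(cohort),
       incidence = rate, panel = panel, imputation = imp,
       selection = selection, prediction = prediction)
}
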