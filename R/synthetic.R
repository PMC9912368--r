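# Synthetic data generator: UKB-shaped input tables (terminology
# dictionaries, primary-care clinical events, hospital admissions, death
# records, assessment table, seed codelists) with planted ground truth, so
# every pipeline stage is testable without access to restricted data.
# Complication onsets follow a proportional-hazards model with known
# coefficients; an independent rule evaluator predicts the expected retained
# cohort directly from the ground truth.

#' Simulation configuration
#'
#' Defaults encode the stated world the generator emulates: ~45% of
#' participants have linked primary-care records; recruitment spans
#' 2006-2010 with ages 40-70 at entry; hospital data run to 2018-02-28 and
#' primary-care data to 2017-12-31; complication hazards are
#' `h0 * exp(x'beta)` with baseline rates per person-year matching incidence
#' on the order of 16/46/72 per 1000 person-years for the three fixture
#' complications. Diabetes is strongly enriched (default prevalence 0.5)
#' because the pipeline operates on the diabetic sub-cohort and desk-scale
#' runs must keep it populated.
#'
#' @param n number of participants.
#' @param seed RNG seed (mandatory at generation time).
#' @param primary_care_linkage_prob probability of linked primary care.
#' @param dm_prevalence probability of diabetes.
#' @param t1d_fraction,t2d_fraction diabetes type mix (rest carry only
#'   generic codes and classify as UNCERTAIN).
#' @param beta named log-hazard-ratio vector over `age` (years, centred 60),
#'   `sex_male`, `bmi` (centred 30) and `mean_sbp` (mmHg, centred 140).
#' @param baseline_hazard named per-outcome baseline rates (events per
#'   person-year at the reference covariates).
#' @param admin_censor_date,pc_censor_date administrative cut-offs.
#' @param lost_prob,death_prob probabilities of loss to follow-up / death.
#' @param dm_onset_mean_years mean of the exponential diabetes-onset lag
#'   before the index date.
#' @param dm_late_prob probability that diabetes onset falls after the
#'   landmark window (plants `dm_after_landmark` violations).
#' @param pre_dm_event_prob probability that a complication event is moved
#'   before diabetes onset (plants `event_before_dm` violations).
#' @param exclusion_plant_prob probability of carrying a risk-set
#'   exclusion-coded event (DKD/DR).
#' @param visit_rate_per_year Poisson visit intensity for primary-care
#'   biomarker measurements.
#' @param placeholder_rate fraction of biomarker rows whose date is replaced
#'   by an administrative placeholder date.
#' @param missing_rate MCAR missingness rate for assessment covariates.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 2000L, seed = NULL,
                       primary_care_linkage_prob = 0.45,
                       dm_prevalence = 0.5,
                       t1d_fraction = 0.02, t2d_fraction = 0.80,
                       beta = c(age = 0.05, sex_male = 0.7,
                                bmi = 0.03, mean_sbp = 0.01),
                       baseline_hazard = c(CVD = 0.0163, DKD = 0.0462,
                                           DR = 0.0718),
                       admin_censor_date = "2018-02-28",
                       pc_censor_date = "2017-12-31",
                       lost_prob = 0.02, death_prob = 0.04,
                       dm_onset_mean_years = 6, dm_late_prob = 0.05,
                       pre_dm_event_prob = 0.03,
                       exclusion_plant_prob = 0.03,
                       visit_rate_per_year = 1.5,
                       placeholder_rate = 0.01,
                       missing_rate = 0.15) {
  probs <- c(primary_care_linkage_prob, dm_prevalence, t1d_fraction,
             t2d_fraction, lost_prob, death_prob, dm_late_prob,
             pre_dm_event_prob, exclusion_plant_prob, placeholder_rate,
             missing_rate)
  stopifnot(all(probs >= 0 & probs <= 1), t1d_fraction + t2d_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# population biomarker models: subject mean ~ N(mean, between_sd), value at
# time t (years from index) = subject mean + slope * t + N(0, within_sd)
SYN_BIOMARKER_MODELS <- data.table::data.table(
  biomarker = c("SBP", "DBP", "GLUCOSE", "HBA1C", "TOTAL_CHOL", "HDL", "LDL",
                "TRIG", "SERUM_CREATININE", "URINE_ALBUMIN",
                "URINE_CREATININE"),
  mean = c(140, 82, 7.5, 52, 4.6, 1.2, 2.7, 1.9, 75, 25, 9),
  between_sd = c(15, 8, 1.5, 8, 0.7, 0.2, 0.5, 0.6, 12, 15, 2.5),
  slope = c(0.3, -0.1, 0.05, 0.3, -0.02, 0, -0.01, 0.01, 0.5, 1.5, 0),
  within_sd = c(8, 6, 1.2, 4, 0.4, 0.12, 0.3, 0.4, 6, 8, 1.5))

syn_gp_row <- function(id, date, system, code, value = NA_real_,
                       unit = NA_character_) {
  data.table::data.table(participant_id = id, date = as.Date(date),
                         system = system, code = code, value = value,
                         unit = unit)
}

#' Generate a full synthetic input bundle with ground truth
#'
#' Produces the six input tables the pipeline consumes (terminology
#' dictionary, primary-care clinical events, hospital admissions, death
#' records, assessment table, seed codelists) plus a ground-truth table
#' sufficient for an independent rule evaluator ([expected_cohort()]) to
#' predict the retained cohort and exclusion reasons exactly. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()]; `seed` must be set.
#' @return list with elements `dictionary`, `gp_clinical`, `hospital`,
#'   `death`, `assessment`, `codelists` (named list of fixture codelists) and
#'   `truth` (per-participant ground truth, with `beta`/`baseline_hazard`
#'   attributes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  set.seed(as.integer(config$seed))
  n <- as.integer(config$n)
  admin <- as.Date(config$admin_censor_date)
  pc_end <- as.Date(config$pc_censor_date)
  ids <- sprintf("P%05d", seq_len(n))

  ## demographics and administrative dates -------------------------------
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.55, 0.45))
  birth_year <- sample(1937:1968, n, replace = TRUE)
  birth_month <- sample(1:12, n, replace = TRUE)
  index_date <- as.Date("2006-03-01") +
    round(stats::runif(n, 0, as.numeric(as.Date("2010-07-01") - as.Date("2006-03-01"))))
  age_at_index <- as.numeric(index_date -
                               as.Date(sprintf("%04d-%02d-15", birth_year, birth_month))) /
    DAYS_PER_YEAR
  ethnicity_code <- sample(c(1001L, 1002L, 2001L, 3001L, 3002L, 4001L, 4002L,
                             5L, 6L, -3L), n, replace = TRUE,
                           prob = c(0.55, 0.2, 0.03, 0.05, 0.03, 0.04, 0.02,
                                    0.02, 0.03, 0.03))
  has_pc <- stats::runif(n) < config$primary_care_linkage_prob
  gp_start <- index_date - round(stats::runif(n, 2, 15) * DAYS_PER_YEAR)

  died <- stats::runif(n) < config$death_prob
  death_date <- as.Date(rep(NA, n))
  death_date[died] <- index_date[died] +
    round(stats::runif(sum(died), 1, 10) * DAYS_PER_YEAR)
  died <- died & !is.na(death_date) & death_date <= admin
  death_date[!died] <- NA
  lost <- stats::runif(n) < config$lost_prob & !died
  lost_date <- as.Date(rep(NA, n))
  lost_date[lost] <- index_date[lost] +
    round(stats::runif(sum(lost), 1, 8) * DAYS_PER_YEAR)
  lost_date[lost & lost_date > admin] <- NA
  censor_date <- compute_censor_date(lost_date, death_date,
                                     rep(admin, n))

  ## diabetes ------------------------------------------------------------
  dm <- stats::runif(n) < config$dm_prevalence
  dm_type <- rep(NA_character_, n)
  u <- stats::runif(n)
  dm_type[dm] <- data.table::fcase(
    u[dm] < config$t1d_fraction, "T1D",
    u[dm] < config$t1d_fraction + config$t2d_fraction, "T2D",
    default = "UNCERTAIN")
  dm_onset <- as.Date(rep(NA, n))
  late <- dm & stats::runif(n) < config$dm_late_prob
  early <- dm & !late
  dm_onset[early] <- index_date[early] -
    round(stats::rexp(sum(early), 1 / config$dm_onset_mean_years) * DAYS_PER_YEAR)
  dm_onset[late] <- index_date[late] +
    round(stats::runif(sum(late), 0.6, 3) * DAYS_PER_YEAR)
  # onset no earlier than age 20
  floor20 <- as.Date(sprintf("%04d-%02d-15", birth_year + 20, birth_month))
  dm_onset[dm] <- pmax(dm_onset[dm], floor20[dm])

  ## latent covariates ---------------------------------------------------
  bmi <- round(stats::rnorm(n, 31, 4.5), 1)
  bm <- SYN_BIOMARKER_MODELS
  subj_mean <- sapply(seq_len(nrow(bm)), function(i)
    stats::rnorm(n, bm$mean[i], bm$between_sd[i]))
  colnames(subj_mean) <- bm$biomarker
  # non-diabetics have lower glycaemia
  subj_mean[!dm, "GLUCOSE"] <- subj_mean[!dm, "GLUCOSE"] - 2.2
  subj_mean[!dm, "HBA1C"] <- subj_mean[!dm, "HBA1C"] - 14

  ## complication events (proportional hazards from the index date) ------
  beta <- config$beta
  lp <- beta[["age"]] * (age_at_index - 60) +
    beta[["sex_male"]] * (sex == "male") +
    beta[["bmi"]] * (bmi - 30) +
    beta[["mean_sbp"]] * (subj_mean[, "SBP"] - 140)
  outcomes <- names(config$baseline_hazard)
  ev <- list()
  for (oc in outcomes) {
    rate <- config$baseline_hazard[[oc]] * exp(lp)
    t_years <- stats::rexp(n, rate)
    latent_date <- index_date + round(t_years * DAYS_PER_YEAR)
    event_date <- as.Date(rep(NA, n))
    rec <- dm & latent_date <= admin
    event_date[rec] <- latent_date[rec]
    # plant some pre-diabetes complication events
    pre <- dm & stats::runif(n) < config$pre_dm_event_prob
    event_date[pre] <- dm_onset[pre] -
      round(stats::runif(sum(pre), 0.5, 3) * DAYS_PER_YEAR)
    # recording source: CVD always hospital; DKD/DR via primary care when
    # linked and within the primary-care window, else hospital
    external <- !is.na(event_date) &
      (oc == "CVD" | !has_pc | event_date > pc_end)
    ev[[oc]] <- list(latent_years = t_years, event_date = event_date,
                     external = external)
  }
  excl_dkd <- dm & stats::runif(n) < config$exclusion_plant_prob
  excl_dr <- dm & stats::runif(n) < config$exclusion_plant_prob

  ## encode events into the tables ---------------------------------------
  gp <- list(); hosp <- list()
  dm_codes_gp <- c(T1D = "C108.", T2D = "C109.", UNCERTAIN = "C10..")
  dm_codes_icd <- c(T1D = "E10", T2D = "E11", UNCERTAIN = "E14")
  dm_codes_sr <- c(T1D = "1222", T2D = "1223", UNCERTAIN = "1220")
  dmi <- which(dm)
  dm_in_gp <- dm & has_pc & dm_onset >= gp_start & dm_onset <= pc_end
  if (any(dm_in_gp)) {
    gp[[length(gp) + 1L]] <- syn_gp_row(ids[dm_in_gp], dm_onset[dm_in_gp],
                                        "READ_V2",
                                        dm_codes_gp[dm_type[dm_in_gp]])
  }
  dm_in_hosp <- dm & !dm_in_gp
  if (any(dm_in_hosp)) {
    hosp[[length(hosp) + 1L]] <- data.table::data.table(
      participant_id = ids[dm_in_hosp], date = dm_onset[dm_in_hosp],
      system = "ICD10", code = dm_codes_icd[dm_type[dm_in_hosp]])
  }
  # date-only monitoring codes after onset, for linked diabetics
  mon <- dm_in_gp & stats::runif(n) < 0.6
  if (any(mon)) {
    gp[[length(gp) + 1L]] <- syn_gp_row(
      ids[mon], dm_onset[mon] + round(stats::runif(sum(mon), 30, 400)),
      "READ_V2", "66A..")
  }
  # self-report at assessment (only when onset precedes the index date,
  # mirroring recall of a pre-existing diagnosis)
  sr <- dm & dm_onset <= index_date & stats::runif(n) < 0.5
  sr_code <- ifelse(sr, dm_codes_sr[dm_type], NA_character_)
  sr_date <- as.Date(ifelse(sr, index_date, NA), origin = "1970-01-01")

  oc_codes <- list(
    CVD = list(hosp = list(system = "ICD10", code = "I21")),
    DKD = list(gp = list(system = "READ_V2", code = "K05.."),
               hosp = list(system = "ICD10", code = "N18")),
    DR = list(gp = list(system = "READ_V2", code = "F420."),
              hosp = list(system = "ICD10", code = "H360")))
  for (oc in outcomes) {
    ed <- ev[[oc]]$event_date
    ext <- ev[[oc]]$external
    rec <- !is.na(ed)
    g <- rec & !ext
    h <- rec & ext
    if (any(g)) {
      gp[[length(gp) + 1L]] <- syn_gp_row(ids[g], ed[g],
                                          oc_codes[[oc]]$gp$system,
                                          oc_codes[[oc]]$gp$code)
    }
    if (any(h)) {
      hosp[[length(hosp) + 1L]] <- data.table::data.table(
        participant_id = ids[h], date = ed[h],
        system = oc_codes[[oc]]$hosp$system, code = oc_codes[[oc]]$hosp$code)
    }
  }
  # planted risk-set exclusion events
  if (any(excl_dkd)) {
    w <- which(excl_dkd)
    d <- index_date[w] + round(stats::runif(length(w), -3, 3) * DAYS_PER_YEAR)
    in_gp <- has_pc[w]
    if (any(in_gp)) {
      gp[[length(gp) + 1L]] <- syn_gp_row(ids[w][in_gp], d[in_gp],
                                          "READ_V2", "K01..")
    }
    if (any(!in_gp)) {
      hosp[[length(hosp) + 1L]] <- data.table::data.table(
        participant_id = ids[w][!in_gp], date = d[!in_gp],
        system = "ICD10", code = "N00")
    }
  }
  if (any(excl_dr)) {
    w <- which(excl_dr)
    d <- index_date[w] + round(stats::runif(length(w), -3, 3) * DAYS_PER_YEAR)
    hosp[[length(hosp) + 1L]] <- data.table::data.table(
      participant_id = ids[w], date = d, system = "ICD10", code = "H353")
  }
  # prior comorbidities feeding the Charlson index (never outcome codes)
  cci_pool <- c("F00", "J44", "K25", "M05", "I50", "C34", "K74")
  n_cci <- stats::rpois(n, 0.5)
  w <- which(n_cci > 0)
  if (length(w)) {
    reps <- n_cci[w]
    hosp[[length(hosp) + 1L]] <- data.table::data.table(
      participant_id = rep(ids[w], reps),
      date = rep(index_date[w], reps) -
        round(stats::runif(sum(reps), 0.5, 10) * DAYS_PER_YEAR),
      system = "ICD10",
      code = sample(cci_pool, sum(reps), replace = TRUE))
  }

  ## primary-care biomarker trajectories ---------------------------------
  linked <- which(has_pc)
  # registration marker so every linked participant appears in gp_clinical
  gp[[length(gp) + 1L]] <- syn_gp_row(ids[linked], gp_start[linked],
                                      "READ_V2", "H33..")
  code_map <- fixture_biomarker_code_map()
  bm_codes <- stats::setNames(code_map$code, code_map$biomarker)
  traj <- list()
  for (i in linked) {
    span_y <- as.numeric(pc_end - gp_start[i]) / DAYS_PER_YEAR
    nv <- stats::rpois(1L, config$visit_rate_per_year * span_y)
    if (nv == 0L) next
    vdates <- gp_start[i] + round(stats::runif(nv, 0, span_y * DAYS_PER_YEAR))
    for (b in seq_len(nrow(bm))) {
      measured <- stats::runif(nv) < 0.4
      if (!any(measured)) next
      t_y <- as.numeric(vdates[measured] - index_date[i]) / DAYS_PER_YEAR
      val <- subj_mean[i, bm$biomarker[b]] + bm$slope[b] * t_y +
        stats::rnorm(sum(measured), 0, bm$within_sd[b])
      val <- pmax(val, 0.05)
      unit <- BIOMARKER_UNITS[[bm$biomarker[b]]]
      # occasional legacy units exercise the conversion rules
      if (bm$biomarker[b] == "GLUCOSE") {
        legacy <- stats::runif(sum(measured)) < 0.1
        val[legacy] <- val[legacy] / 0.0555
        unit <- ifelse(legacy, "mg/dL", unit)
      }
      traj[[length(traj) + 1L]] <- syn_gp_row(
        ids[i], vdates[measured], "READ_V2",
        bm_codes[[bm$biomarker[b]]], round(val, 2), unit)
    }
  }
  if (length(traj)) {
    tr <- data.table::rbindlist(traj)
    # placeholder-date injection (biomarker rows only, so outcome phenotyping
    # is unaffected and the planted truth stays authoritative)
    ph <- stats::runif(nrow(tr)) < config$placeholder_rate
    if (any(ph)) {
      tr$date[ph] <- sample(DEFAULT_PLACEHOLDER_DATES, sum(ph), replace = TRUE)
    }
    gp[[length(gp) + 1L]] <- tr
  }
  gp_clinical <- data.table::rbindlist(gp, fill = TRUE)
  data.table::setorderv(gp_clinical, c("participant_id", "date", "system", "code"))
  hospital <- data.table::rbindlist(hosp)
  data.table::setorderv(hospital, c("participant_id", "date", "code"))
  death <- data.table::data.table(
    participant_id = ids[died], date = death_date[died],
    code = sample(c("J18", "C34"), sum(died), replace = TRUE))

  ## assessment table ----------------------------------------------------
  qual_pool <- isced_map()$qualification
  assessment <- data.table::data.table(
    participant_id = ids, sex = sex, birth_year = birth_year,
    birth_month = birth_month, ethnicity_code = ethnicity_code,
    index_date = index_date,
    bmi = bmi,
    ever_smoked = stats::runif(n) < 0.5,
    smoking_pack_years = round(stats::rexp(n, 1 / 25), 1),
    insulin = dm & stats::runif(n) < ifelse(dm_type %in% "T1D", 0.95, 0.2),
    bp_med = stats::runif(n) < 0.6,
    chol_med = stats::runif(n) < 0.7,
    qualification = sample(qual_pool, n, replace = TRUE),
    walk_days = sample(0:7, n, replace = TRUE),
    walk_min = sample(c(0, 10, 20, 30, 45, 60), n, replace = TRUE),
    moderate_days = sample(0:7, n, replace = TRUE),
    moderate_min = sample(c(0, 15, 30, 45, 60), n, replace = TRUE),
    vigorous_days = sample(0:4, n, replace = TRUE),
    vigorous_min = sample(c(0, 15, 30, 45), n, replace = TRUE),
    sr_illness_1 = sr_code, sr_illness_1_date = sr_date,
    lost_to_followup_date = lost_date)
  assessment[smoking_pack_years > 0 & !ever_smoked, smoking_pack_years := 0]
  # MCAR missingness on imputable covariates
  for (v in c("bmi", "qualification", "ethnicity_code", "smoking_pack_years",
              "walk_min", "moderate_min", "vigorous_min")) {
    hit <- stats::runif(n) < config$missing_rate
    assessment[hit, (v) := NA]
  }

  ## ground truth ---------------------------------------------------------
  truth <- data.table::data.table(
    participant_id = ids, sex = sex, age_at_index = age_at_index,
    birth_year = birth_year, birth_month = birth_month,
    index_date = index_date, has_primary_care = has_pc,
    gp_start = data.table::fifelse(has_pc, gp_start, as.Date(NA)),
    dm = dm, dm_type = dm_type, dm_onset = dm_onset,
    bmi_true = bmi, sbp_mean_true = subj_mean[, "SBP"],
    death_date = death_date, lost_date = lost_date,
    censor_date = censor_date,
    censor_cause = data.table::fcase(
      !is.na(death_date) & censor_date == death_date, "death",
      !is.na(lost_date) & censor_date == lost_date, "lost",
      default = "admin"),
    dkd_exclusion = excl_dkd, dr_exclusion = excl_dr)
  for (oc in outcomes) {
    truth[, paste0("latent_years_", tolower(oc)) := ev[[oc]]$latent_years]
    truth[, paste0("event_date_", tolower(oc)) := ev[[oc]]$event_date]
    truth[, paste0("event_external_", tolower(oc)) := ev[[oc]]$external]
  }
  data.table::setattr(truth, "beta", beta)
  data.table::setattr(truth, "baseline_hazard", config$baseline_hazard)

  achieved <- sum(!is.na(truth$event_date_cvd) & truth$dm)
  if (achieved == 0L) {
    warning(sprintf("configured hazards produced no recorded events (n = %d)", n),
            call. = FALSE)
  }
  list(dictionary = fixture_dictionary(), gp_clinical = gp_clinical,
       hospital = hospital, death = death, assessment = assessment,
       codelists = list(DM = fixture_codelist("DM"),
                        CVD = fixture_codelist("CVD"),
                        DKD = fixture_codelist("DKD"),
                        DR = fixture_codelist("DR")),
       truth = truth, config = config)
}

#' Independent rule evaluator: expected cohort from ground truth
#'
#' Re-derives, from the ground truth alone (never from the pipeline), which
#' participants the cohort module must retain for an outcome and the first
#' matching exclusion reason for every excluded diabetic. This is the
#' module's central oracle: it is a direct vectorised transcription of the
#' study-design rules, sharing no code with the event/cohort pipeline.
#'
#' @param truth ground-truth table from [generate_cohort()].
#' @param outcome one of [COHORT_OUTCOMES].
#' @param config a [cohort_config()] (defaults to the outcome's defaults).
#' @return `data.table` `participant_id`, `status`, `time_years`, `excluded`,
#'   `exclusion_reason` for every diabetic participant.
#' @export
expected_cohort <- function(truth, outcome, config = cohort_config(outcome)) {
  tr <- data.table::as.data.table(truth)[dm == TRUE]
  ev_col <- paste0("event_date_", tolower(outcome))
  ext_col <- paste0("event_external_", tolower(outcome))
  event_date <- tr[[ev_col]]
  external <- tr[[ext_col]]
  excl_flag <- switch(outcome,
                      DKD = tr$dkd_exclusion,
                      DR = tr$dr_exclusion,
                      rep(FALSE, nrow(tr)))
  dm_first <- tr$dm_onset
  idx <- tr$index_date
  cens <- tr$censor_date
  status <- as.integer(!is.na(event_date) & event_date <= cens)
  time_years <- as.numeric(data.table::fifelse(status == 1L, event_date, cens) - idx) /
    DAYS_PER_YEAR
  reason <- rep(NA_character_, nrow(tr))
  hit <- function(cond, r) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- r
  }
  hit(!is.na(event_date) & event_date < dm_first, "event_before_dm")
  hit(!is.na(event_date) & event_date > cens, "event_after_censor")
  hit(excl_flag, "exclusion_condition")
  hit(status == 1L & !(dm_first <= idx & idx <= event_date),
      "index_not_between")
  hit(status == 0L &
        !(as.numeric(dm_first - idx) <=
            config$dm_window_after_index_months * SIX_MONTHS_DAYS / 6),
      "dm_after_landmark")
  if (isTRUE(config$require_primary_care)) {
    has_ext <- !is.na(event_date) & external
    hit(!tr$has_primary_care & !has_ext, "no_primary_care")
  }
  if (config$min_years_dm_to_event > 0) {
    hit(status == 1L &
          as.numeric(event_date - dm_first) / DAYS_PER_YEAR <
            config$min_years_dm_to_event, "short_dm_to_event")
  }
  if (config$min_years_dm_followup > 0) {
    hit(status == 0L &
          as.numeric(cens - dm_first) / DAYS_PER_YEAR <
            config$min_years_dm_followup, "short_dm_followup")
  }
  hit(time_years <= 0, "nonpositive_followup")
  data.table::data.table(participant_id = tr$participant_id, status = status,
                         time_years = time_years,
                         excluded = !is.na(reason),
                         exclusion_reason = reason)
}

#' Hand-constructed rule fixture for the cohort module
#'
#' Sixteen hand-built participants, each designed to exercise exactly one
#' cohort rule (or to survive cleanly), for the DKD-style configuration
#' (primary care required, 5-year diabetes-duration rules). The expected
#' survivor list and per-participant reasons are stated by construction, not
#' computed by any pipeline code.
#'
#' @return list with cohort-module inputs (`dm_assignments`,
#'   `first_occurrence`, `exclusion_events`, `censor_info`, `index_dates`,
#'   `has_primary_care`, `external_outcome_ids`), the `outcome`, its
#'   `config`, and `expected` (`participant_id`, `retained`, `reason`).
#' @export
generate_rule_fixture <- function() {
  d <- function(x) as.Date(x)
  idx <- d("2008-07-01"); admin <- d("2018-02-28")
  p <- data.table::data.table(
    participant_id = sprintf("F%02d", 1:16),
    dm_onset = d(c("2000-01-01", "2000-01-01", "2000-01-01", "2000-01-01",
                   "2000-01-01", "2009-06-01", "2000-01-01", "2009-06-01",
                   "2008-12-01", "2000-01-01", "2000-01-01", "2006-01-01",
                   "2005-01-01", "2000-01-01", "2000-01-01", "1998-01-01")),
    index_date = c(rep(idx, 14), as.Date(NA), idx),
    event_date = d(c("2010-01-01", NA, "1999-06-01", "2017-01-01",
                     "2010-01-01", "2012-01-01", "2007-01-01", NA,
                     NA, NA, "2010-01-01", "2010-01-01",
                     NA, "2008-07-01", NA, "2011-05-01")),
    lost_date = d(c(NA, NA, NA, "2015-01-01", NA, NA, NA, NA,
                    NA, NA, NA, NA, "2009-06-01", NA, NA, NA)),
    death_date = d(c(NA, NA, NA, NA, NA, NA, NA, NA,
                     NA, NA, NA, NA, NA, NA, NA, "2012-01-01")),
    has_primary_care = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                         TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    is_exclusion = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expected <- data.table::data.table(
    participant_id = p$participant_id,
    retained = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    reason = c(NA, NA, "event_before_dm", "event_after_censor",
               "exclusion_condition", "index_not_between", "index_not_between",
               "dm_after_landmark", NA, "no_primary_care", NA,
               "short_dm_to_event", "short_dm_followup",
               "nonpositive_followup", "missing_admin", NA))
  list(
    outcome = "DKD",
    config = cohort_config("DKD"),
    dm_assignments = p[, list(participant_id, dm_type = "T2D",
                              first_evidence_date = dm_onset)],
    first_occurrence = p[!is.na(event_date),
                         list(participant_id, outcome_id = "DKD",
                              date = event_date, source = "HOSPITAL")],
    exclusion_events = p[is_exclusion == TRUE,
                         list(participant_id, date = index_date)],
    censor_info = p[, list(participant_id,
                           censor_date = compute_censor_date(
                             lost_date, death_date, rep(admin, .N)))],
    index_dates = p[, list(participant_id, index_date)],
    has_primary_care = p[, list(participant_id, has_primary_care)],
    # F11's event is documented in hospital records despite no linked
    # primary care; F16's likewise (all fixture events are HOSPITAL-source)
    external_outcome_ids = p[!is.na(event_date), participant_id],
    expected = expected)
}
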