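# Package-level declarations.

#' @importFrom data.table := .N .I .SD data.table
#' @importFrom stats setNames
#' @importFrom survival coxph Surv survfit survdiff
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "..cols", ".arow", ".priority", "action", "adate", "age_at_index",
  "alb", "biomarker", "birth_date", "birth_month", "birth_year", "bmi",
  "bp_med", "category", "cci", "cdate", "censor_date", "chol_med", "ci_high",
  "ci_low", "code", "cre", "date", "dd", "description", "dm", "dm_type",
  "end_date", "estimate", "ethnicity_code", "ever_smoked", "event_date",
  "excluded", "exclusion_reason", "factor", "gap", "gp_first", "gp_start",
  "has_primary_care", "has_t1", "has_t2", "hr", "i.birth_date",
  "i.cci", "i.death_date", "i.factor", "i.index_date", "i.lower",
  "i.upper", "icd10_prefix", "index_date", "insulin", "invalid_reason",
  "is_exclusion", "isced_gt2", "kind", "lost", "lost_to_followup_date",
  "lower", "met_hours_week", "moderate_days", "moderate_min", "n_desc",
  "outcome_id", "p", "participant_id", "qualification", "read2_code",
  "risk_group", "risk_score", "role", "se", "sex", "smoking_pack_years",
  "sr_illness_1", "sr_illness_1_date", "status", "system", "term",
  "time_years", "unit_original", "upper", "valid", "value", "vigorous_days",
  "vigorous_min", "walk_days", "walk_min", "weight", "window_end",
  "window_start", "x.factor", "ctv3_code", "i.death_date", "i.lower"))
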