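# Cohort construction: diabetes type classification, censoring dates,
# initial time-to-event tables, refinement and prospective-design exclusion
# rules, incidence rates.

#' Cohort outcomes
#' @export
COHORT_OUTCOMES <- c("CVD", "DKD", "DR")

#' Exclusion reasons, in precedence order
#'
#' When several rules would exclude the same participant, the first matching
#' reason in this fixed order is recorded, so exclusion audits are
#' deterministic.
#' @export
EXCLUSION_REASONS <- c("missing_admin", "event_before_dm", "event_after_censor",
                       "exclusion_condition", "index_not_between",
                       "dm_after_landmark", "no_primary_care",
                       "short_dm_to_event", "short_dm_followup",
                       "nonpositive_followup")

#' Classify diabetes type from coded events
#'
#' Participants with at least one valid `DEFINING`-role diabetes event are
#' assigned a type from the specificity of their type-tagged codes: `T1D` if
#' only type-1-specific codes are present, `T2D` if only type-2-specific,
#' and `UNCERTAIN` when both types, or only generic diabetes codes, appear.
#' Participants carrying only `DATE_ONLY` events are not assigned (consistent
#' with the first-occurrence gating rule). The first-evidence date is the
#' [first_occurrence()] date (date-only codes may pull it earlier).
#'
#' @param dm_events merged diabetes event table (roles `DEFINING`/`DATE_ONLY`).
#' @param type_codes table `system`, `code`, `dm_type` with
#'   `dm_type` in `T1D`, `T2D`, `GENERIC`.
#' @return `data.table` `participant_id`, `dm_type`, `first_evidence_date`.
#' @export
classify_diabetes <- function(dm_events, type_codes) {
  ev <- data.table::as.data.table(dm_events)
  tc <- data.table::as.data.table(type_codes)
  assert_cols(tc, c("system", "code", "dm_type"), "type_codes")
  stopifnot(all(tc$dm_type %in% c("T1D", "T2D", "GENERIC")))
  fo <- first_occurrence(dm_events, outcome_id = "DM")
  if (!nrow(fo)) {
    return(data.table::data.table(participant_id = character(),
                                  dm_type = character(),
                                  first_evidence_date = as.Date(character())))
  }
  typed <- merge(ev[valid == TRUE & role == "DEFINING"],
                 tc, by = c("system", "code"))
  flags <- typed[, list(has_t1 = any(dm_type == "T1D"),
                        has_t2 = any(dm_type == "T2D")),
                 by = "participant_id"]
  out <- merge(fo[, list(participant_id, first_evidence_date = date)],
               flags, by = "participant_id", all.x = TRUE)
  out[is.na(has_t1), has_t1 := FALSE]
  out[is.na(has_t2), has_t2 := FALSE]
  out[, dm_type := data.table::fcase(has_t1 & !has_t2, "T1D",
                                     has_t2 & !has_t1, "T2D",
                                     default = "UNCERTAIN")]
  out[, c("has_t1", "has_t2") := NULL]
  data.table::setcolorder(out, c("participant_id", "dm_type",
                                 "first_evidence_date"))
  out[]
}

#' Censoring date: earliest of loss-to-follow-up, death and showcase cut-off
#'
#' @param lost_to_followup_date,death_date optional dates (may be `NA`).
#' @param showcase_censor_date administrative cut-off (always present).
#' @return the element-wise minimum of the non-missing dates.
#' @export
compute_censor_date <- function(lost_to_followup_date = NULL,
                                death_date = NULL,
                                showcase_censor_date) {
  sc <- as_date_col(showcase_censor_date)
  if (anyNA(sc)) stop("showcase_censor_date must be present", call. = FALSE)
  n <- length(sc)
  fill <- function(x) if (is.null(x)) as.Date(rep(NA, n)) else as_date_col(x)
  pmin(sc, fill(lost_to_followup_date), fill(death_date), na.rm = TRUE)
}

#' Build the initial time-to-event table
#'
#' One row per diabetes participant: event status is positive if the outcome
#' first occurrence is on or before the censoring date; otherwise the
#' participant is at risk until censoring. Follow-up time is measured from
#' the index date in years (365.25 days/year). Participants lacking an index
#' date or censoring information are flagged `excluded` with reason
#' `missing_admin`.
#'
#' @param dm_assignments [classify_diabetes()] output.
#' @param outcome_first_occurrence [first_occurrence()] table for the outcome.
#' @param censor_info table `participant_id`, `censor_date` (see
#'   [compute_censor_date()]).
#' @param index_dates table `participant_id`, `index_date`.
#' @param outcome_id one of [COHORT_OUTCOMES].
#' @param has_primary_care optional table `participant_id`,
#'   `has_primary_care` (logical); defaults to `FALSE` when absent.
#' @return time-to-event `data.table` with columns `participant_id`,
#'   `outcome_id`, `index_date`, `dm_first_evidence_date`, `event_date`,
#'   `censor_date`, `status`, `time_years`, `has_primary_care`, `excluded`,
#'   `exclusion_reason`.
#' @export
build_initial_tte <- function(dm_assignments, outcome_first_occurrence,
                              censor_info, index_dates, outcome_id,
                              has_primary_care = NULL) {
  stopifnot(outcome_id %in% COHORT_OUTCOMES)
  dm <- data.table::as.data.table(dm_assignments)
  assert_cols(dm, c("participant_id", "first_evidence_date"), "dm_assignments")
  fo <- data.table::as.data.table(outcome_first_occurrence)
  ci <- data.table::as.data.table(censor_info)
  assert_cols(ci, c("participant_id", "censor_date"), "censor_info")
  ix <- data.table::as.data.table(index_dates)
  assert_cols(ix, c("participant_id", "index_date"), "index_dates")
  for (tab in list(dm, fo, ci, ix)) {
    if (anyDuplicated(tab$participant_id)) {
      stop("duplicate participant rows in an input table", call. = FALSE)
    }
  }
  out <- dm[, list(participant_id,
                   dm_first_evidence_date = as_date_col(first_evidence_date))]
  if ("dm_type" %in% names(dm)) out[, dm_type := dm$dm_type]
  out[, outcome_id := outcome_id]
  out[ix, index_date := as_date_col(i.index_date), on = "participant_id"]
  out[ci, censor_date := as_date_col(i.censor_date), on = "participant_id"]
  if (nrow(fo)) {
    assert_cols(fo, c("participant_id", "date"), "outcome_first_occurrence")
    out[fo, event_date := as_date_col(i.date), on = "participant_id"]
  } else {
    out[, event_date := as.Date(NA)]
  }
  if (!is.null(has_primary_care)) {
    hp <- data.table::as.data.table(has_primary_care)
    assert_cols(hp, c("participant_id", "has_primary_care"), "has_primary_care")
    out[hp, has_primary_care := i.has_primary_care, on = "participant_id"]
    out[is.na(has_primary_care), has_primary_care := FALSE]
  } else {
    out[, has_primary_care := FALSE]
  }
  out[, excluded := FALSE]
  out[, exclusion_reason := NA_character_]
  miss <- is.na(out$index_date) | is.na(out$censor_date)
  out[miss, `:=`(excluded = TRUE, exclusion_reason = "missing_admin")]
  out[, status := data.table::fifelse(!is.na(event_date) &
                                        event_date <= censor_date, 1L, 0L)]
  out[, end_date := data.table::fifelse(status == 1L, event_date, censor_date)]
  out[, time_years := as.numeric(end_date - index_date) / DAYS_PER_YEAR]
  out[, end_date := NULL]
  cols <- c("participant_id", "outcome_id", "index_date",
            "dm_first_evidence_date", "event_date", "censor_date", "status",
            "time_years", "has_primary_care", "excluded", "exclusion_reason")
  data.table::setcolorder(out, c(cols, setdiff(names(out), cols)))
  out[]
}

#' Refine the time-to-event table
#'
#' Flags (never deletes) rows violating the refinement rules, in fixed
#' precedence order: the complication event occurred before the first
#' documented evidence of diabetes (`event_before_dm`); the event occurred
#' after the censoring date (`event_after_censor`); the participant carries
#' any risk-set exclusion event (`exclusion_condition`).
#'
#' @param records [build_initial_tte()] output.
#' @param exclusion_events table of exclusion-role events with
#'   `participant_id` (dates not required: any exclusion event on record
#'   removes the participant from the risk set).
#' @return the records with updated `excluded`/`exclusion_reason`.
#' @export
refine_tte <- function(records, exclusion_events = NULL) {
  out <- data.table::copy(data.table::as.data.table(records))
  flag <- function(cond, reason) {
    hit <- cond & !out$excluded
    hit[is.na(hit)] <- FALSE
    out[hit, `:=`(excluded = TRUE, exclusion_reason = reason)]
  }
  flag(!is.na(out$event_date) & out$event_date < out$dm_first_evidence_date,
       "event_before_dm")
  flag(!is.na(out$event_date) & out$event_date > out$censor_date,
       "event_after_censor")
  if (!is.null(exclusion_events) && nrow(exclusion_events)) {
    ex_ids <- unique(as.character(
      data.table::as.data.table(exclusion_events)$participant_id))
    flag(out$participant_id %in% ex_ids, "exclusion_condition")
  }
  out[]
}

#' Per-outcome prospective-design configuration
#'
#' Defaults encode the platform's study design: outcomes heavily ascertained
#' from primary care (DKD, DR) require primary-care representation unless the
#' event is documented in hospital/death records; kidney-disease events must
#' occur at least 5 years after the first evidence of diabetes (and the risk
#' set must have 5 years of follow-up since first evidence) to preferentially
#' capture diabetes-related kidney disease; diabetes must be evidenced no
#' later than 6 months after the index date.
#'
#' @param outcome one of [COHORT_OUTCOMES].
#' @param require_primary_care,min_years_dm_to_event,min_years_dm_followup,dm_window_after_index_months
#'   overrides of the per-outcome defaults.
#' @return a named list of rule parameters.
#' @export
cohort_config <- function(outcome,
                          require_primary_care = NULL,
                          min_years_dm_to_event = NULL,
                          min_years_dm_followup = NULL,
                          dm_window_after_index_months = 6) {
  if (!outcome %in% COHORT_OUTCOMES) {
    stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE)
  }
  defaults <- list(
    CVD = list(require_primary_care = FALSE, min_years_dm_to_event = 0,
               min_years_dm_followup = 0),
    DKD = list(require_primary_care = TRUE, min_years_dm_to_event = 5,
               min_years_dm_followup = 5),
    DR  = list(require_primary_care = TRUE, min_years_dm_to_event = 0,
               min_years_dm_followup = 0))[[outcome]]
  list(outcome = outcome,
       require_primary_care = require_primary_care %||% defaults$require_primary_care,
       min_years_dm_to_event = min_years_dm_to_event %||% defaults$min_years_dm_to_event,
       min_years_dm_followup = min_years_dm_followup %||% defaults$min_years_dm_followup,
       dm_window_after_index_months = dm_window_after_index_months)
}

#' Apply the prospective-design exclusion rules
#'
#' Applies, in order, to rows not already excluded:
#' (a) participants with the event are excluded unless
#'     `dm_first_evidence <= index_date <= event_date`;
#' (b) participants without the event are excluded unless the first evidence
#'     of diabetes is before, or within 6 months after, the index date;
#' (c) when the outcome requires primary-care representation, participants
#'     without linked primary care are excluded unless their outcome event is
#'     documented in hospital admissions or the death record;
#' (d) events closer than `min_years_dm_to_event` years to the first evidence
#'     of diabetes are excluded, and at-risk participants with less than
#'     `min_years_dm_followup` years between first evidence and censoring are
#'     excluded;
#' (e) rows with non-positive follow-up time are excluded (events on the
#'     index date count as time 0 and are excluded; ties are not retained).
#'
#' "Within 6 months" is calendar arithmetic on days: `index + 182.625` days.
#'
#' @param records refined time-to-event table.
#' @param config a [cohort_config()] list (its `outcome` must match the
#'   records' `outcome_id`).
#' @param external_outcome_ids participant ids whose outcome event is
#'   documented in hospital or death records (used by rule (c)).
#' @return the records with updated `excluded`/`exclusion_reason`.
#' @export
apply_prospective_design <- function(records, config,
                                     external_outcome_ids = character()) {
  out <- data.table::copy(data.table::as.data.table(records))
  if (nrow(out) && !all(out$outcome_id %in% config$outcome)) {
    stop(sprintf("records are for outcome %s but config is for %s",
                 paste(unique(out$outcome_id), collapse = ","),
                 config$outcome), call. = FALSE)
  }
  flag <- function(cond, reason) {
    hit <- cond & !out$excluded
    hit[is.na(hit)] <- FALSE
    out[hit, `:=`(excluded = TRUE, exclusion_reason = reason)]
  }
  is_event <- out$status == 1L
  # (a) events: dm evidence <= index <= event date
  flag(is_event & !(out$dm_first_evidence_date <= out$index_date &
                      out$index_date <= out$event_date),
       "index_not_between")
  # (b) non-events: dm evidence <= index + 6 months
  win_days <- config$dm_window_after_index_months * SIX_MONTHS_DAYS / 6
  flag(!is_event &
         !(as.numeric(out$dm_first_evidence_date - out$index_date) <= win_days),
       "dm_after_landmark")
  # (c) primary-care representation
  if (isTRUE(config$require_primary_care)) {
    flag(!out$has_primary_care &
           !(out$participant_id %in% external_outcome_ids),
         "no_primary_care")
  }
  # (d) minimum diabetes duration rules
  if (config$min_years_dm_to_event > 0) {
    flag(is_event &
           as.numeric(out$event_date - out$dm_first_evidence_date) / DAYS_PER_YEAR <
             config$min_years_dm_to_event,
         "short_dm_to_event")
  }
  if (config$min_years_dm_followup > 0) {
    flag(!is_event &
           as.numeric(out$censor_date - out$dm_first_evidence_date) / DAYS_PER_YEAR <
             config$min_years_dm_followup,
         "short_dm_followup")
  }
  # (e) non-positive follow-up
  flag(out$time_years <= 0, "nonpositive_followup")
  out[]
}

#' Tabulate exclusions
#'
#' @param records time-to-event table with exclusion flags.
#' @return `data.table` of exclusion reasons and counts, in precedence order.
#' @export
exclusion_summary <- function(records) {
  rec <- data.table::as.data.table(records)
  tab <- rec[excluded == TRUE, .N, by = "exclusion_reason"]
  tab[, exclusion_reason := factor(exclusion_reason, levels = EXCLUSION_REASONS)]
  data.table::setorderv(tab, "exclusion_reason")
  tab[, exclusion_reason := as.character(exclusion_reason)]
  tab[]
}

#' Incidence rate per 1000 person-years with exact Poisson CI
#'
#' `rate = 1000 * n_events / person_years`, over unexcluded rows. The 95%
#' confidence interval uses the exact Poisson/chi-square relation on the
#' event count: lower `qchisq(a/2, 2k)/2` (0 when `k = 0`), upper
#' `qchisq(1 - a/2, 2k + 2)/2`, scaled by person-years.
#'
#' @param cohort time-to-event table (rows with `excluded == TRUE` ignored).
#' @param conf_level confidence level, default 0.95.
#' @return one-row `data.table`: `outcome_id`, `n_events`, `person_years`,
#'   `rate_per_1000`, `ci_low`, `ci_high`.
#' @export
incidence_rate <- function(cohort, conf_level = 0.95) {
  co <- data.table::as.data.table(cohort)
  if ("excluded" %in% names(co)) co <- co[excluded == FALSE]
  if (!nrow(co)) stop("cohort has no unexcluded rows", call. = FALSE)
  k <- sum(co$status)
  py <- sum(co$time_years)
  if (py <= 0) stop("zero person-years", call. = FALSE)
  a <- 1 - conf_level
  lo <- if (k == 0) 0 else stats::qchisq(a / 2, 2 * k) / 2
  hi <- stats::qchisq(1 - a / 2, 2 * k + 2) / 2
  data.table::data.table(
    outcome_id = if ("outcome_id" %in% names(co)) co$outcome_id[1L] else NA_character_,
    n_events = as.integer(k), person_years = py,
    rate_per_1000 = 1000 * k / py,
    ci_low = 1000 * lo / py, ci_high = 1000 * hi / py)
}
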