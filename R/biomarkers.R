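# Longitudinal biomarker curation: trajectory extraction and unit
# harmonisation, CKD-EPI eGFR, urine albumin-to-creatinine ratio, derived
# albuminuria / prolonged-low-eGFR events, landmark-window summaries.

#' Recognised biomarkers and their canonical units
#'
#' Concentrations are harmonised to mmol/L (glucose, lipids), mmol/mol
#' (HbA1c, IFCC), mg/mmol (uACR), micromol/L (serum creatinine), mmol/L
#' (urine creatinine), mg/L (urine albumin), mmHg (blood pressures) and
#' ml/min/1.73m2 (eGFR).
#' @export
BIOMARKER_UNITS <- c(
  GLUCOSE = "mmol/L", HBA1C = "mmol/mol", URINE_ALBUMIN = "mg/L",
  URINE_CREATININE = "mmol/L", UACR = "mg/mmol", SERUM_CREATININE = "umol/L",
  SBP = "mmHg", DBP = "mmHg", TOTAL_CHOL = "mmol/L", HDL = "mmol/L",
  LDL = "mmol/L", TRIG = "mmol/L", EGFR = "ml/min/1.73m2")

# plausibility bounds in canonical units; values outside are flagged invalid
DEFAULT_BIOMARKER_BOUNDS <- data.table::data.table(
  biomarker = names(BIOMARKER_UNITS),
  lower = c(1, 10, 0.01, 0.1, 0.001, 10, 40, 20, 0.5, 0.1, 0.1, 0.1, 1),
  upper = c(60, 250, 5000, 100, 3000, 3000, 300, 200, 25, 10, 15, 50, 250))

#' Extract and harmonise biomarker trajectories
#'
#' Combines valued primary-care events (mapped to biomarkers via a code map)
#' with assessment-centre measurements into one unit-harmonised, date-sorted
#' trajectory table per participant. Values outside per-biomarker
#' plausibility bounds are flagged invalid, not dropped.
#'
#' @param primary_care_values table `participant_id`, `date`, `system`,
#'   `code`, `value`, `unit`.
#' @param assessment_measures table `participant_id`, `date`, `biomarker`,
#'   `value`, `unit` (may be `NULL`).
#' @param biomarker_code_map table `system`, `code`, `biomarker`.
#' @param unit_rules table `biomarker`, `unit`, `factor`: multiplying a value
#'   recorded in `unit` by `factor` yields the canonical unit. Canonical
#'   units themselves need no rule (factor 1 implied).
#' @param bounds plausibility bounds per biomarker
#'   (`biomarker`, `lower`, `upper`).
#' @return `data.table` `participant_id`, `biomarker`, `date`, `value`
#'   (canonical unit), `unit_original`, `valid`, sorted by participant and
#'   date.
#' @export
extract_trajectories <- function(primary_care_values = NULL,
                                 assessment_measures = NULL,
                                 biomarker_code_map = NULL,
                                 unit_rules = NULL,
                                 bounds = DEFAULT_BIOMARKER_BOUNDS) {
  pieces <- list()
  if (!is.null(primary_care_values) && nrow(primary_care_values)) {
    pc <- data.table::as.data.table(primary_care_values)
    assert_cols(pc, c("participant_id", "date", "system", "code", "value", "unit"),
                "primary care values")
    assert_cols(biomarker_code_map, c("system", "code", "biomarker"),
                "biomarker code map")
    cm <- data.table::as.data.table(biomarker_code_map)
    pc <- merge(pc, cm, by = c("system", "code"))
    pieces[[1L]] <- pc[, list(participant_id = as.character(participant_id),
                              biomarker, date = as_date_col(date),
                              value = as.numeric(value),
                              unit_original = as.character(unit))]
  }
  if (!is.null(assessment_measures) && nrow(assessment_measures)) {
    am <- data.table::as.data.table(assessment_measures)
    assert_cols(am, c("participant_id", "date", "biomarker", "value", "unit"),
                "assessment measures")
    pieces[[length(pieces) + 1L]] <-
      am[, list(participant_id = as.character(participant_id),
                biomarker = as.character(biomarker), date = as_date_col(date),
                value = as.numeric(value), unit_original = as.character(unit))]
  }
  if (!length(pieces)) {
    return(data.table::data.table(participant_id = character(),
                                  biomarker = character(),
                                  date = as.Date(character()),
                                  value = numeric(), unit_original = character(),
                                  valid = logical()))
  }
  tr <- data.table::rbindlist(pieces)
  bad_bm <- setdiff(unique(tr$biomarker), names(BIOMARKER_UNITS))
  if (length(bad_bm)) {
    stop(sprintf("unknown biomarker(s): %s", paste(bad_bm, collapse = ", ")),
         call. = FALSE)
  }
  # unit harmonisation
  tr[, factor := data.table::fifelse(unit_original == BIOMARKER_UNITS[biomarker],
                                     1, NA_real_)]
  if (!is.null(unit_rules) && nrow(unit_rules)) {
    ur <- data.table::as.data.table(unit_rules)
    assert_cols(ur, c("biomarker", "unit", "factor"), "unit rules")
    tr[ur, factor := data.table::fifelse(is.na(x.factor), i.factor, x.factor),
       on = c("biomarker", unit_original = "unit")]
  }
  if (anyNA(tr$factor)) {
    off <- unique(tr[is.na(factor), paste0(biomarker, ":", unit_original)])
    stop(sprintf("no unit conversion rule for: %s", paste(off, collapse = ", ")),
         call. = FALSE)
  }
  tr[, value := value * factor]
  tr[, factor := NULL]
  b <- data.table::as.data.table(bounds)
  tr[b, `:=`(lower = i.lower, upper = i.upper), on = "biomarker"]
  tr[, valid := !is.na(value) & !is.na(date) &
       (is.na(lower) | value >= lower) & (is.na(upper) | value <= upper)]
  tr[, c("lower", "upper") := NULL]
  data.table::setorderv(tr, c("participant_id", "biomarker", "date"))
  tr[]
}

#' Estimated glomerular filtration rate (CKD-EPI creatinine 2009)
#'
#' Computes eGFR in ml/min/1.73m2 from serum creatinine via the CKD-EPI 2009
#' creatinine equation:
#' `141 * min(Scr/k, 1)^alpha * max(Scr/k, 1)^(-1.209) * 0.993^age *
#'  1.018[female] * 1.159[black]`,
#' with `k = 0.7` (female) / `0.9` (male) and `alpha = -0.329` / `-0.411`.
#' The race coefficient belongs to the original 2009 fit and can be disabled
#' with `use_race_term = FALSE` (the 2021 refit removed it).
#'
#' @param creatinine serum creatinine, by default in mg/dL.
#' @param age age in years.
#' @param sex `"female"`/`"male"` (or a logical `female` indicator).
#' @param black logical, self-identified Black race (only used when
#'   `use_race_term` is `TRUE`).
#' @param units `"mg/dL"` or `"umol/L"` (micromol/L values are divided by
#'   88.4 first).
#' @param use_race_term apply the 1.159 race coefficient.
#' @return eGFR in ml/min/1.73m2 (vectorised).
#' @export
compute_egfr <- function(creatinine, age, sex, black = FALSE,
                         units = c("mg/dL", "umol/L"), use_race_term = TRUE) {
  units <- match.arg(units)
  if (any(creatinine <= 0, na.rm = TRUE) || any(age <= 0, na.rm = TRUE)) {
    stop("creatinine and age must be positive", call. = FALSE)
  }
  scr <- if (units == "umol/L") creatinine / 88.4 else creatinine
  female <- if (is.logical(sex)) sex else tolower(as.character(sex)) %in% c("female", "f")
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- scr / kappa
  egfr <- 141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age
  egfr <- egfr * ifelse(female, 1.018, 1)
  if (use_race_term) egfr <- egfr * ifelse(rep_len(black, length(egfr)), 1.159, 1)
  egfr
}

#' Urine albumin-to-creatinine ratio from paired measurements
#'
#' Pairs each urine albumin measurement with the nearest-dated urine
#' creatinine measurement of the same participant within
#' `pairing_window_days` (ties resolved towards the earlier creatinine
#' date) and returns uACR = albumin / creatinine in mg/mmol. Unpaired
#' albumin measurements, and pairs with zero creatinine, are skipped with a
#' logged count. Directly recorded uACR measurements can simply be
#' concatenated by the caller.
#'
#' @param albumin_series table `participant_id`, `date`, `value` (mg/L).
#' @param creatinine_series table `participant_id`, `date`, `value` (mmol/L).
#' @param pairing_window_days maximum date gap for pairing, default 7
#'   (same-visit urine panels).
#' @return `data.table` `participant_id`, `biomarker = "UACR"`, `date`
#'   (albumin date), `value` (mg/mmol), `valid`.
#' @export
compute_uacr <- function(albumin_series, creatinine_series,
                         pairing_window_days = 7) {
  alb <- data.table::as.data.table(albumin_series)
  cre <- data.table::as.data.table(creatinine_series)
  assert_cols(alb, c("participant_id", "date", "value"), "albumin series")
  assert_cols(cre, c("participant_id", "date", "value"), "creatinine series")
  alb <- alb[, list(participant_id = as.character(participant_id),
                    adate = as_date_col(date), alb = as.numeric(value))]
  cre <- cre[, list(participant_id = as.character(participant_id),
                    cdate = as_date_col(date), cre = as.numeric(value))]
  if (!nrow(alb)) {
    return(data.table::data.table(participant_id = character(),
                                  biomarker = character(),
                                  date = as.Date(character()),
                                  value = numeric(), valid = logical()))
  }
  alb[, .arow := .I]
  j <- merge(alb, cre, by = "participant_id", allow.cartesian = TRUE)
  j <- j[abs(as.numeric(adate - cdate)) <= pairing_window_days]
  # nearest date; ties -> earlier creatinine date
  data.table::setorderv(j, c(".arow"))
  j[, gap := abs(as.numeric(adate - cdate))]
  data.table::setorderv(j, c(".arow", "gap", "cdate"))
  j <- j[!duplicated(.arow)]
  n_skipped <- nrow(alb) - nrow(j)
  zero <- j$cre == 0
  if (any(zero)) {
    n_skipped <- n_skipped + sum(zero)
    j <- j[!zero]
  }
  if (n_skipped > 0L) {
    message(sprintf("uACR pairing: %d albumin measurement(s) skipped (no creatinine partner or zero creatinine)",
                    n_skipped))
  }
  out <- j[, list(participant_id, biomarker = "UACR", date = adate,
                  value = alb / cre, valid = TRUE)]
  data.table::setorderv(out, c("participant_id", "date"))
  out[]
}

#' Detect albuminuria events from a uACR trajectory
#'
#' Emits a `MICROALBUMINURIA` event at the first date with
#' uACR >= `micro_threshold` and a `MACROALBUMINURIA` event at the first date
#' with uACR >= `macro_threshold`. Both events may fire, possibly on the same
#' date. Default thresholds follow the KDIGO albuminuria categories
#' (A2: 3 mg/mmol, A3: 30 mg/mmol).
#'
#' @param uacr_trajectory table `participant_id`, `date`, `value` (mg/mmol);
#'   a `valid` column, when present, restricts to valid measurements.
#' @param micro_threshold,macro_threshold thresholds in mg/mmol,
#'   `micro_threshold < macro_threshold`.
#' @return `data.table` `participant_id`, `kind`, `date`.
#' @export
detect_albuminuria_events <- function(uacr_trajectory, micro_threshold = 3,
                                      macro_threshold = 30) {
  stopifnot(micro_threshold < macro_threshold)
  tr <- data.table::as.data.table(uacr_trajectory)
  assert_cols(tr, c("participant_id", "date", "value"), "uACR trajectory")
  if ("valid" %in% names(tr)) tr <- tr[valid == TRUE]
  tr <- tr[!is.na(value) & !is.na(date)]
  tr[, date := as_date_col(date)]
  data.table::setorderv(tr, c("participant_id", "date"))
  micro <- tr[value >= micro_threshold,
              list(kind = "MICROALBUMINURIA", date = date[1L]),
              by = "participant_id"]
  macro <- tr[value >= macro_threshold,
              list(kind = "MACROALBUMINURIA", date = date[1L]),
              by = "participant_id"]
  out <- rbind(micro, macro)
  data.table::setcolorder(out, c("participant_id", "kind", "date"))
  data.table::setorderv(out, c("participant_id", "kind"))
  out[]
}

#' Detect prolonged low eGFR events
#'
#' A sustained-low rule in the KDIGO chronicity spirit: an event fires at the
#' first measurement `M2` for which some earlier measurement `M1` satisfies
#' `date(M2) - date(M1) >= min_span_days` with every measurement between
#' `M1` and `M2` (inclusive) below `threshold`. The event date is the date of
#' the confirming measurement `M2`.
#'
#' @param egfr_trajectory table `participant_id`, `date`, `value`
#'   (ml/min/1.73m2), date-sorted per participant (re-sorted defensively).
#' @param threshold eGFR threshold, default 60.
#' @param min_span_days minimum span of the sustained-low run, default 90.
#' @return `data.table` `participant_id`, `kind = "LOW_EGFR_PROLONGED"`,
#'   `date`.
#' @export
detect_prolonged_low_egfr <- function(egfr_trajectory, threshold = 60,
                                      min_span_days = 90) {
  tr <- data.table::as.data.table(egfr_trajectory)
  assert_cols(tr, c("participant_id", "date", "value"), "eGFR trajectory")
  if ("valid" %in% names(tr)) tr <- tr[valid == TRUE]
  tr <- tr[!is.na(value) & !is.na(date)]
  tr[, date := as_date_col(date)]
  data.table::setorderv(tr, c("participant_id", "date"))
  one <- function(dates, values) {
    run_start <- NA_integer_
    for (i in seq_along(values)) {
      if (values[i] < threshold) {
        if (is.na(run_start)) run_start <- i
        if (as.numeric(dates[i] - dates[run_start]) >= min_span_days) {
          return(dates[i])
        }
      } else {
        run_start <- NA_integer_
      }
    }
    as.Date(NA)
  }
  out <- tr[, list(kind = "LOW_EGFR_PROLONGED", date = one(date, value)),
            by = "participant_id"]
  out[!is.na(date)][]
}

#' Summarise biomarker trajectories over the landmark window
#'
#' The landmark period runs from the start of a participant's primary-care
#' record to six months after the index date; baseline biomarker summaries
#' (mean and coefficient of variation) are computed from measurements inside
#' that window. The CV (sample sd / mean) is reported only when at least
#' `cv_min_n` measurements are available and the mean is positive.
#'
#' @param trajectory biomarker trajectory table (`participant_id`,
#'   `biomarker`, `date`, `value`, optional `valid`).
#' @param window_start,window_end either scalar dates, or a table
#'   `participant_id`, `window_start`, `window_end` passed as `window_start`
#'   (per-participant landmark windows) with `window_end = NULL`.
#' @param cv_min_n minimum number of measurements for a CV, default 2.
#' @return `data.table` `participant_id`, `biomarker`, `n_measurements`,
#'   `mean`, `cv`.
#' @export
summarize_landmark <- function(trajectory, window_start, window_end = NULL,
                               cv_min_n = 2L) {
  tr <- data.table::as.data.table(trajectory)
  assert_cols(tr, c("participant_id", "biomarker", "date", "value"),
              "trajectory")
  if ("valid" %in% names(tr)) tr <- tr[valid == TRUE]
  tr <- tr[!is.na(value) & !is.na(date)]
  tr[, date := as_date_col(date)]
  if (is.data.frame(window_start)) {
    w <- data.table::as.data.table(window_start)
    assert_cols(w, c("participant_id", "window_start", "window_end"),
                "window table")
    w <- w[, list(participant_id = as.character(participant_id),
                  window_start = as_date_col(window_start),
                  window_end = as_date_col(window_end))]
    tr <- merge(tr, w, by = "participant_id")
  } else {
    ws <- as_date_col(window_start); we <- as_date_col(window_end)
    if (ws > we) stop("window_start must be <= window_end", call. = FALSE)
    tr[, `:=`(window_start = ws, window_end = we)]
  }
  tr <- tr[date >= window_start & date <= window_end]
  out <- tr[, list(n_measurements = .N,
                   mean = mean(value),
                   cv = if (.N >= cv_min_n && mean(value) > 0)
                     stats::sd(value) / mean(value) else NA_real_),
            by = c("participant_id", "biomarker")]
  data.table::setorderv(out, c("participant_id", "biomarker"))
  out[]
}
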