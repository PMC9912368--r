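# Baseline covariate panel: ethnicity recode, Charlson Comorbidity Index,
# MET physical activity, ISCED education, panel assembly.

#' Recode a hierarchical self-reported ethnicity code into four groups
#'
#' UK-Biobank-style ethnicity codings are hierarchical: the leading digit of
#' the (positive) code identifies the top-level group. The four-group scheme
#' maps top-level 1 to White, 3 to Asian, 4 to Black and everything else
#' (mixed, Chinese, other ethnic group) to Other. Negative and missing codes
#' (do-not-know / prefer-not-to-answer) map to missing, to be handled by
#' imputation. The mapping is overridable via `mapping`.
#'
#' @param raw_code integer-like vector of raw ethnicity codes.
#' @param mapping optional table `top_digit`, `ethnicity4` overriding the
#'   default top-digit rule.
#' @return character vector in `{"Asian", "Black", "Other", "White"}` or `NA`.
#' @export
recode_ethnicity <- function(raw_code, mapping = NULL) {
  raw <- suppressWarnings(as.integer(raw_code))
  top <- ifelse(is.na(raw) | raw < 0, NA_integer_,
                as.integer(substr(as.character(raw), 1L, 1L)))
  if (is.null(mapping)) {
    mapping <- default_ethnicity_map()
  }
  m <- data.table::as.data.table(mapping)
  assert_cols(m, c("top_digit", "ethnicity4"), "ethnicity mapping")
  lut <- stats::setNames(m$ethnicity4, m$top_digit)
  out <- unname(lut[as.character(top)])
  out[!is.na(top) & is.na(out)] <- "Other"
  out
}

default_ethnicity_map <- function() {
  read_tsv(ehrpheno_extdata("ethnicity_map.tsv"))
}

#' Load the shipped Quan (2005) ICD-10 Charlson mapping
#'
#' Prefix-to-category map with original Charlson weights, shipped as an
#' editable TSV (`charlson_icd10.tsv`): columns `icd10_prefix`, `category`,
#' `weight`. Dots in codes are ignored when matching.
#' @return `data.table`.
#' @export
charlson_map <- function() {
  read_tsv(ehrpheno_extdata("charlson_icd10.tsv"))
}

# category hierarchy: when both members are present the severe one is counted
CHARLSON_HIERARCHY <- list(
  c("diabetes_complicated", "diabetes"),
  c("moderate_severe_liver", "mild_liver"),
  c("metastatic_tumour", "malignancy"))

#' Charlson Comorbidity Index from prior hospital diagnoses
#'
#' Sum of Charlson category weights over ICD-10 diagnoses dated strictly
#' before the index date; each category is counted once, and within the
#' diabetes / liver / cancer severity pairs only the more severe member
#' contributes. Unmappable codes are ignored (count logged).
#'
#' @param hospital_diagnoses table `participant_id`, `date`, `code`
#'   (ICD-10; dots optional). A `system` column, when present, restricts to
#'   `ICD10` rows.
#' @param index_date scalar date or table `participant_id`, `index_date`.
#' @param mapping Charlson map (default the shipped Quan 2005 table).
#' @param participants optional id vector fixing the output rows (ids with no
#'   prior mapped diagnosis get CCI 0).
#' @return `data.table` `participant_id`, `cci`.
#' @export
compute_cci <- function(hospital_diagnoses, index_date,
                        mapping = charlson_map(), participants = NULL) {
  dx <- data.table::as.data.table(hospital_diagnoses)
  assert_cols(dx, c("participant_id", "date", "code"), "hospital diagnoses")
  if ("system" %in% names(dx)) dx <- dx[system == "ICD10"]
  dx <- dx[, list(participant_id = as.character(participant_id),
                  date = as_date_col(date),
                  code = gsub(".", "", toupper(as.character(code)), fixed = TRUE))]
  if (is.data.frame(index_date)) {
    ix <- data.table::as.data.table(index_date)
    assert_cols(ix, c("participant_id", "index_date"), "index_date table")
    dx[ix, index_date := as_date_col(i.index_date), on = "participant_id"]
  } else {
    dx[, index_date := as_date_col(index_date)]
  }
  dx <- dx[!is.na(date) & !is.na(index_date) & date < index_date]
  m <- data.table::as.data.table(mapping)
  assert_cols(m, c("icd10_prefix", "category", "weight"), "Charlson mapping")
  m[, icd10_prefix := gsub(".", "", toupper(icd10_prefix), fixed = TRUE)]
  # longest-prefix match
  matched <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    hit <- startsWith(dx$code, m$icd10_prefix[i])
    if (any(hit)) {
      matched[[i]] <- data.table::data.table(
        participant_id = dx$participant_id[hit],
        category = m$category[i], weight = m$weight[i])
    }
  }
  hits <- data.table::rbindlist(Filter(Negate(is.null), matched))
  n_unmapped <- if (nrow(dx)) {
    length(unique(dx$code)) - length(unique(unlist(
      lapply(seq_len(nrow(m)), function(i)
        dx$code[startsWith(dx$code, m$icd10_prefix[i])]))))
  } else 0L
  if (n_unmapped > 0L) {
    message(sprintf("CCI: %d distinct prior code(s) not in the Charlson map (ignored)",
                    n_unmapped))
  }
  base_ids <- as.character(participants %||% unique(dx$participant_id))
  if (!nrow(hits)) {
    return(data.table::data.table(participant_id = base_ids,
                                  cci = rep(0L, length(base_ids))))
  }
  hits <- unique(hits, by = c("participant_id", "category"))
  for (pair in CHARLSON_HIERARCHY) {
    severe <- hits[category == pair[1], participant_id]
    hits <- hits[!(category == pair[2] & participant_id %in% severe)]
  }
  cci <- hits[, list(cci = as.integer(sum(weight))), by = "participant_id"]
  out <- data.table::data.table(participant_id = base_ids)
  out[cci, cci := i.cci, on = "participant_id"]
  out[is.na(cci), cci := 0L]
  out[]
}

#' Weekly physical activity in MET hours
#'
#' IPAQ scoring of self-reported activity: MET-minutes/week =
#' `3.3 * walking + 4.0 * moderate + 8.0 * vigorous` (each days/week x
#' minutes/day), converted to hours/week.
#'
#' @param walk_days,walk_min,moderate_days,moderate_min,vigorous_days,vigorous_min
#'   days per week (0-7) and minutes per day for each intensity.
#' @return MET hours/week (vectorised; `NA` propagates).
#' @export
compute_met <- function(walk_days, walk_min, moderate_days, moderate_min,
                        vigorous_days, vigorous_min) {
  stopifnot(all(walk_days >= 0 & walk_days <= 7, na.rm = TRUE),
            all(moderate_days >= 0 & moderate_days <= 7, na.rm = TRUE),
            all(vigorous_days >= 0 & vigorous_days <= 7, na.rm = TRUE))
  met_min <- 3.3 * walk_days * walk_min +
    4.0 * moderate_days * moderate_min +
    8.0 * vigorous_days * vigorous_min
  met_min / 60
}

#' Load the shipped qualification-to-ISCED mapping
#' @return `data.table` with columns `qualification`, `isced_level`.
#' @export
isced_map <- function() {
  read_tsv(ehrpheno_extdata("isced_map.tsv"))
}

#' Translate highest qualification to an ISCED level
#'
#' @param highest_qualification_code character vector of qualification labels
#'   (matched against the mapping's `qualification` column).
#' @param mapping mapping table, default the shipped one.
#' @return `data.table` `isced_level` (integer, `NA` if unmapped) and
#'   `isced_gt2` (`level > 2`).
#' @export
compute_isced <- function(highest_qualification_code, mapping = isced_map()) {
  m <- data.table::as.data.table(mapping)
  assert_cols(m, c("qualification", "isced_level"), "ISCED mapping")
  lut <- stats::setNames(as.integer(m$isced_level), m$qualification)
  lev <- unname(lut[as.character(highest_qualification_code)])
  data.table::data.table(isced_level = lev,
                         isced_gt2 = data.table::fifelse(is.na(lev), NA,
                                                         lev > 2L))
}

#' Assemble the baseline covariate panel
#'
#' Left-joins demographic, covariate and biomarker-summary pieces onto the
#' retained cohort rows, preserving missingness for downstream imputation.
#' Biomarker summaries are spread to `mean_<biomarker>` / `cv_<biomarker>`
#' columns. Age at index is computed from birth year/month (mid-month
#' convention) to the index date.
#'
#' @param cohort retained time-to-event rows (`participant_id`, `index_date`,
#'   `time_years`, `status`, optionally `dm_type`).
#' @param demographics table with `participant_id`, `sex`, `birth_year`,
#'   `birth_month` and any directly-carried covariate columns (`bmi`,
#'   `ever_smoked`, `smoking_pack_years`, `insulin`, `bp_med`, `chol_med`,
#'   `ethnicity` already recoded, ...).
#' @param covariate_pieces named list of tables keyed by `participant_id`
#'   (e.g. the [compute_cci()] output); each is left-joined.
#' @param biomarker_summaries [summarize_landmark()] output (optional).
#' @return one row per cohort participant, `data.table`.
#' @export
assemble_panel <- function(cohort, demographics, covariate_pieces = list(),
                           biomarker_summaries = NULL) {
  co <- data.table::as.data.table(cohort)
  if ("excluded" %in% names(co)) co <- co[excluded == FALSE]
  assert_cols(co, c("participant_id", "index_date", "time_years", "status"),
              "cohort")
  keep <- intersect(c("participant_id", "index_date", "time_years", "status",
                      "dm_type"), names(co))
  panel <- co[, keep, with = FALSE]
  dem <- data.table::as.data.table(demographics)
  assert_cols(dem, "participant_id", "demographics")
  pieces <- c(list(demographics = dem), covariate_pieces)
  for (nm in names(pieces)) {
    p <- data.table::as.data.table(pieces[[nm]])
    if (anyDuplicated(p$participant_id)) {
      stop(sprintf("duplicate participant rows in covariate piece '%s'", nm),
           call. = FALSE)
    }
    p[, participant_id := as.character(participant_id)]
    panel <- merge(panel, p, by = "participant_id", all.x = TRUE,
                   sort = FALSE, suffixes = c("", paste0(".", nm)))
  }
  if (all(c("birth_year", "birth_month") %in% names(panel))) {
    approx_birth <- as.Date(sprintf("%04d-%02d-15", panel$birth_year,
                                    panel$birth_month))
    panel[, age_at_index := as.numeric(index_date - approx_birth) / DAYS_PER_YEAR]
  }
  if (!is.null(biomarker_summaries) && nrow(biomarker_summaries)) {
    bs <- data.table::as.data.table(biomarker_summaries)
    assert_cols(bs, c("participant_id", "biomarker", "mean", "cv"),
                "biomarker summaries")
    wide <- data.table::dcast(bs, participant_id ~ biomarker,
                              value.var = c("mean", "cv"), sep = "_")
    data.table::setnames(wide, names(wide), tolower(names(wide)))
    wide[, participant_id := as.character(participant_id)]
    panel <- merge(panel, wide, by = "participant_id", all.x = TRUE,
                   sort = FALSE)
  }
  data.table::setorderv(panel, "participant_id")
  panel[]
}
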