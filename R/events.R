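# Event consolidation: master event table across assessment-centre fields,
# hospital admissions, death records and primary care; date cleaning;
# outcome-specific extraction; cross-source merging; first occurrences.

#' Event source labels
#' @export
EVENT_SOURCES <- c("FIRST_OCC_FIELD", "ALGO_FIELD", "HOSPITAL", "DEATH",
                   "SELF_REPORT", "PRIMARY_CARE", "CUSTOM_FIELD",
                   "BIOMARKER_DERIVED")

# Fixed tie-break priority when several sources share the minimal event date.
# Arbitrary but deterministic; the date itself is unaffected.
SOURCE_PRIORITY <- c(PRIMARY_CARE = 1, HOSPITAL = 2, DEATH = 3,
                     SELF_REPORT = 4, FIRST_OCC_FIELD = 5, ALGO_FIELD = 6,
                     CUSTOM_FIELD = 7, BIOMARKER_DERIVED = 8)

new_event_records <- function(participant_id, source, system, code, date) {
  data.table::data.table(
    participant_id = as.character(participant_id),
    source = as.character(source),
    system = as.character(system),
    code = as.character(code),
    date = as_date_col(date),
    valid = !is.na(as_date_col(date)),
    invalid_reason = data.table::fifelse(is.na(as_date_col(date)),
                                         "missing_date", NA_character_))
}

#' Build the master event table
#'
#' Unpivots the wide assessment-centre table into one dated event record per
#' non-missing code cell (per the field map), and appends hospital admission
#' and death record events. Records with a missing date are kept but flagged
#' `valid = FALSE` (reason `missing_date`); nothing is dropped.
#'
#' @param assessment_table wide table with a `participant_id` column plus the
#'   code/date columns named in `field_map`.
#' @param hospital_table long table `participant_id`, `date`, `system`
#'   (`ICD10`/`OPCS4`), `code`.
#' @param death_table long table `participant_id`, `date`, `code` (ICD-10
#'   underlying cause).
#' @param field_map table describing assessment columns, with columns:
#'   `code_field` (name of the column holding the code; `NA` for fields whose
#'   identity is itself the "code", e.g. first-occurrence date fields),
#'   `date_field` (name of the column holding the event date), `source`
#'   (an [EVENT_SOURCES] label), `system` (code system), `code` (constant
#'   code to use when `code_field` is `NA`).
#' @return an event-record `data.table` with columns `participant_id`,
#'   `source`, `system`, `code`, `date`, `valid`, `invalid_reason`.
#' @export
build_master_event_table <- function(assessment_table, hospital_table = NULL,
                                     death_table = NULL, field_map = NULL) {
  out <- list()
  if (!is.null(field_map)) {
    fm <- data.table::as.data.table(field_map)
    assert_cols(fm, c("code_field", "date_field", "source", "system"),
                "field_map")
    if (!"code" %in% names(fm)) fm[, code := NA_character_]
    at <- data.table::as.data.table(assessment_table)
    assert_cols(at, "participant_id", "assessment table")
    named <- stats::na.omit(c(fm$code_field, fm$date_field))
    missing_fields <- setdiff(named, names(at))
    if (length(missing_fields)) {
      stop(sprintf("field_map names column(s) absent from the assessment table: %s",
                   paste(missing_fields, collapse = ", ")), call. = FALSE)
    }
    for (i in seq_len(nrow(fm))) {
      dates <- as_date_col(at[[fm$date_field[i]]])
      if (is.na(fm$code_field[i])) {
        codes <- rep(fm$code[i], nrow(at))
        keep <- !is.na(dates)
      } else {
        codes <- as.character(at[[fm$code_field[i]]])
        keep <- !is.na(codes) & nzchar(codes)
      }
      if (!any(keep)) next
      out[[length(out) + 1L]] <- new_event_records(
        at$participant_id[keep], fm$source[i], fm$system[i],
        codes[keep], dates[keep])
    }
  }
  if (!is.null(hospital_table) && nrow(hospital_table)) {
    ht <- data.table::as.data.table(hospital_table)
    assert_cols(ht, c("participant_id", "date", "system", "code"),
                "hospital table")
    out[[length(out) + 1L]] <- new_event_records(
      ht$participant_id, "HOSPITAL", ht$system, ht$code, ht$date)
  }
  if (!is.null(death_table) && nrow(death_table)) {
    dt <- data.table::as.data.table(death_table)
    assert_cols(dt, c("participant_id", "date", "code"), "death table")
    out[[length(out) + 1L]] <- new_event_records(
      dt$participant_id, "DEATH", "ICD10", dt$code, dt$date)
  }
  if (!length(out)) {
    return(new_event_records(character(), character(), character(),
                             character(), as.Date(character())))
  }
  data.table::rbindlist(out)[]
}

#' Convert a primary-care clinical table to event records
#'
#' @param gp_table long table with `participant_id`, `date`, `system`, `code`.
#' @param source source label, default `PRIMARY_CARE`.
#' @return event-record `data.table`.
#' @export
as_event_records <- function(gp_table, source = "PRIMARY_CARE") {
  gp <- data.table::as.data.table(gp_table)
  assert_cols(gp, c("participant_id", "date", "system", "code"), "gp table")
  new_event_records(gp$participant_id, source, gp$system, gp$code, gp$date)
}

#' Default placeholder dates
#'
#' Administrative placeholder dates conventionally used in UK Biobank-style
#' extracts to encode unknown or special dates.
#' @export
DEFAULT_PLACEHOLDER_DATES <- as.Date(c("1900-01-01", "1901-01-01",
                                       "1902-02-02", "1903-03-03",
                                       "2037-07-07"))

#' Flag implausible event dates
#'
#' Marks records whose date is a configured placeholder, precedes the
#' participant's birth date, or falls outside the plausibility window. Rows
#' are never deleted; invalidation is flag-based so the audit trail is
#' preserved. Reason precedence: `placeholder`, then `pre_birth`, then
#' `out_of_window`; already-invalid records are untouched.
#'
#' @param records event-record table.
#' @param birth_dates optional table `participant_id`, `birth_date`.
#' @param plausibility_window length-2 date vector (inclusive bounds).
#' @param placeholder_dates vector of placeholder dates.
#' @return the records with updated `valid`/`invalid_reason`.
#' @export
clean_dates <- function(records,
                        birth_dates = NULL,
                        plausibility_window = as.Date(c("1910-01-01", "2025-12-31")),
                        placeholder_dates = DEFAULT_PLACEHOLDER_DATES) {
  rec <- data.table::copy(data.table::as.data.table(records))
  plausibility_window <- as_date_col(plausibility_window)
  placeholder_dates <- as_date_col(placeholder_dates)
  newly <- function(cond) cond & rec$valid
  ph <- newly(!is.na(rec$date) & rec$date %in% placeholder_dates)
  rec[ph, `:=`(valid = FALSE, invalid_reason = "placeholder")]
  if (!is.null(birth_dates)) {
    bd <- data.table::as.data.table(birth_dates)
    assert_cols(bd, c("participant_id", "birth_date"), "birth_dates")
    bd <- bd[, list(participant_id = as.character(participant_id),
                    birth_date = as_date_col(birth_date))]
    rec[bd, birth_date := i.birth_date, on = "participant_id"]
    pb <- newly(!is.na(rec$date) & !is.na(rec$birth_date) &
                  rec$date < rec$birth_date)
    rec[pb, `:=`(valid = FALSE, invalid_reason = "pre_birth")]
    rec[, birth_date := NULL]
  }
  ow <- newly(!is.na(rec$date) &
                (rec$date < plausibility_window[1] |
                   rec$date > plausibility_window[2]))
  rec[ow, `:=`(valid = FALSE, invalid_reason = "out_of_window")]
  rec[]
}

#' Extract outcome-specific events
#'
#' Joins valid event records against a role-tagged codelist, keeping records
#' whose `(system, code)` carries one of the requested roles. The matched
#' role is carried on the output.
#'
#' @param records event-record table (only `valid` records can match).
#' @param codelist a [new_codelist()] object.
#' @param roles roles to extract, subset of [CODE_ROLES].
#' @return outcome event `data.table` with an `outcome_id` attribute.
#' @export
extract_outcome_events <- function(records, codelist,
                                   roles = c("DEFINING", "DATE_ONLY")) {
  if (is.null(codelist) || nrow(codelist) == 0L) {
    stop("codelist is empty", call. = FALSE)
  }
  stopifnot(all(roles %in% CODE_ROLES))
  rec <- data.table::as.data.table(records)
  cl <- data.table::as.data.table(codelist)[role %in% roles,
                                            list(system, code, role)]
  out <- merge(rec[valid == TRUE], cl, by = c("system", "code"),
               allow.cartesian = FALSE)
  data.table::setcolorder(out, c("participant_id", "source", "system", "code",
                                 "date", "valid", "invalid_reason", "role"))
  data.table::setattr(out, "outcome_id", attr(codelist, "outcome_id"))
  out[]
}

#' Merge outcome event tables across sources
#'
#' Concatenates outcome event tables (e.g. assessment-centre-derived, primary
#' care, biomarker-derived) for the same outcome, preserving `source` and
#' collapsing exact duplicate `(participant, date, system, code)` rows. When
#' duplicates differ in source, the highest-priority source label is kept
#' (see `SOURCE_PRIORITY`).
#'
#' @param ... outcome event tables, each carrying an `outcome_id` attribute.
#' @return merged `data.table` with the common `outcome_id` attribute.
#' @export
merge_outcome_events <- function(...) {
  tabs <- Filter(Negate(is.null), list(...))
  stopifnot(length(tabs) >= 1L)
  ids <- unique(unlist(lapply(tabs, function(t) attr(t, "outcome_id") %||% NA_character_)))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1L) {
    stop(sprintf("outcome_id mismatch across tables: %s",
                 paste(ids, collapse = " vs ")), call. = FALSE)
  }
  all <- data.table::rbindlist(lapply(tabs, data.table::as.data.table),
                               use.names = TRUE, fill = TRUE)
  all[, .priority := SOURCE_PRIORITY[source]]
  data.table::setorderv(all, c("participant_id", "date", "system", "code",
                               ".priority"))
  out <- unique(all, by = c("participant_id", "date", "system", "code"))
  out[, .priority := NULL]
  data.table::setattr(out, "outcome_id",
                      if (length(ids)) ids else NA_character_)
  out[]
}

#' Resolve per-participant first occurrences
#'
#' Computes, per participant, the earliest valid event date over events whose
#' role is in `role_filter`. `DATE_ONLY` events contribute a date only for
#' participants who also carry at least one `DEFINING`-role event (the
#' two-category rule: date-only codes refine the incidence date but never by
#' themselves classify a participant as having the outcome). The reported
#' source is that of the minimal-date record, ties broken by the fixed
#' source-priority order.
#'
#' @param merged_events merged outcome event table for one outcome.
#' @param outcome_id outcome identifier (defaults to the table's attribute).
#' @param role_filter roles allowed to contribute dates.
#' @return `data.table` `participant_id`, `outcome_id`, `date`, `source`,
#'   one row per participant with at least one qualifying event.
#' @export
first_occurrence <- function(merged_events,
                             outcome_id = attr(merged_events, "outcome_id"),
                             role_filter = c("DEFINING", "DATE_ONLY")) {
  ev <- data.table::as.data.table(merged_events)
  if (!nrow(ev)) {
    return(data.table::data.table(participant_id = character(),
                                  outcome_id = character(),
                                  date = as.Date(character()),
                                  source = character()))
  }
  ev <- ev[valid == TRUE & role %in% role_filter & !is.na(date)]
  if ("DATE_ONLY" %in% role_filter) {
    qualified <- unique(ev[role == "DEFINING", participant_id])
    ev <- ev[role != "DATE_ONLY" | participant_id %in% qualified]
  }
  # a participant qualifies only via a DEFINING event when DEFINING is requested
  if ("DEFINING" %in% role_filter) {
    ev <- ev[participant_id %in% unique(ev[role == "DEFINING", participant_id])]
  }
  if (!nrow(ev)) {
    return(data.table::data.table(participant_id = character(),
                                  outcome_id = character(),
                                  date = as.Date(character()),
                                  source = character()))
  }
  ev[, .priority := SOURCE_PRIORITY[source]]
  data.table::setorderv(ev, c("participant_id", "date", ".priority"))
  fo <- ev[, list(date = date[1L], source = source[1L]), by = "participant_id"]
  fo[, outcome_id := outcome_id %||% NA_character_]
  data.table::setcolorder(fo, c("participant_id", "outcome_id", "date", "source"))
  fo[]
}
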