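mk_dm_events <- function(df) {
  x <- data.table::as.data.table(df)
  x[, `:=`(source = "PRIMARY_CARE", valid = TRUE,
           invalid_reason = NA_character_)]
  data.table::setattr(x, "outcome_id", "DM")
  x
}

test_that("classify_diabetes follows the code-specificity rule", {
  tc <- fixture_dm_type_codes()
  ev <- mk_dm_events(data.table::data.table(
    participant_id = c("A", "B", "B", "C", "D"),
    system = "READ_V2",
    code = c("C108.", "C108.", "C109.", "C10..", "66A.."),
    date = days(1:5),
    role = c("DEFINING", "DEFINING", "DEFINING", "DEFINING", "DATE_ONLY")))
  out <- classify_diabetes(ev, tc)
  expect_equal(out[participant_id == "A", dm_type], "T1D")     # only T1D codes
  expect_equal(out[participant_id == "B", dm_type], "UNCERTAIN") # both types
  expect_equal(out[participant_id == "C", dm_type], "UNCERTAIN") # generic only
  expect_false("D" %in% out$participant_id)  # DATE_ONLY only: not assigned
  expect_true(all(!is.na(out$first_evidence_date)))
})

test_that("compute_censor_date takes the earliest available date", {
  expect_equal(compute_censor_date(NULL, as.Date("2016-05-01"),
                                   as.Date("2017-12-31")),
               as.Date("2016-05-01"))
  expect_equal(compute_censor_date(as.Date("2015-01-01"), NULL,
                                   as.Date("2017-12-31")),
               as.Date("2015-01-01"))
  expect_equal(compute_censor_date(NULL, NULL, as.Date("2017-12-31")),
               as.Date("2017-12-31"))
  expect_error(compute_censor_date(NULL, NULL, as.Date(NA)), "present")
})

basic_inputs <- function() {
  list(
    dm = data.table::data.table(participant_id = c("P1", "P2"),
                                dm_type = "T2D",
                                first_evidence_date = as.Date("2000-06-15")),
    fo = data.table::data.table(participant_id = "P1", outcome_id = "CVD",
                                date = as.Date("2012-01-01"),
                                source = "HOSPITAL"),
    ci = data.table::data.table(participant_id = c("P1", "P2"),
                                censor_date = as.Date("2018-01-01")),
    ix = data.table::data.table(participant_id = c("P1", "P2"),
                                index_date = as.Date("2008-01-01")))
}

test_that("build_initial_tte sets status and follow-up time", {
  b <- basic_inputs()
  tte <- build_initial_tte(b$dm, b$fo, b$ci, b$ix, "CVD")
  p1 <- tte[participant_id == "P1"]
  expect_equal(p1$status, 1L)
  expect_equal(p1$time_years, 4, tolerance = 0.01)
  p2 <- tte[participant_id == "P2"]
  expect_equal(p2$status, 0L)
  expect_equal(p2$time_years, 10, tolerance = 0.01)
  # missing index date -> missing_admin
  b$ix$index_date[2] <- NA
  tte2 <- build_initial_tte(b$dm, b$fo, b$ci, b$ix, "CVD")
  expect_equal(tte2[participant_id == "P2", exclusion_reason], "missing_admin")
})

test_that("refine_tte flags rule violations in precedence order", {
  b <- basic_inputs()
  tte <- build_initial_tte(b$dm, b$fo, b$ci, b$ix, "CVD")
  # event before first diabetes evidence
  t1 <- data.table::copy(tte)[participant_id == "P1",
                              event_date := as.Date("1999-01-01")]
  expect_equal(refine_tte(t1)[participant_id == "P1", exclusion_reason],
               "event_before_dm")
  # event after censoring
  t2 <- data.table::copy(tte)[participant_id == "P1",
                              event_date := as.Date("2019-01-01")]
  expect_equal(refine_tte(t2)[participant_id == "P1", exclusion_reason],
               "event_after_censor")
  # exclusion-coded condition on record
  ex <- data.table::data.table(participant_id = "P1",
                               date = as.Date("2010-01-01"))
  expect_equal(refine_tte(tte, ex)[participant_id == "P1", exclusion_reason],
               "exclusion_condition")
  # a row violating several rules gets only the first reason
  t3 <- data.table::copy(t1)
  out <- refine_tte(t3, ex)
  expect_equal(out[participant_id == "P1", exclusion_reason],
               "event_before_dm")
})

test_that("apply_prospective_design applies the index/landmark rules", {
  cfg <- cohort_config("DKD")
  mk <- function(dm, index, event, censor = "2018-01-01", pc = TRUE) {
    ev <- as.Date(if (is.null(event)) NA else event)
    status <- as.integer(!is.na(ev) && ev <= as.Date(censor))
    end <- if (!is.na(ev)) ev else as.Date(censor)
    data.table::data.table(
      participant_id = "X", outcome_id = "DKD",
      index_date = as.Date(index),
      dm_first_evidence_date = as.Date(dm),
      event_date = ev,
      censor_date = as.Date(censor),
      status = status,
      time_years = as.numeric(end - as.Date(index)) / 365.25,
      has_primary_care = pc, excluded = FALSE,
      exclusion_reason = NA_character_)
  }
  # event row where the index precedes first diabetes evidence
  r <- apply_prospective_design(mk("2010-01-01", "2008-01-01", "2012-06-01"),
                                cfg)
  expect_equal(r$exclusion_reason, "index_not_between")
  # DKD event less than 5 years after first diabetes evidence
  r2 <- apply_prospective_design(mk("2010-01-01", "2010-06-01", "2013-01-01"),
                                 cfg)
  expect_equal(r2$exclusion_reason, "short_dm_to_event")
  # non-event with diabetes evidenced within 6 months after index: retained
  r3 <- apply_prospective_design(mk("2009-03-01", "2009-01-01", NULL), cfg)
  expect_false(r3$excluded)
  # non-event with diabetes later than 6 months after index
  r4 <- apply_prospective_design(mk("2009-08-15", "2009-01-01", NULL), cfg)
  expect_equal(r4$exclusion_reason, "dm_after_landmark")
  # primary-care requirement with an externally documented event
  r5 <- apply_prospective_design(mk("2000-01-01", "2008-01-01", "2012-06-01",
                                    pc = FALSE), cfg,
                                 external_outcome_ids = "X")
  expect_false(r5$excluded)
  r6 <- apply_prospective_design(mk("2000-01-01", "2008-01-01", NULL,
                                    pc = FALSE), cfg)
  expect_equal(r6$exclusion_reason, "no_primary_care")
  expect_error(apply_prospective_design(mk("2000-01-01", "2008-01-01", NULL),
                                        cohort_config("CVD")), "outcome")
})

test_that("weakening thresholds never shrinks the retained set", {
  fx <- generate_rule_fixture()
  strict <- build_cohort(fx$dm_assignments, fx$first_occurrence,
                         fx$exclusion_events, fx$censor_info, fx$index_dates,
                         fx$has_primary_care, fx$external_outcome_ids,
                         "DKD", cohort_config("DKD"))
  weak <- build_cohort(fx$dm_assignments, fx$first_occurrence,
                       fx$exclusion_events, fx$censor_info, fx$index_dates,
                       fx$has_primary_care, fx$external_outcome_ids,
                       "DKD", cohort_config("DKD",
                                            require_primary_care = FALSE,
                                            min_years_dm_to_event = 0,
                                            min_years_dm_followup = 0))
  kept_strict <- strict[excluded == FALSE, participant_id]
  kept_weak <- weak[excluded == FALSE, participant_id]
  expect_true(all(kept_strict %in% kept_weak))
  # every excluded row has exactly one reason, and counts sum correctly
  expect_true(all(!is.na(strict[excluded == TRUE, exclusion_reason])))
  expect_true(all(is.na(strict[excluded == FALSE, exclusion_reason])))
  expect_equal(sum(exclusion_summary(strict)$N), sum(strict$excluded))
})

test_that("retained rows satisfy the design invariants", {
  res <- quiet(generate_cohort(sim_config(n = 400, seed = 19)))
  for (oc in c("CVD", "DKD")) {
    exp <- expected_cohort(res$truth, oc)
    keep <- merge(exp[excluded == FALSE], res$truth, by = "participant_id")
    expect_true(all(as.numeric(keep$dm_onset - keep$index_date) <= 182.625))
    ev <- keep[status == 1]
    edate <- ev[[paste0("event_date_", tolower(oc))]]
    expect_true(all(ev$index_date <= edate & edate <= ev$censor_date))
  }
})

test_that("incidence_rate matches the closed form and exact Poisson CI", {
  co <- data.table::data.table(outcome_id = "CVD",
                               status = c(1L, 1L, rep(0L, 8)),
                               time_years = rep(10, 10),
                               excluded = FALSE)
  r <- incidence_rate(co)
  expect_equal(r$rate_per_1000, 20)
  expect_equal(r$n_events, 2L)
  # zero events: rate 0 with CI lower bound 0
  co0 <- data.table::copy(co)[, status := 0L]
  r0 <- incidence_rate(co0)
  expect_equal(r0$rate_per_1000, 0)
  expect_equal(r0$ci_low, 0)
  expect_gt(r0$ci_high, 0)
  expect_error(incidence_rate(co[0]), "unexcluded")
})
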