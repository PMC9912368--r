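test_that("extract_trajectories harmonises units and flags implausible values", {
  pc <- data.table::data.table(
    participant_id = "P1", date = days(c(10, 5)),
    system = "READ_V2", code = "44g1.",
    value = c(126, 7.2), unit = c("mg/dL", "mmol/L"))
  am <- data.table::data.table(participant_id = "P1", date = days(0),
                               biomarker = "SBP", value = 1200,
                               unit = "mmHg")
  tr <- extract_trajectories(pc, am, fixture_biomarker_code_map(),
                             fixture_unit_rules())
  glu <- tr[biomarker == "GLUCOSE"]
  # 126 mg/dL x 0.0555 = 6.993 mmol/L
  expect_equal(glu[date == days(10), value], 6.993)
  # assessment + GP rows interleave into one per-biomarker date-sorted trajectory
  expect_equal(glu$date, sort(glu$date))
  expect_equal(glu[1, value], 7.2)
  # SBP 1200 outside [40, 300] flagged invalid, not dropped
  expect_false(tr[biomarker == "SBP", valid])
  expect_equal(nrow(tr), 3L)

  pc_bad <- data.table::copy(pc)[1, unit := "furlongs"]
  expect_error(extract_trajectories(pc_bad, NULL,
                                    fixture_biomarker_code_map(),
                                    fixture_unit_rules()),
               "furlongs")
})

test_that("compute_egfr reproduces the CKD-EPI 2009 worked examples", {
  # male, 40y, Scr 0.9 = kappa: both min/max terms are 1
  expect_equal(compute_egfr(0.9, 40, "male"), 141 * 0.993^40)
  expect_equal(round(compute_egfr(0.9, 40, "male"), 1), 106.5)
  # female, 50y, Scr 0.7 = kappa
  expect_equal(compute_egfr(0.7, 50, "female"), 141 * 0.993^50 * 1.018)
  expect_equal(round(compute_egfr(0.7, 50, "female"), 1), 101.0)
  # micromol/L inputs divide by 88.4 first
  expect_equal(compute_egfr(0.9 * 88.4, 40, "male", units = "umol/L"),
               compute_egfr(0.9, 40, "male"))
  # race coefficient
  expect_equal(compute_egfr(0.9, 40, "male", black = TRUE),
               141 * 0.993^40 * 1.159)
  expect_equal(compute_egfr(0.9, 40, "male", black = TRUE,
                            use_race_term = FALSE),
               141 * 0.993^40)
  expect_error(compute_egfr(0, 40, "male"), "positive")
})

test_that("compute_egfr is strictly decreasing in creatinine and age", {
  scr <- seq(0.3, 5, length.out = 60)
  for (sex in c("male", "female")) {
    e <- compute_egfr(scr, 55, sex)
    expect_true(all(diff(e) < 0))
    ages <- seq(25, 90, length.out = 60)
    e2 <- compute_egfr(1.1, ages, sex)
    expect_true(all(diff(e2) < 0))
  }
})

test_that("compute_uacr pairs albumin with nearest creatinine in the window", {
  alb <- data.table::data.table(participant_id = "P1", date = days(0),
                                value = 30)
  cre <- data.table::data.table(participant_id = "P1", date = days(0),
                                value = 10)
  out <- quiet(compute_uacr(alb, cre))
  expect_equal(out$value, 3.0)
  expect_equal(out$biomarker, "UACR")

  # nearest creatinine 40 days away with a 7-day window: skipped
  cre40 <- data.table::data.table(participant_id = "P1", date = days(40),
                                  value = 10)
  expect_equal(nrow(quiet(compute_uacr(alb, cre40))), 0L)
  # zero creatinine: pair skipped
  cre0 <- data.table::data.table(participant_id = "P1", date = days(0),
                                 value = 0)
  expect_equal(nrow(quiet(compute_uacr(alb, cre0))), 0L)
  # tie resolves to the earlier creatinine date
  cre_tie <- data.table::data.table(participant_id = "P1",
                                    date = days(c(-2, 2)), value = c(5, 20))
  expect_equal(quiet(compute_uacr(alb, cre_tie))$value, 6)
})

test_that("compute_uacr equals brute-force nearest-date pairing", {
  set.seed(8)
  alb <- data.table::data.table(
    participant_id = sample(sprintf("P%d", 1:20), 100, replace = TRUE),
    date = days(sample(0:700, 100, replace = TRUE)),
    value = stats::runif(100, 5, 200))
  cre <- data.table::data.table(
    participant_id = sample(sprintf("P%d", 1:20), 100, replace = TRUE),
    date = days(sample(0:700, 100, replace = TRUE)),
    value = stats::runif(100, 2, 20))
  got <- quiet(compute_uacr(alb, cre, pairing_window_days = 14))
  # brute force
  n_expected <- 0
  for (i in seq_len(nrow(alb))) {
    cand <- cre[participant_id == alb$participant_id[i]]
    cand <- cand[abs(as.numeric(date - alb$date[i])) <= 14]
    if (!nrow(cand)) next
    cand <- cand[order(abs(as.numeric(date - alb$date[i])), date)]
    n_expected <- n_expected + 1
    ratio <- alb$value[i] / cand$value[1]
    expect_true(any(abs(got$value - ratio) < 1e-12))
  }
  expect_equal(nrow(got), n_expected)
})

test_that("albuminuria events fire at first threshold crossings", {
  tr <- data.table::data.table(participant_id = "P1", date = days(c(0, 30)),
                               value = c(2.0, 3.5))
  ev <- detect_albuminuria_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "MICROALBUMINURIA")
  expect_equal(ev$date, days(30))

  # single measurement over both thresholds: both events, same date
  tr2 <- data.table::data.table(participant_id = "P1", date = days(0),
                                value = 35)
  ev2 <- detect_albuminuria_events(tr2)
  expect_setequal(ev2$kind, c("MICROALBUMINURIA", "MACROALBUMINURIA"))
  expect_true(all(ev2$date == days(0)))

  # all below micro: nothing
  tr3 <- data.table::data.table(participant_id = "P1", date = days(0:2),
                                value = c(1, 2, 2.5))
  expect_equal(nrow(detect_albuminuria_events(tr3)), 0L)
  # re-running detection is idempotent
  expect_identical(detect_albuminuria_events(tr), ev)
})

test_that("prolonged low eGFR requires an uninterrupted 90-day run", {
  tr <- function(v, d) data.table::data.table(participant_id = "P1",
                                              date = days(d), value = v)
  ev <- detect_prolonged_low_egfr(tr(c(55, 58), c(0, 100)))
  expect_equal(ev$date, days(100))
  expect_equal(ev$kind, "LOW_EGFR_PROLONGED")
  # interruption resets the run
  expect_equal(nrow(detect_prolonged_low_egfr(tr(c(55, 65, 55),
                                                 c(0, 50, 100)))), 0L)
  # single low measurement: span unmet
  expect_equal(nrow(detect_prolonged_low_egfr(tr(55, 0))), 0L)
  # event date is the confirming (not the first) measurement
  ev2 <- detect_prolonged_low_egfr(tr(c(55, 50, 58), c(0, 50, 95)))
  expect_equal(ev2$date, days(95))
})

test_that("summarize_landmark computes windowed means and CVs", {
  tr <- data.table::data.table(participant_id = "P1", biomarker = "SBP",
                               date = days(0:2), value = c(1, 2, 3))
  s <- summarize_landmark(tr, days(0), days(10))
  expect_equal(s$mean, 2)
  expect_equal(s$cv, 0.5)
  # single value: CV missing
  s1 <- summarize_landmark(tr[1], days(0), days(10))
  expect_equal(s1$mean, 1)
  expect_true(is.na(s1$cv))
  # CV is scale invariant
  tr2 <- data.table::copy(tr)[, value := value * 7.3]
  expect_equal(summarize_landmark(tr2, days(0), days(10))$cv, 0.5)
  expect_error(summarize_landmark(tr, days(10), days(0)), "window_start")
})

test_that("summarize_landmark equals brute-force filter-then-moments", {
  set.seed(12)
  tr <- data.table::data.table(
    participant_id = sample(sprintf("P%d", 1:15), 400, replace = TRUE),
    biomarker = sample(c("SBP", "GLUCOSE"), 400, replace = TRUE),
    date = days(sample(0:1000, 400, replace = TRUE)),
    value = stats::runif(400, 1, 200))
  for (rep in 1:3) {
    w0 <- days(sample(0:400, 1)); w1 <- w0 + sample(100:500, 1)
    s <- summarize_landmark(tr, w0, w1)
    sub <- tr[date >= w0 & date <= w1]
    oracle <- sub[, .(n = .N, m = mean(value),
                      cv = if (.N >= 2) stats::sd(value) / mean(value)
                           else NA_real_),
                  by = .(participant_id, biomarker)]
    m <- merge(s, oracle, by = c("participant_id", "biomarker"))
    expect_equal(nrow(m), nrow(oracle))
    expect_equal(m$n_measurements, m$n)
    expect_equal(m$mean, m$m)
    expect_equal(m$cv.x, m$cv.y)
  }
})
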