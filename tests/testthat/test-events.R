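test_that("build_master_event_table unpivots code cells with sources", {
  at <- data.table::data.table(
    participant_id = c("P1", "P2"),
    icd_code = c("I21", "E11"),
    icd_date = as.Date(c("2010-01-01", "2011-02-03")))
  fm <- data.table::data.table(code_field = "icd_code",
                               date_field = "icd_date",
                               source = "HOSPITAL", system = "ICD10",
                               code = NA_character_)
  rec <- build_master_event_table(at, field_map = fm)
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$source == "HOSPITAL"))
  expect_true(all(rec$valid))

  # missing date -> record kept but invalid
  at2 <- data.table::as.data.table(at)
  at2$icd_date[2] <- NA
  rec2 <- build_master_event_table(at2, field_map = fm)
  expect_equal(nrow(rec2), 2L)
  expect_false(rec2[participant_id == "P2", valid])
  expect_equal(rec2[participant_id == "P2", invalid_reason], "missing_date")

  expect_error(build_master_event_table(
    at[, .(participant_id, icd_code)], field_map = fm), "icd_date")
})

test_that("master event record count equals brute-force non-missing cell count", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    at <- data.table::data.table(participant_id = sprintf("P%02d", 1:n))
    fm <- list()
    for (f in 1:3) {
      cc <- paste0("code", f); dd <- paste0("date", f)
      at[[cc]] <- ifelse(stats::runif(n) < 0.4, NA_character_,
                         sample(LETTERS, n, replace = TRUE))
      at[[dd]] <- as.Date("2005-01-01") + sample(0:1000, n, replace = TRUE)
      fm[[f]] <- data.table::data.table(code_field = cc, date_field = dd,
                                        source = "SELF_REPORT",
                                        system = "SELF_REPORT_ILLNESS",
                                        code = NA_character_)
    }
    rec <- build_master_event_table(at, field_map = data.table::rbindlist(fm))
    oracle <- sum(!is.na(at$code1)) + sum(!is.na(at$code2)) +
      sum(!is.na(at$code3))
    expect_equal(nrow(rec), oracle)
  }
})

test_that("clean_dates flags placeholders, pre-birth and out-of-window dates", {
  rec <- as_event_records(data.table::data.table(
    participant_id = c("P1", "P2", "P3", "P4"),
    date = as.Date(c("1901-01-01", "1935-05-05", "2015-06-01", "1800-01-01")),
    system = "READ_V2", code = "C10.."))
  births <- data.table::data.table(participant_id = c("P1", "P2", "P3", "P4"),
                                   birth_date = as.Date("1940-01-01"))
  out <- clean_dates(rec, births)
  expect_equal(out$invalid_reason,
               c("placeholder", "pre_birth", NA, "pre_birth"))
  expect_equal(out$valid, c(FALSE, FALSE, TRUE, FALSE))
  # nothing deleted
  expect_equal(nrow(out), 4L)

  # out-of-window without birth dates
  out2 <- clean_dates(rec["P4" == participant_id])
  expect_equal(out2$invalid_reason, "out_of_window")
})

test_that("clean_dates invalidates exactly the injected placeholders", {
  set.seed(3)
  n <- 500
  rec <- as_event_records(data.table::data.table(
    participant_id = sprintf("P%03d", 1:n),
    date = as.Date("2000-01-01") + sample(0:5000, n, replace = TRUE),
    system = "READ_V2", code = "H33.."))
  k <- 37
  hit <- sample(n, k)
  rec$date[hit] <- sample(DEFAULT_PLACEHOLDER_DATES, k, replace = TRUE)
  out <- clean_dates(rec)
  expect_equal(sum(!out$valid), k)
  expect_true(all(out$invalid_reason[hit] == "placeholder"))
})

test_that("extract_outcome_events joins valid records against roles", {
  cl <- new_codelist(data.table::data.table(
    system = "READ_V2", code = c("C10..", "K05.."),
    description = c("dm", "ckd"), role = c("DEFINING", "EXCLUSION")), "X")
  rec <- as_event_records(data.table::data.table(
    participant_id = sprintf("P%d", 1:5),
    date = days(1:5),
    system = "READ_V2",
    code = c("C10..", "H33..", "K05..", "C10..", "G20..")))
  out <- extract_outcome_events(rec, cl, roles = "DEFINING")
  expect_equal(sort(out$participant_id), c("P1", "P4"))
  expect_true(all(out$role == "DEFINING"))
  excl <- extract_outcome_events(rec, cl, roles = "EXCLUSION")
  expect_equal(excl$participant_id, "P3")

  # invalid-dated matching record is excluded
  rec$valid[1] <- FALSE
  expect_equal(extract_outcome_events(rec, cl, roles = "DEFINING")$participant_id,
               "P4")
  expect_error(extract_outcome_events(rec, cl[0]), "empty")
})

test_that("merge_outcome_events collapses exact duplicates across sources", {
  mk <- function(ids, dates, src) {
    x <- data.table::data.table(participant_id = ids, source = src,
                                system = "READ_V2", code = "C10..",
                                date = dates, valid = TRUE,
                                invalid_reason = NA_character_,
                                role = "DEFINING")
    data.table::setattr(x, "outcome_id", "DM"); x
  }
  a <- mk(c("P1", "P2", "P3"), days(1:3), "PRIMARY_CARE")
  b <- mk(c("P4", "P5"), days(4:5), "HOSPITAL")
  expect_equal(nrow(merge_outcome_events(a, b)), 5L)
  # identical row in both collapses
  dup <- mk("P1", days(1), "HOSPITAL")
  m <- merge_outcome_events(a, dup)
  expect_equal(nrow(m), 3L)
  expect_equal(m[participant_id == "P1", source], "PRIMARY_CARE")

  bad <- data.table::copy(b); data.table::setattr(bad, "outcome_id", "CVD")
  expect_error(merge_outcome_events(a, bad), "mismatch")
})

test_that("merged row count equals brute-force union size", {
  for (rep in 1:5) {
    a <- random_events(30, 80, c("C10..", "C100."), seed = rep)
    b <- random_events(30, 80, c("C10..", "C100."), seed = rep + 50)
    b <- rbind(b, a[sample(.N, 20)])   # planted overlap
    data.table::setattr(a, "outcome_id", "DM")
    data.table::setattr(b, "outcome_id", "DM")
    m <- merge_outcome_events(a, b)
    oracle <- unique(rbind(a, b)[, .(participant_id, date, system, code)])
    expect_equal(nrow(m), nrow(oracle))
  }
})

test_that("first_occurrence applies the DATE_ONLY gating rule", {
  mk <- function(id, date, role) data.table::data.table(
    participant_id = id, source = "PRIMARY_CARE", system = "READ_V2",
    code = "C10..", date = as.Date(date), valid = TRUE,
    invalid_reason = NA_character_, role = role)
  # date-only event earlier than defining: date-only date wins
  ev <- rbind(mk("P1", "1999-03-01", "DATE_ONLY"),
              mk("P1", "2001-06-01", "DEFINING"),
              mk("P2", "2000-01-01", "DATE_ONLY"))   # date-only alone: no row
  fo <- first_occurrence(ev, outcome_id = "DM")
  expect_equal(nrow(fo), 1L)
  expect_equal(fo$participant_id, "P1")
  expect_equal(fo$date, as.Date("1999-03-01"))
})

test_that("first_occurrence ties break by fixed source priority", {
  ev <- data.table::data.table(
    participant_id = "P1",
    source = c("HOSPITAL", "PRIMARY_CARE", "DEATH"),
    system = "READ_V2", code = "C10..", date = days(0), valid = TRUE,
    invalid_reason = NA_character_, role = "DEFINING")
  expect_equal(first_occurrence(ev, "DM")$source, "PRIMARY_CARE")
})

test_that("first_occurrence equals brute-force minima on random tables", {
  ev <- random_events(200, 1500, c("C10..", "C100.", "66A.."), seed = 21)
  ev[code == "66A..", role := "DATE_ONLY"]
  ev[code != "66A..", role := "DEFINING"]
  fo <- first_occurrence(ev, outcome_id = "DM")
  # brute force per participant
  oracle <- list()
  for (id in unique(ev$participant_id)) {
    rows <- ev[participant_id == id]
    if (!any(rows$role == "DEFINING")) next
    oracle[[id]] <- min(rows$date)
  }
  expect_equal(nrow(fo), length(oracle))
  expect_equal(fo$date, unname(as.Date(unlist(oracle[fo$participant_id]),
                                       origin = "1970-01-01")))
})

test_that("first occurrence of a merge is the elementwise min of first occurrences", {
  a <- random_events(50, 300, c("C10..", "C100."), seed = 31,
                     roles = "DEFINING")
  b <- random_events(50, 300, c("C10..", "C100."), seed = 32,
                     roles = "DEFINING")
  data.table::setattr(a, "outcome_id", "DM")
  data.table::setattr(b, "outcome_id", "DM")
  fa <- first_occurrence(a, "DM"); fb <- first_occurrence(b, "DM")
  fm <- first_occurrence(merge_outcome_events(a, b), "DM")
  both <- intersect(fa$participant_id, fb$participant_id)
  expect_true(length(both) > 10)
  for (id in both) {
    expect_equal(fm[participant_id == id, date],
                 min(fa[participant_id == id, date],
                     fb[participant_id == id, date]))
  }
})
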