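# shared builders for small in-code fixtures

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

tiny_dict <- function() {
  data.table::data.table(
    system = c("READ_V2", "READ_V2", "READ_V2", "READ_V2", "CTV3"),
    code = c("C10..", "C100.", "C10E.", "H33..", "X40J4"),
    description = c("Diabetes mellitus",
                    "Diabetes mellitus with no mention of complication",
                    "Type 1 diabetes mellitus", "Asthma",
                    "Type 2 diabetes mellitus"))
}

# random code universe with Read-v2-style prefixes
random_dict <- function(n, seed) {
  set.seed(seed)
  roots <- c("C10", "C11", "H33", "K05", "G20", "F42")
  code <- vapply(seq_len(n), function(i) {
    r <- sample(roots, 1)
    depth <- sample(0:2, 1)
    suffix <- paste0(sample(c(LETTERS, 0:9), depth, replace = TRUE),
                     collapse = "")
    code <- paste0(r, suffix)
    paste0(code, strrep(".", max(0, 5 - nchar(code))))
  }, character(1))
  unique(data.table::data.table(system = "READ_V2", code = code,
                                description = paste("term", seq_len(n))))
}

random_events <- function(n_participants, n_events, codes, seed,
                          roles = c("DEFINING", "DATE_ONLY")) {
  set.seed(seed)
  data.table::data.table(
    participant_id = sprintf("P%04d", sample(n_participants, n_events,
                                             replace = TRUE)),
    source = sample(c("PRIMARY_CARE", "HOSPITAL", "DEATH", "SELF_REPORT"),
                    n_events, replace = TRUE),
    system = "READ_V2",
    code = sample(codes, n_events, replace = TRUE),
    date = as.Date("2000-01-01") + sample(0:6000, n_events, replace = TRUE),
    valid = TRUE,
    invalid_reason = NA_character_,
    role = sample(roles, n_events, replace = TRUE))
}

days <- function(x) as.Date("2010-01-01") + x
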