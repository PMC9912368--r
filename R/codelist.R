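# Codelist curation: master terminology dictionary, keyword search,
# Read v2 hierarchy expansion, Read v2 <-> CTV3 forward mapping, usage
# filtering and annotation-driven refinement into role-tagged codelists.

#' Recognised clinical code systems
#' @export
CODE_SYSTEMS <- c("READ_V2", "CTV3", "ICD10", "OPCS4",
                  "SELF_REPORT_ILLNESS", "SELF_REPORT_OPERATION",
                  "TPP_LOCAL", "UKB_FIELD")

#' Codelist entry roles
#'
#' `DEFINING` codes are sufficient on their own to classify a participant as
#' having the outcome; `DATE_ONLY` codes contribute only to the assignment of
#' the first incidence date for participants who also carry a defining code;
#' `EXCLUSION` codes mark conditions that remove a participant from the risk
#' set of the outcome.
#' @export
CODE_ROLES <- c("DEFINING", "DATE_ONLY", "EXCLUSION")

validate_code_table <- function(x, what = "code table") {
  assert_cols(x, c("system", "code"), what)
  x <- data.table::as.data.table(x)
  x[, system := as.character(system)]
  x[, code := as.character(code)]
  bad <- setdiff(unique(stats::na.omit(x$system)), CODE_SYSTEMS)
  if (length(bad)) {
    stop(sprintf("%s contains unknown code system(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.na(x$code) & !nzchar(x$code))) {
    stop(sprintf("%s contains empty codes", what), call. = FALSE)
  }
  x
}

#' Build the master terminology dictionary
#'
#' Combines several terminology tables (e.g. Read v2, CTV3 and TPP local
#' dictionaries) into one master dictionary. Duplicate `(system, code)` rows
#' are collapsed keeping the first description seen; the number of collapsed
#' duplicates is reported, and conflicting descriptions for the same code
#' raise a warning (not an error).
#'
#' @param dictionaries a list of tables, each with columns
#'   `system`, `code`, `description`.
#' @return a `data.table` with columns `system`, `code`, `description` and a
#'   `"n_collapsed"` attribute.
#' @export
build_master_dictionary <- function(dictionaries) {
  if (data.frame_like(dictionaries)) dictionaries <- list(dictionaries)
  tabs <- lapply(seq_along(dictionaries), function(i) {
    d <- dictionaries[[i]]
    assert_cols(d, c("system", "code", "description"),
                sprintf("dictionary %d", i))
    d <- validate_code_table(d, sprintf("dictionary %d", i))
    d[, list(system, code, description = as.character(description))]
  })
  all <- data.table::rbindlist(tabs)
  dup <- duplicated(all, by = c("system", "code"))
  n_collapsed <- sum(dup)
  # conflicting descriptions among duplicates -> warning
  if (n_collapsed > 0L) {
    conf <- all[, list(n_desc = data.table::uniqueN(description)),
                by = c("system", "code")][n_desc > 1L]
    if (nrow(conf)) {
      warning(sprintf(
        "%d (system, code) pair(s) have conflicting descriptions; keeping the first",
        nrow(conf)), call. = FALSE)
    }
  }
  out <- all[!dup]
  message(sprintf("master dictionary: %d entries (%d duplicate rows collapsed)",
                  nrow(out), n_collapsed))
  data.table::setattr(out, "n_collapsed", n_collapsed)
  out[]
}

data.frame_like <- function(x) is.data.frame(x)

#' Keyword search of a terminology dictionary
#'
#' Returns the dictionary entries whose description matches at least one
#' include keyword and no exclude keyword, plus any seed codes. Matching is
#' case-insensitive substring by default; set `regex = TRUE` to interpret
#' keywords as regular expressions. Exclude keywords take precedence over
#' include keywords.
#'
#' @param dict master dictionary (`system`, `code`, `description`).
#' @param include_keywords character vector of inclusion keywords.
#' @param exclude_keywords character vector of exclusion keywords.
#' @param seed_codes seed entries always included: either a character vector
#'   of codes or a table with `system`, `code` columns. Seeds absent from the
#'   dictionary are kept with an empty description.
#' @param regex interpret keywords as regular expressions.
#' @return `data.table` of candidate entries (`system`, `code`, `description`).
#' @export
search_terms <- function(dict, include_keywords, exclude_keywords = character(),
                         seed_codes = NULL, regex = FALSE) {
  dict <- validate_code_table(dict, "dictionary")
  include_keywords <- include_keywords[nzchar(include_keywords %||% character())]
  no_seeds <- is.null(seed_codes) || (length(seed_codes) == 0L) ||
    (is.data.frame(seed_codes) && nrow(seed_codes) == 0L)
  if (!length(include_keywords) && no_seeds) {
    stop("nothing to search: include keyword list and seed codes are both empty",
         call. = FALSE)
  }
  desc <- dict$description %||% character()
  match_kw <- function(kw) {
    # fixed = TRUE ignores ignore.case, so lower-case both sides for the
    # default substring mode
    if (regex) grepl(kw, desc, ignore.case = TRUE)
    else grepl(tolower(kw), tolower(desc), fixed = TRUE)
  }
  hit <- rep(FALSE, nrow(dict))
  for (kw in include_keywords) hit <- hit | match_kw(kw)
  for (kw in exclude_keywords[nzchar(exclude_keywords %||% character())]) {
    hit <- hit & !match_kw(kw)
  }
  out <- dict[hit, list(system, code, description)]
  if (!no_seeds) {
    if (is.character(seed_codes)) {
      seed_dt <- dict[code %in% seed_codes, list(system, code, description)]
      missing_seed <- setdiff(seed_codes, seed_dt$code)
      if (length(missing_seed)) {
        seed_dt <- rbind(seed_dt,
                         data.table::data.table(system = NA_character_,
                                                code = missing_seed,
                                                description = ""))
      }
    } else {
      seed_dt <- validate_code_table(seed_codes, "seed_codes")
      if (!"description" %in% names(seed_dt)) {
        seed_dt[, description := ""]
      }
      # prefer the dictionary description when present
      seed_dt <- merge(seed_dt[, list(system, code)],
                       dict, by = c("system", "code"), all.x = TRUE)
      seed_dt[is.na(description), description := ""]
    }
    out <- rbind(out, seed_dt[, list(system, code, description)])
  }
  unique(out, by = c("system", "code"))[]
}

strip_read_dots <- function(code) sub("\\.+$", "", code)

#' Expand Read v2 parent codes to all their children
#'
#' The Read v2 terminology is prefix-hierarchical on its 5-character codes:
#' after stripping trailing '.' padding, every code whose stripped form has a
#' stripped parent as a proper-or-equal prefix is a descendant of that parent.
#'
#' @param dict master dictionary.
#' @param parent_codes character vector of Read v2 parent codes.
#' @return `data.table` of all `READ_V2` entries at or below any parent.
#' @export
expand_children <- function(dict, parent_codes) {
  dict <- validate_code_table(dict, "dictionary")
  rv2 <- dict[system == "READ_V2"]
  known <- strip_read_dots(parent_codes) %in% strip_read_dots(rv2$code)
  if (any(!known)) {
    warning(sprintf("parent code(s) not in dictionary: %s (expanding by prefix anyway)",
                    paste(parent_codes[!known], collapse = ", ")), call. = FALSE)
  }
  stripped <- strip_read_dots(rv2$code)
  keep <- rep(FALSE, nrow(rv2))
  for (p in strip_read_dots(parent_codes)) {
    keep <- keep | startsWith(stripped, p)
  }
  rv2[keep, list(system, code, description)][]
}

#' Read a Read v2 to CTV3 mapping table
#'
#' @param path TSV with columns `read2_code`, `ctv3_code`.
#' @return `data.table` mapping table.
#' @export
read_mapping <- function(path) {
  m <- read_tsv(path)
  assert_cols(m, c("read2_code", "ctv3_code"), "mapping table")
  m
}

#' Augment a candidate code set with forward-mapped partner terms
#'
#' For every candidate code that appears in the Read v2 <-> CTV3 mapping
#' table, the partner code in the other terminology is added to the set
#' (Read v2 to CTV3, or vice versa). The number of additions is reported.
#'
#' @param codes candidate code set (`system`, `code`, `description`).
#' @param mapping table with columns `read2_code`, `ctv3_code`.
#' @param dict optional master dictionary used to fill partner descriptions.
#' @return augmented candidate `data.table`.
#' @export
forward_map <- function(codes, mapping, dict = NULL) {
  codes <- data.table::as.data.table(codes)
  if (is.null(mapping) || nrow(mapping) == 0L) {
    message("forward mapping: 0 terms added")
    return(codes[])
  }
  assert_cols(mapping, c("read2_code", "ctv3_code"), "mapping table")
  in_r2 <- codes[system == "READ_V2", code]
  in_c3 <- codes[system == "CTV3", code]
  add <- rbind(
    data.table::data.table(system = "CTV3",
                           code = mapping[read2_code %in% in_r2, ctv3_code]),
    data.table::data.table(system = "READ_V2",
                           code = mapping[ctv3_code %in% in_c3, read2_code]))
  add <- unique(add)
  # drop partners already present
  add <- add[!codes[, list(system, code)], on = c("system", "code")]
  if (nrow(add)) {
    if (!is.null(dict)) {
      dict <- validate_code_table(dict, "dictionary")
      add <- merge(add, dict, by = c("system", "code"), all.x = TRUE)
      add[is.na(description), description := ""]
    } else {
      add[, description := ""]
    }
  } else {
    add[, description := character(0)]
  }
  message(sprintf("forward mapping: %d term(s) added", nrow(add)))
  unique(rbind(codes[, list(system, code, description)],
               add[, list(system, code, description)]),
         by = c("system", "code"))[]
}

#' Retain only codes observed in a clinical event table
#'
#' @param codes candidate code set.
#' @param primary_care_events event table with `system`, `code` columns.
#' @return the subset of `codes` with at least one occurrence. Candidate rows
#'   with missing `system` (bare seed codes) are matched on code alone.
#' @export
filter_by_usage <- function(codes, primary_care_events) {
  codes <- data.table::as.data.table(codes)
  ev <- data.table::as.data.table(primary_care_events)
  assert_cols(ev, c("system", "code"), "event table")
  used <- unique(ev[, list(system = as.character(system),
                           code = as.character(code))])
  keep <- codes[, list(system, code)][used, on = c("system", "code"),
                                      nomatch = NULL]
  out <- codes[!is.na(system)][keep, on = c("system", "code"), nomatch = NULL]
  bare <- codes[is.na(system) & code %in% used$code]
  out <- unique(rbind(out, bare), by = c("system", "code"))
  message(sprintf("usage filter: %d of %d candidate term(s) occur in events",
                  nrow(out), nrow(codes)))
  out[]
}

#' Read a review-annotation file
#'
#' @param path TSV with columns `code`, `action`
#'   (`keep`, `drop`, `date_only`, `exclusion`).
#' @return `data.table`.
#' @export
read_annotations <- function(path) {
  a <- read_tsv(path)
  assert_cols(a, c("code", "action"), "annotation table")
  a
}

#' Apply expert-review annotations to finalise a codelist
#'
#' Expert review (exclusion of generic, rare or semantically distant terms,
#' and role assignment) is modelled as an annotation file mapping codes to
#' actions. `drop` removes the code; `keep` assigns the `DEFINING` role;
#' `date_only` and `exclusion` assign the corresponding roles. Unannotated
#' candidates default to `DEFINING` with a logged warning.
#'
#' @param codes candidate code set (`system`, `code`, `description`).
#' @param annotations table with columns `code`, `action`.
#' @param outcome_id identifier of the phenotype the codelist defines.
#' @return a `codelist` object: `data.table` with columns `system`, `code`,
#'   `description`, `role` and attribute `outcome_id`.
#' @export
apply_review_annotations <- function(codes, annotations, outcome_id = "outcome") {
  codes <- data.table::as.data.table(codes)
  ann <- data.table::as.data.table(annotations)
  assert_cols(ann, c("code", "action"), "annotation table")
  bad_action <- setdiff(unique(ann$action), c("keep", "drop", "date_only", "exclusion"))
  if (length(bad_action)) {
    stop(sprintf("unknown annotation action(s): %s",
                 paste(bad_action, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(ann$code, codes$code)
  if (length(unknown)) {
    stop(sprintf("annotation references code(s) not in the candidate set: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out <- merge(codes, ann, by = "code", all.x = TRUE, sort = FALSE)
  n_default <- sum(is.na(out$action))
  if (n_default > 0L) {
    warning(sprintf("%d unannotated candidate(s) default to role DEFINING",
                    n_default), call. = FALSE)
  }
  out[is.na(action), action := "keep"]
  out <- out[action != "drop"]
  out[, role := c(keep = "DEFINING", date_only = "DATE_ONLY",
                  exclusion = "EXCLUSION")[action]]
  out[, action := NULL]
  data.table::setcolorder(out, c("system", "code", "description", "role"))
  new_codelist(out, outcome_id)
}

#' Construct a codelist object
#'
#' @param entries table with columns `system`, `code`, `description`, `role`.
#' @param outcome_id phenotype identifier.
#' @return a `codelist` (`data.table` subclass).
#' @export
new_codelist <- function(entries, outcome_id) {
  x <- validate_code_table(entries, "codelist")
  assert_cols(x, c("system", "code", "description", "role"), "codelist")
  bad <- setdiff(unique(x$role), CODE_ROLES)
  if (length(bad)) {
    stop(sprintf("unknown role(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x, by = c("system", "code"))) {
    stop("a code appears more than once in the codelist", call. = FALSE)
  }
  # canonical (C-locale) entry order so codelists compare byte-exactly
  data.table::setorderv(x, c("system", "code"))
  data.table::setattr(x, "outcome_id", outcome_id)
  data.table::setattr(x, "class", c("codelist", class(x)))
  x
}

#' @export
print.codelist <- function(x, ...) {
  cat(sprintf("<codelist: %s> %d entries (%s)\n",
              attr(x, "outcome_id"), nrow(x),
              paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                    collapse = ", ")))
  print(data.table::as.data.table(x), ...)
  invisible(x)
}

#' Read / write codelists
#'
#' Codelist files are UTF-8 TSV with header
#' `system code description role`.
#'
#' @param path file path.
#' @param outcome_id phenotype identifier (read direction).
#' @return `read_codelist`: a `codelist`; `write_codelist`: `path`, invisibly.
#' @export
read_codelist <- function(path, outcome_id = tools::file_path_sans_ext(basename(path))) {
  x <- read_tsv(path)
  new_codelist(x, outcome_id)
}

#' @rdname read_codelist
#' @param x codelist to write.
#' @export
write_codelist <- function(x, path) {
  write_tsv(data.table::as.data.table(x)[, list(system, code, description, role)],
            path)
}

#' Run the full codelist curation pipeline
#'
#' Convenience wrapper chaining keyword search, Read v2 child expansion,
#' forward mapping, usage filtering and annotation refinement.
#'
#' @param dict master dictionary.
#' @param include_keywords,exclude_keywords keyword lists for [search_terms()].
#' @param parent_codes Read v2 parents for [expand_children()] (optional).
#' @param mapping Read v2/CTV3 mapping table (optional).
#' @param events event table for [filter_by_usage()] (optional; when `NULL`
#'   the usage filter is skipped).
#' @param annotations annotation table for [apply_review_annotations()].
#' @param outcome_id phenotype identifier.
#' @param seed_codes,regex passed to [search_terms()].
#' @return a `codelist`.
#' @export
curate_codelist <- function(dict, include_keywords, exclude_keywords = character(),
                            parent_codes = NULL, mapping = NULL, events = NULL,
                            annotations = NULL, outcome_id = "outcome",
                            seed_codes = NULL, regex = FALSE) {
  cand <- search_terms(dict, include_keywords, exclude_keywords,
                       seed_codes = seed_codes, regex = regex)
  if (!is.null(parent_codes) && length(parent_codes)) {
    cand <- unique(rbind(cand, expand_children(dict, parent_codes)),
                   by = c("system", "code"))
  }
  if (!is.null(mapping)) cand <- forward_map(cand, mapping, dict = dict)
  if (!is.null(events)) cand <- filter_by_usage(cand, events)
  if (is.null(annotations)) {
    annotations <- data.table::data.table(code = character(), action = character())
  }
  apply_review_annotations(cand, annotations, outcome_id = outcome_id)
}
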