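# Loaders for the miniature fixture terminology shipped with the package.
# The fixture dictionary is a ~50-code synthetic miniature with Read-v2-style
# prefixes (so hierarchy expansion is exercised); it is NOT a real
# terminology release and all curation keyword lists are illustrative.

#' Fixture terminology dictionary
#'
#' A synthetic miniature master dictionary covering Read v2, CTV3, ICD-10,
#' OPCS4, self-report and TPP-local systems, used by tests, examples and the
#' synthetic data generator.
#' @return `data.table` `system`, `code`, `description`.
#' @export
fixture_dictionary <- function() {
  read_tsv(ehrpheno_extdata("fixture_dictionary.tsv"))
}

#' Fixture Read v2 / CTV3 mapping table
#' @return `data.table` `read2_code`, `ctv3_code`.
#' @export
fixture_mapping <- function() {
  read_mapping(ehrpheno_extdata("fixture_mapping.tsv"))
}

#' Fixture outcome codelists
#'
#' Role-tagged codelists for the fixture phenotypes: `DM` (diabetes, with
#' `DATE_ONLY` monitoring codes), `CVD` (composite cardiovascular event),
#' `DKD` (kidney disease, with risk-set `EXCLUSION` codes) and `DR`
#' (retinopathy, with `EXCLUSION` codes).
#'
#' @param outcome one of `"DM"`, `"CVD"`, `"DKD"`, `"DR"`.
#' @return a `codelist`.
#' @export
fixture_codelist <- function(outcome = c("DM", "CVD", "DKD", "DR")) {
  outcome <- match.arg(outcome)
  read_codelist(ehrpheno_extdata(paste0("codelist_", tolower(outcome), ".tsv")),
                outcome_id = outcome)
}

#' Fixture diabetes type-specific code tags
#' @return `data.table` `system`, `code`, `dm_type` (`T1D`/`T2D`/`GENERIC`).
#' @export
fixture_dm_type_codes <- function() {
  read_tsv(ehrpheno_extdata("dm_type_codes.tsv"))
}

#' Fixture biomarker code map and unit rules
#' @return `data.table`.
#' @export
fixture_biomarker_code_map <- function() {
  read_tsv(ehrpheno_extdata("biomarker_code_map.tsv"))
}

#' @rdname fixture_biomarker_code_map
#' @export
fixture_unit_rules <- function() {
  read_tsv(ehrpheno_extdata("unit_rules.tsv"))
}
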