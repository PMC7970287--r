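# Instrument dictionaries are shipped as YAML under inst/extdata and
# cached per session; every scorer validates against them.

the <- new.env(parent = emptyenv())

#' Instrument dictionaries
#'
#' Returns the registered item dictionaries for the field instruments the
#' package scores: FCI (Family Care Indicators) subscales, the five ASQ
#' inventory domains, the 20-item CES-D with its reverse-coded key, the
#' CDI word inventories, and the maternal / child minimum-dietary-diversity
#' food-group lists.  The dictionaries are read once from the YAML shipped
#' with the package and cached.
#'
#' @param instrument Optional instrument name (`"fci"`, `"asqi"`, `"cesd"`,
#'   `"cdi"`, `"diet"`); if omitted the full dictionary list is returned.
#' @return A named list (the full dictionary, or one instrument's entry).
#' @export
#' @examples
#' names(instrument_dictionary())
#' instrument_dictionary("fci")$activities
instrument_dictionary <- function(instrument = NULL) {
  if (is.null(the$dict)) {
    path <- system.file("extdata", "instruments.yaml", package = "ecdtrial")
    the$dict <- yaml::read_yaml(path)
  }
  if (is.null(instrument)) {
    return(the$dict)
  }
  if (!instrument %in% names(the$dict)) {
    abort(paste0("unknown instrument: '", instrument, "'"))
  }
  the$dict[[instrument]]
}

# item-id helpers used by the simulator and the scorers
fci_item_ids <- function(subscale) instrument_dictionary("fci")[[subscale]]

asqi_domains <- function() instrument_dictionary("asqi")$domains

asqi_item_ids <- function(domain, n_items = NULL) {
  n <- n_items %||% instrument_dictionary("asqi")$items_per_domain
  paste0(domain, "_", seq_len(n))
}

cesd_item_ids <- function() paste0("cesd_", seq_len(instrument_dictionary("cesd")$n_items))

cdi_word_ids <- function(domain = c("receptive", "expressive")) {
  domain <- match.arg(domain)
  n <- instrument_dictionary("cdi")[[paste0("n_", domain)]]
  paste0(substr(domain, 1, 3), "_w", sprintf("%03d", seq_len(n)))
}

diet_groups <- function(role = c("maternal", "child")) {
  role <- match.arg(role)
  instrument_dictionary("diet")[[paste0(role, "_groups")]]
}

#' Registered covariate dictionary for adjusted analyses
#'
#' The ordered candidate-covariate list used by [prescreen_covariates()]
#' and [estimate_effects()]: parental education, child age and sex,
#' household income (median split), wall material, electricity, household
#' assets, the baseline measure of the outcome, and (for child development
#' and home-observation outcomes) interviewer.
#'
#' @param outcome Outcome name; used to resolve the baseline-measure column
#'   (`baseline_<outcome>`) and whether interviewer applies.
#' @param data Optional data frame; when given, candidates whose column is
#'   absent are dropped.
#' @return Character vector of candidate covariate column names, in
#'   registered order.
#' @export
candidate_covariates <- function(outcome, data = NULL) {
  interviewer_families <- c("fci_activities", "fci_materials", "fci_observation",
                            "asqi", "cdi")
  uses_interviewer <- any(vapply(interviewer_families, function(f) {
    startsWith(outcome, f)
  }, logical(1)))
  cands <- c("maternal_primary_education", "child_age_months", "child_sex",
             "household_income_above_median", "wall_material", "asset_count",
             "electricity", paste0("baseline_", outcome),
             if (uses_interviewer) "interviewer")
  if (!is.null(data)) cands <- intersect(cands, names(data))
  cands
}

`%||%` <- function(x, y) if (is.null(x)) y else x
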