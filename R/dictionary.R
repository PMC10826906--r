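#' Data dictionary for a cohort table
#'
#' Every non-identifier column of a cohort table must be declared exactly once
#' in a data dictionary. The dictionary drives schema validation in
#' [read_cohort()], component selection in [build_context_score()] (via the
#' `context_*` roles and risky/protective polarity), and the grouping of
#' outcomes into domains for FDR-family construction in [screen_battery()].
#'
#' @param variables data.frame with columns `variable_name`, `role`,
#'   `polarity`, `value_domain` and optionally `domain` (outcome domain:
#'   `behavioral`, `mental`, `cognitive`; brain variables take their domain
#'   from their role).
#' @return a validated `pse_dictionary` data.frame.
#' @export
data_dictionary <- function(variables) {
  req <- c("variable_name", "role", "polarity", "value_domain")
  missing_cols <- setdiff(req, names(variables))
  if (length(missing_cols)) {
    pse_schema_error(sprintf("dictionary lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  roles <- c("id", "demographic", "exposure", "context_birth", "context_family",
             "context_society", "context_genetic", "outcome", "brain_structure",
             "brain_function", "nuisance")
  bad <- setdiff(unique(variables$role), roles)
  if (length(bad)) {
    pse_schema_error(sprintf("unknown role(s): %s", paste(bad, collapse = ", ")))
  }
  pol <- c("risky", "protective", "neutral")
  badp <- setdiff(unique(variables$polarity), pol)
  if (length(badp)) {
    pse_schema_error(sprintf("unknown polarity value(s): %s",
                             paste(badp, collapse = ", ")))
  }
  dup <- variables$variable_name[duplicated(variables$variable_name)]
  if (length(dup)) {
    pse_integrity_error(sprintf("variable(s) declared more than once: %s",
                                paste(unique(dup), collapse = ", ")))
  }
  non_ctx <- !grepl("^context_", variables$role)
  off <- variables$variable_name[non_ctx & variables$polarity != "neutral"]
  if (length(off)) {
    pse_schema_error(sprintf(
      "polarity must be neutral for non-context variable(s): %s",
      paste(off, collapse = ", ")))
  }
  if (!"domain" %in% names(variables)) variables$domain <- NA_character_
  variables$domain[variables$role == "brain_structure"] <- "brain_structure"
  variables$domain[variables$role == "brain_function"]  <- "brain_function"
  structure(as.data.frame(variables, stringsAsFactors = FALSE),
            class = c("pse_dictionary", "data.frame"))
}

#' Read a data dictionary from a TSV file
#'
#' @param path path to a tab-separated file with the columns described in
#'   [data_dictionary()].
#' @return a `pse_dictionary`.
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) pse_io_error(sprintf("no such file: %s", path))
  data_dictionary(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a data dictionary to a TSV file
#' @param dictionary a `pse_dictionary`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  utils::write.table(dictionary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Expected storage type of a declared variable, parsed from the leading token
## of its value_domain description ("string", "integer ...", "numeric ...",
## "binary ...", "enum: a|b|c").
dict_type <- function(value_domain) {
  tok <- sub("^([a-z_]+).*$", "\\1", tolower(trimws(value_domain)))
  ifelse(tok %in% c("numeric", "integer", "binary"), "numeric",
         ifelse(tok %in% c("string", "enum"), "character", "character"))
}

#' Default data dictionary matching the synthetic cohort generator
#'
#' Declares identifiers, demographics, raw exposure-report fields, derived
#' exposure variables, context-score components (with risky/protective
#' polarity), the four composite context scores, the outcome battery with
#' domains, brain metrics, and nuisance covariates.
#'
#' @param extra_outcomes optional character vector of additional outcome
#'   variable names (declared as numeric, domain `"mental"`) so that generated
#'   batteries of arbitrary size validate.
#' @return a `pse_dictionary`.
#' @export
default_dictionary <- function(extra_outcomes = character()) {
  row <- function(name, role, polarity, vd, domain = NA_character_) {
    data.frame(variable_name = name, role = role, polarity = polarity,
               value_domain = vd, domain = domain, stringsAsFactors = FALSE)
  }
  d <- rbind(
    row("child_id",  "id", "neutral", "string"),
    row("family_id", "id", "neutral", "string"),
    row("site_id",   "id", "neutral", "string"),
    row("wave",      "id", "neutral", "enum: baseline|year2"),
    row("sex",            "demographic", "neutral", "enum: female|male"),
    row("race_ethnicity", "demographic", "neutral",
        "enum: Asian|Black|Hispanic|White|Other"),
    row("age_months",     "demographic", "neutral", "integer (months)"),
    ## raw exposure reports
    row("caffeine_use",  "exposure", "neutral", "enum: yes|no"),
    row("caffeine_freq", "exposure", "neutral", "enum: daily|weekly|monthly"),
    row("caffeine_quantity", "exposure", "neutral",
        "numeric (cups per frequency unit)"),
    row("alcohol_before", "exposure", "neutral", "enum: yes|no"),
    row("alcohol_after",  "exposure", "neutral", "enum: yes|no"),
    row("alcohol_drinks_week_before", "exposure", "neutral", "numeric (drinks/week)"),
    row("alcohol_drinks_week_after",  "exposure", "neutral", "numeric (drinks/week)"),
    row("tobacco_before", "exposure", "neutral", "enum: yes|no"),
    row("tobacco_after",  "exposure", "neutral", "enum: yes|no"),
    row("tobacco_per_day_before", "exposure", "neutral", "numeric (uses/day)"),
    row("tobacco_per_day_after",  "exposure", "neutral", "numeric (uses/day)"),
    row("marijuana_before", "exposure", "neutral", "enum: yes|no"),
    row("marijuana_after",  "exposure", "neutral", "enum: yes|no"),
    row("marijuana_per_day_before", "exposure", "neutral", "numeric (uses/day)"),
    row("marijuana_per_day_after",  "exposure", "neutral", "numeric (uses/day)"),
    ## derived exposure variables (written back by derive_exposures)
    row("pse_caffeine",  "exposure", "neutral", "binary 0/1"),
    row("pse_alcohol",   "exposure", "neutral", "binary 0/1"),
    row("pse_tobacco",   "exposure", "neutral", "binary 0/1"),
    row("pse_marijuana", "exposure", "neutral", "binary 0/1"),
    row("pse_polysubstance", "exposure", "neutral", "binary 0/1"),
    row("kg_alcohol",   "exposure", "neutral", "enum: no_exposure|before_only|after"),
    row("kg_tobacco",   "exposure", "neutral", "enum: no_exposure|before_only|after"),
    row("kg_marijuana", "exposure", "neutral", "enum: no_exposure|before_only|after"),
    row("total_caffeine",  "exposure", "neutral", "numeric (cups, pregnancy total)"),
    row("total_alcohol",   "exposure", "neutral", "numeric (drinks, pregnancy total)"),
    row("total_tobacco",   "exposure", "neutral", "numeric (instances, pregnancy total)"),
    row("total_marijuana", "exposure", "neutral", "numeric (instances, pregnancy total)"),
    row("pattern_caffeine",  "exposure", "neutral", "enum: daily|weekly|monthly"),
    row("pattern_alcohol",   "exposure", "neutral",
        "enum: light_reducing|light_stable|heavier_reducing|heavier_stable|increasing"),
    row("pattern_tobacco",   "exposure", "neutral",
        "enum: light_reducing|light_stable|heavier_reducing|heavier_stable|increasing"),
    row("pattern_marijuana", "exposure", "neutral", "enum: any"),
    ## birth context components
    row("pse_cocaine",             "context_birth", "risky",      "binary 0/1"),
    row("obstetric_complications", "context_birth", "risky",      "numeric (0 no, 0.5 unknown, 1 yes)"),
    row("prenatal_vitamin",        "context_birth", "protective", "binary 0/1"),
    row("breastfeeding_months",    "context_birth", "protective", "numeric (months)"),
    ## family context components
    row("family_conflict",    "context_family", "risky",      "numeric (scale score)"),
    row("parental_education", "context_family", "protective", "numeric (years)"),
    row("family_income",      "context_family", "protective", "numeric (log USD)"),
    ## society context components
    row("lead_risk",           "context_society", "risky",      "numeric (index)"),
    row("area_deprivation",    "context_society", "risky",      "numeric (index)"),
    row("neighborhood_safety", "context_society", "protective", "numeric (scale score)"),
    ## genetic context components
    row("family_history_mental", "context_genetic", "risky",      "numeric (density score)"),
    row("prs_adhd",              "context_genetic", "risky",      "numeric (z)"),
    row("prs_edu",               "context_genetic", "protective", "numeric (z)"),
    ## composite context scores (neutral polarity: not re-summed as components)
    row("ctx_birth",   "context_birth",   "neutral", "numeric (signed score)"),
    row("ctx_family",  "context_family",  "neutral", "numeric (signed score)"),
    row("ctx_society", "context_society", "neutral", "numeric (signed score)"),
    row("ctx_genetic", "context_genetic", "neutral", "numeric (signed score)"),
    ## outcome battery
    row("sleep_problems",         "outcome", "neutral", "numeric (scale score)", "behavioral"),
    row("upps_sensation_seeking", "outcome", "neutral", "numeric (scale score)", "behavioral"),
    row("cbcl_total",         "outcome", "neutral", "numeric (scale score)", "mental"),
    row("cbcl_internalizing", "outcome", "neutral", "numeric (scale score)", "mental"),
    row("cbcl_externalizing", "outcome", "neutral", "numeric (scale score)", "mental"),
    row("cbcl_attention",     "outcome", "neutral", "numeric (scale score)", "mental"),
    row("cog_crystallized", "outcome", "neutral", "numeric (composite)", "cognitive"),
    row("cog_fluid",        "outcome", "neutral", "numeric (composite)", "cognitive"),
    ## brain metrics
    row("brain_sa_global",      "brain_structure", "neutral", "numeric (mm^2)"),
    row("brain_vol_midtemporal","brain_structure", "neutral", "numeric (mm^3)"),
    row("rsfc_con_subc",        "brain_function",  "neutral", "numeric (Fisher z)"),
    ## nuisance covariates
    row("icv",           "nuisance", "neutral", "numeric (mm^3)"),
    row("head_motion",   "nuisance", "neutral", "numeric (mean FD, mm)"),
    row("image_quality", "nuisance", "neutral", "numeric (QC score)")
  )
  if (length(extra_outcomes)) {
    d <- rbind(d, data.frame(variable_name = extra_outcomes, role = "outcome",
                             polarity = "neutral",
                             value_domain = "numeric (scale score)",
                             domain = "mental", stringsAsFactors = FALSE))
  }
  data_dictionary(d)
}
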