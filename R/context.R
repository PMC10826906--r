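#' Min-max normalization to [0, 1]
#'
#' Rescales a vector to `(x - min) / (max - min)` over its non-missing
#' entries; missing values propagate. Used to make context components
#' comparable and additive before signed summation.
#'
#' @param x numeric vector, possibly with missing values.
#' @return numeric vector in `[0, 1]` with the missingness pattern of `x`.
#' @export
min_max_normalize <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2L) {
    pse_domain_error("min-max normalization needs at least two non-missing values")
  }
  rng <- range(v)
  if (rng[1] == rng[2]) {
    pse_domain_error("degenerate scale: all non-missing values identical")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Composite context risk score
#'
#' Builds one of the four context scores (birth, family, society, genetic) as
#' the signed sum of min-max-normalized components declared in the data
#' dictionary: risky components are added and protective components are
#' subtracted, so higher scores always indicate higher risk. Normalization
#' bounds are computed on the analysis sample, making scores cohort-relative.
#' A child missing any component receives a missing score (no partial sums).
#'
#' @param cohort a `cohort_table`.
#' @param dictionary a [data_dictionary()]; components of the requested
#'   context are its variables with role `context_<context>` and non-neutral
#'   polarity.
#' @param context one of `"birth"`, `"family"`, `"society"`, `"genetic"`.
#' @return numeric vector of per-record scores, aligned with `cohort` rows.
#' @export
build_context_score <- function(cohort, dictionary, context) {
  context <- match.arg(context, c("birth", "family", "society", "genetic"))
  role <- paste0("context_", context)
  comp <- dictionary[dictionary$role == role &
                       dictionary$polarity != "neutral", , drop = FALSE]
  if (nrow(comp) == 0L) {
    pse_schema_error(sprintf("no components declared for context '%s'", context))
  }
  absent <- setdiff(comp$variable_name, names(cohort))
  if (length(absent)) {
    pse_schema_error(sprintf("undeclared/absent component column(s): %s",
                             paste(absent, collapse = ", ")))
  }
  score <- rep(0, nrow(cohort))
  for (i in seq_len(nrow(comp))) {
    z <- min_max_normalize(cohort[[comp$variable_name[i]]])
    score <- score + if (comp$polarity[i] == "risky") z else -z
  }
  score
}

#' Add all four context scores to a cohort table
#'
#' Convenience wrapper computing `ctx_birth`, `ctx_family`, `ctx_society` and
#' `ctx_genetic` with [build_context_score()].
#'
#' @inheritParams build_context_score
#' @return the cohort with the four `ctx_*` columns added.
#' @export
derive_context_scores <- function(cohort,
                                  dictionary = attr(cohort, "dictionary")) {
  for (ctx in c("birth", "family", "society", "genetic")) {
    cohort[[paste0("ctx_", ctx)]] <-
      build_context_score(cohort, dictionary, ctx)
  }
  cohort
}

#' Association of a context score with an exposure
#'
#' Regresses a context score on a binary exposure with the essential
#' covariates under the standard mixed model (random intercepts for site and
#' family in site), reporting the standardized coefficient. Used to
#' characterize which contexts co-occur with which exposures.
#'
#' @param cohort a `cohort_table` with derived exposures and `ctx_*` columns.
#' @param score name of the context-score column (e.g. `"ctx_family"`).
#' @param exposure name of the exposure column (e.g. `"pse_alcohol"`).
#' @param wave which wave's records to use.
#' @return a one-row `association_result` data.frame (see [fit_association()]).
#' @export
score_exposure_association <- function(cohort, score, exposure,
                                       wave = "baseline") {
  spec <- model_spec(outcome = score, exposures = exposure, wave = wave)
  fit_association(cohort, spec)
}
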