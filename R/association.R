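#' Specification of one exposure-outcome mixed model
#'
#' Fixed effects are the exposure(s) plus the essential covariates (sex,
#' race/ethnicity, age at assessment), plus intracranial volume for volumetric
#' brain outcomes and head motion and image quality for functional
#' connectivity outcomes; in `context_adjusted` mode all four exposures enter
#' jointly together with the four context scores. Random effects are
#' intercepts for study site and for family nested in site.
#'
#' @param outcome outcome column name.
#' @param exposures character vector of exposure column names entering the
#'   fixed effects; the first is the focal exposure unless all are focal
#'   (adjusted mode).
#' @param wave `"baseline"` or `"year2"`.
#' @param mode `"unadjusted_context"` or `"context_adjusted"` (adds the four
#'   `ctx_*` scores).
#' @param extra_covariates additional covariate column names; when `NULL` they
#'   are inferred from the outcome's dictionary role at fit time.
#' @return a `model_spec` list.
#' @export
model_spec <- function(outcome, exposures, wave = "baseline",
                       mode = c("unadjusted_context", "context_adjusted"),
                       extra_covariates = NULL) {
  mode <- match.arg(mode)
  structure(list(outcome = outcome, exposures = exposures, wave = wave,
                 mode = mode, extra_covariates = extra_covariates),
            class = "model_spec")
}

essential_covariates <- c("sex", "race_ethnicity", "age_months")

## Outcome-family extras from the dictionary: icv for volumetric structure
## metrics; head motion and image quality for functional connectivity.
infer_extras <- function(outcome, dictionary) {
  if (is.null(dictionary) || !outcome %in% dictionary$variable_name) {
    return(character())
  }
  i <- match(outcome, dictionary$variable_name)
  role <- dictionary$role[i]
  if (role == "brain_structure" &&
      grepl("mm\\^?3", dictionary$value_domain[i])) return("icv")
  if (role == "brain_function") return(c("head_motion", "image_quality"))
  character()
}

## Assemble the per-fit analysis frame: focal wave, complete cases, z-scored
## outcome and continuous predictors, factor coding with White reference.
build_fit_frame <- function(cohort, spec, dictionary) {
  extras <- spec$extra_covariates %||% infer_extras(spec$outcome, dictionary)
  ctx <- if (spec$mode == "context_adjusted") {
    c("ctx_birth", "ctx_family", "ctx_society", "ctx_genetic")
  } else character()
  vars <- unique(c(spec$outcome, spec$exposures, essential_covariates, extras,
                   ctx, "site_id", "family_id"))
  absent <- setdiff(vars, names(cohort))
  if (length(absent)) {
    pse_schema_error(sprintf("model variables absent from cohort: %s",
                             paste(absent, collapse = ", ")))
  }
  d <- cohort[cohort$wave == spec$wave, vars, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) pse_design_error("no complete cases for this model")
  if (length(unique(d$site_id)) < 2L || length(unique(d$family_id)) < 2L) {
    pse_design_error("fewer than 2 sites or 2 families after filtering")
  }
  if (stats::sd(d[[spec$outcome]]) == 0) {
    pse_design_error(sprintf("outcome '%s' is constant on the fit sample",
                             spec$outcome))
  }
  d$.y <- zscore(d[[spec$outcome]])
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$race_ethnicity <- stats::relevel(
    factor(d$race_ethnicity,
           levels = c("Asian", "Black", "Hispanic", "White", "Other")),
    ref = "White")
  d$race_ethnicity <- droplevels(d$race_ethnicity)
  for (v in c("age_months", extras, ctx)) d[[v]] <- zscore(d[[v]])
  ## continuous (non-binary) exposures are z-scored; binary stay 0/1
  for (v in spec$exposures) {
    u <- unique(d[[v]])
    if (!all(u %in% c(0, 1))) d[[v]] <- zscore(d[[v]])
    if (stats::sd(d[[v]]) == 0) {
      pse_design_error(sprintf("predictor '%s' has no variance", v))
    }
  }
  attr(d, "fixed_terms") <- c(spec$exposures, "sex", "race_ethnicity",
                              "age_months", extras, ctx)
  d
}

fixed_formula_rhs <- function(d) paste(attr(d, "fixed_terms"), collapse = " + ")

## Fit the mixed model with the non-convergence fallback ladder:
## full (site + family-in-site) -> family-only random intercept ->
## OLS with family-cluster-robust standard errors.
fit_mixed_ladder <- function(d) {
  rhs <- fixed_formula_rhs(d)
  f_full <- stats::as.formula(
    paste(".y ~", rhs, "+ (1 | site_id) + (1 | site_id:family_id)"))
  f_fam <- stats::as.formula(paste(".y ~", rhs, "+ (1 | family_id)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- tryCatch({
    m <- suppressMessages(lme4::lmer(f_full, data = d, REML = TRUE,
                                     control = ctrl))
    if (length(m@optinfo$conv$lme4$code %||% integer()) > 0) stop("non-convergence")
    list(model = m, fallback = "none")
  }, error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch({
      m <- suppressMessages(lme4::lmer(f_fam, data = d, REML = TRUE,
                                       control = ctrl))
      if (length(m@optinfo$conv$lme4$code %||% integer()) > 0) stop("non-convergence")
      list(model = m, fallback = "family_only")
    }, error = function(e) NULL)
  }
  if (is.null(fit)) {
    m <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
    fit <- list(model = m, fallback = "ols_cluster_robust")
  }
  fit
}

## Extract per-exposure coefficient rows from a fitted ladder model.
extract_assoc <- function(fit, d, spec) {
  m <- fit$model
  if (inherits(m, "merMod")) {
    b <- lme4::fixef(m)
    V <- as.matrix(stats::vcov(m))
  } else {
    b <- stats::coef(m)
    V <- sandwich::vcovCL(m, cluster = d$family_id)
  }
  rows <- lapply(spec$exposures, function(e) {
    se <- sqrt(V[e, e])
    z <- b[[e]] / se
    data.frame(exposure = e, outcome = spec$outcome, wave = spec$wave,
               beta = unname(b[[e]]), se = se,
               p = 2 * stats::pnorm(-abs(z)), p_fdr = NA_real_,
               n_fit = nrow(d), mode = spec$mode, fallback = fit$fallback,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Fit one exposure-outcome linear mixed model
#'
#' Fits `outcome ~ exposure(s) + covariates + (1 | site) + (1 | family in
#' site)` by REML on the complete-case sample for the requested wave. The
#' outcome and all continuous predictors are z-scored on the fit sample, so
#' the reported coefficient of a binary exposure is a standardized effect in
#' outcome-SD units. P-values are Wald tests with a normal reference
#' (large-sample). If the full model fails to converge the model is refitted
#' with a single family random intercept, and failing that by OLS with
#' family-cluster-robust standard errors; the fallback used is recorded.
#'
#' @param cohort a `cohort_table`.
#' @param spec a [model_spec()].
#' @param dictionary dictionary used to infer outcome-family covariates;
#'   defaults to the one attached to the cohort.
#' @return an `association_result` data.frame, one row per exposure in the
#'   spec, with columns `exposure`, `outcome`, `wave`, `beta`, `se`, `p`,
#'   `p_fdr` (NA until [fdr_adjust()] is applied across a battery), `n_fit`,
#'   `mode`, `fallback`.
#' @export
fit_association <- function(cohort, spec,
                            dictionary = attr(cohort, "dictionary")) {
  d <- build_fit_frame(cohort, spec, dictionary)
  fit <- fit_mixed_ladder(d)
  extract_assoc(fit, d, spec)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1) with rejection flags at
#' level `alpha`.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `p_fdr` (adjusted p-values) and `reject` (logical).
#' @export
fdr_adjust <- function(pvalues, alpha = 0.05) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    pse_domain_error("p-values must lie in [0, 1]")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    pse_domain_error("alpha must lie in (0, 1)")
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(p_fdr = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Screen an exposure set against an outcome battery
#'
#' Fits the standard mixed model for every exposure-outcome pair at one wave.
#' In `unadjusted_context` mode each exposure is fitted alone; in
#' `context_adjusted` mode all exposures enter one model per outcome together
#' with the four context scores. FDR is applied within each exposure x
#' outcome-domain x wave family (domains from the dictionary: behavioral,
#' mental, cognitive, brain_structure, brain_function). Outcomes sharing a
#' complete-case sample and covariate set reuse a single fitted model via
#' response refitting, which is exact. Per-cell fit failures are recorded and
#' do not abort the battery.
#'
#' @param cohort a `cohort_table` with derived exposures (and `ctx_*` scores
#'   in adjusted mode).
#' @param exposures character vector of exposure column names.
#' @param outcomes character vector of outcome column names.
#' @param wave `"baseline"` or `"year2"`.
#' @param mode `"unadjusted_context"` or `"context_adjusted"`.
#' @param alpha FDR level.
#' @param dictionary dictionary (defaults to the cohort's).
#' @return an `association_result` data.frame with `p_fdr` and `significant`
#'   filled in; failed cells appear with NA estimates and the error message in
#'   `fallback`.
#' @export
screen_battery <- function(cohort, exposures, outcomes, wave = "baseline",
                           mode = c("unadjusted_context", "context_adjusted"),
                           alpha = 0.05,
                           dictionary = attr(cohort, "dictionary")) {
  mode <- match.arg(mode)
  if (length(outcomes) == 0L) {
    out <- data.frame(exposure = character(), outcome = character(),
                      wave = character(), beta = numeric(), se = numeric(),
                      p = numeric(), p_fdr = numeric(), n_fit = integer(),
                      mode = character(), fallback = character(),
                      significant = logical(), stringsAsFactors = FALSE)
    class(out) <- c("association_result", "data.frame")
    return(out)
  }
  exposure_sets <- if (mode == "context_adjusted") list(exposures)
                   else as.list(exposures)
  results <- list()
  for (eset in exposure_sets) {
    ## group outcomes by (covariate extras, complete-case set) for refit reuse
    cache <- new.env(parent = emptyenv())
    for (oc in outcomes) {
      res <- tryCatch({
        spec <- model_spec(oc, eset, wave = wave, mode = mode)
        d <- build_fit_frame(cohort, spec, dictionary)
        key <- paste(paste(attr(d, "fixed_terms"), collapse = "|"),
                     nrow(d), sep = "#")
        base <- get0(key, envir = cache)
        reusable <- !is.null(base) &&
          identical(rownames(base$d), rownames(d)) &&
          inherits(base$fit$model, "merMod") &&
          base$fit$fallback == "none"
        if (reusable) {
          m2 <- suppressMessages(lme4::refit(base$fit$model, newresp = d$.y))
          extract_assoc(list(model = m2, fallback = "none"), d, spec)
        } else {
          fit <- fit_mixed_ladder(d)
          if (fit$fallback == "none") assign(key, list(d = d, fit = fit), cache)
          extract_assoc(fit, d, spec)
        }
      }, error = function(e) {
        do.call(rbind, lapply(if (mode == "context_adjusted") eset else eset[1],
          function(e1) data.frame(
            exposure = e1, outcome = oc, wave = wave, beta = NA_real_,
            se = NA_real_, p = NA_real_, p_fdr = NA_real_, n_fit = NA_integer_,
            mode = mode, fallback = paste("failed:", conditionMessage(e)),
            stringsAsFactors = FALSE)))
      })
      results[[length(results) + 1L]] <- res
    }
  }
  out <- do.call(rbind, results)
  ## FDR within exposure x outcome-domain x wave
  dom <- rep("outcome", nrow(out))
  if (!is.null(dictionary)) {
    i <- match(out$outcome, dictionary$variable_name)
    dom <- ifelse(is.na(i), "outcome",
                  ifelse(is.na(dictionary$domain[i]), "outcome",
                         dictionary$domain[i]))
  }
  out$domain <- dom
  out$significant <- FALSE
  for (g in split(seq_len(nrow(out)),
                  paste(out$exposure, dom, out$wave, sep = "\r"))) {
    adj <- fdr_adjust(out$p[g], alpha)
    out$p_fdr[g] <- adj$p_fdr
    out$significant[g] <- adj$reject
  }
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}

#' Robustness filter: which associations survive context adjustment
#'
#' Compares the unadjusted-context and context-adjusted screens cell by cell.
#' An association is `robust` if FDR-significant in the adjusted screen,
#' `confounded` if significant unadjusted but not adjusted, and
#' `never_significant` otherwise. Also computes, per exposure, the percent
#' reduction in the number of significant associations caused by context
#' adjustment (attached as the `"reduction"` attribute and retrievable with
#' [reduction_summary()]).
#'
#' @param unadjusted,adjusted `association_result` tables from
#'   [screen_battery()] in the two modes, with matching
#'   (exposure, outcome, wave) cells.
#' @param alpha FDR level used for the significance flags.
#' @return a `robustness_verdict` data.frame with columns `exposure`,
#'   `outcome`, `wave`, `significant_unadjusted`, `significant_adjusted`,
#'   `verdict`.
#' @export
robustness_filter <- function(unadjusted, adjusted, alpha = 0.05) {
  key_u <- paste(unadjusted$exposure, unadjusted$outcome, unadjusted$wave)
  key_a <- paste(adjusted$exposure, adjusted$outcome, adjusted$wave)
  if (!setequal(key_u, key_a) || anyDuplicated(key_u) || anyDuplicated(key_a)) {
    pse_contract_error("unadjusted and adjusted results do not align on (exposure, outcome, wave)")
  }
  a <- adjusted[match(key_u, key_a), , drop = FALSE]
  sig_u <- !is.na(unadjusted$p_fdr) & unadjusted$p_fdr <= alpha
  sig_a <- !is.na(a$p_fdr) & a$p_fdr <= alpha
  verdict <- ifelse(sig_a, "robust",
                    ifelse(sig_u, "confounded", "never_significant"))
  out <- data.frame(exposure = unadjusted$exposure,
                    outcome = unadjusted$outcome, wave = unadjusted$wave,
                    significant_unadjusted = as.integer(sig_u),
                    significant_adjusted = as.integer(sig_a),
                    verdict = verdict, stringsAsFactors = FALSE)
  red <- do.call(rbind, lapply(split(out, out$exposure), function(g) {
    nu <- sum(g$significant_unadjusted)
    na_ <- sum(g$significant_unadjusted & g$significant_adjusted)
    data.frame(exposure = g$exposure[1], n_significant_unadjusted = nu,
               n_remaining_adjusted = na_,
               reduction_percent = if (nu > 0) round(100 * (1 - na_ / nu), 1)
                                   else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(red) <- NULL
  attr(out, "reduction") <- red
  class(out) <- c("robustness_verdict", "data.frame")
  out
}

#' Per-exposure reduction in significant associations after adjustment
#' @param verdicts a `robustness_verdict` from [robustness_filter()].
#' @return data.frame with per-exposure counts and `reduction_percent`.
#' @export
reduction_summary <- function(verdicts) {
  attr(verdicts, "reduction")
}
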