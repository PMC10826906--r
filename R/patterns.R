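#' Cluster-bootstrap CI for the between-wave effect-size difference
#'
#' Point estimates of the standardized exposure effect at baseline and at the
#' 2-year follow-up come from the REML mixed-model fits; the percentile
#' confidence interval of their difference (beta_year2 - beta_baseline) comes
#' from resampling families with replacement within site strata, keeping both
#' waves of every child in a sampled family so the longitudinal pairing is
#' preserved. Within bootstrap replicates the coefficient is recomputed by
#' least squares on the resampled design (cluster resampling carries the
#' dependence; fixed effects are unbiased under the random-intercept model),
#' which keeps thousands of replicates feasible.
#'
#' @param cohort a `cohort_table` with two waves.
#' @param exposure exposure column name.
#' @param outcome outcome column name.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param mode covariate mode as in [model_spec()].
#' @param dictionary dictionary (defaults to the cohort's).
#' @return list with `beta_baseline`, `beta_year2`, `delta`, `ci_low`,
#'   `ci_high`, `n_boot_used` (replicates with estimable coefficients).
#' @export
bootstrap_delta <- function(cohort, exposure, outcome, n_boot = 10000,
                            seed = 1L, mode = "unadjusted_context",
                            dictionary = attr(cohort, "dictionary")) {
  if (n_boot < 100) pse_domain_error("n_boot must be at least 100")
  frames <- lapply(c("baseline", "year2"), function(w) {
    spec <- model_spec(outcome, exposure, wave = w, mode = mode)
    d <- build_fit_frame(cohort, spec, dictionary)
    fit <- fit_mixed_ladder(d)
    res <- extract_assoc(fit, d, spec)
    mm <- stats::model.matrix(
      stats::as.formula(paste("~", fixed_formula_rhs(d))), data = d)
    list(d = d, beta = res$beta, X = mm, y = d$.y,
         coef_idx = match(exposure, colnames(mm)))
  })
  names(frames) <- c("baseline", "year2")
  b0 <- frames$baseline$beta
  b2 <- frames$year2$beta

  ## family resampling within site strata, shared across both waves
  fam_site <- unique(rbind(
    frames$baseline$d[, c("family_id", "site_id")],
    frames$year2$d[, c("family_id", "site_id")]))
  fam_site <- fam_site[order(fam_site$family_id), , drop = FALSE]
  rows_by_fam <- lapply(frames, function(fr) {
    split(seq_len(nrow(fr$d)), factor(fr$d$family_id,
                                      levels = fam_site$family_id))
  })
  fams_by_site <- split(seq_len(nrow(fam_site)), fam_site$site_id)

  boot_beta <- function(fr, fam_idx) {
    idx <- unlist(lapply(rows_by_fam[[fr]][fam_idx], identity),
                  use.names = FALSE)
    X <- frames[[fr]]$X[idx, , drop = FALSE]
    y <- frames[[fr]]$y[idx]
    sy <- stats::sd(y)
    if (!is.finite(sy) || sy == 0) return(NA_real_)
    fit <- stats::lm.fit(X, (y - mean(y)) / sy)
    co <- fit$coefficients[frames[[fr]]$coef_idx]
    if (is.na(co)) NA_real_ else unname(co)
  }

  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  deltas <- rep(NA_real_, n_boot)
  for (r in seq_len(n_boot)) {
    fam_idx <- unlist(lapply(fams_by_site, function(f)
      f[sample.int(length(f), length(f), replace = TRUE)]), use.names = FALSE)
    d0 <- boot_beta("baseline", fam_idx)
    d2 <- boot_beta("year2", fam_idx)
    deltas[r] <- d2 - d0
  }
  ok <- deltas[!is.na(deltas)]
  if (length(ok) < 0.8 * n_boot) {
    pse_error("psecontext_bootstrap_error",
              sprintf("bootstrap unstable: %d of %d replicates failed",
                      n_boot - length(ok), n_boot))
  }
  ci <- unname(stats::quantile(ok, c(0.025, 0.975)))
  list(beta_baseline = b0, beta_year2 = b2, delta = b2 - b0,
       ci_low = ci[1], ci_high = ci[2], n_boot_used = length(ok))
}

#' Developmental-pattern label from significance flags and the delta CI
#'
#' Applies the verbal rule table: an association significant at both waves is
#' `persistent`; one significant only at baseline whose effect size decreased
#' significantly (the 95% bootstrap CI of beta_year2 - beta_baseline excludes
#' zero in the attenuating direction relative to the baseline effect sign) is
#' `transient`; one significant only at year 2 whose effect size increased
#' significantly (CI excludes zero in the growing direction relative to the
#' year-2 effect sign) is `late_onset`; anything else is `unclassified`.
#'
#' @param sig_baseline,sig_year2 logical FDR-significance flags.
#' @param ci_low,ci_high percentile bootstrap bounds on
#'   beta_year2 - beta_baseline.
#' @param beta_baseline,beta_year2 effect signs (defaults positive; only the
#'   sign is used).
#' @return one of `"persistent"`, `"transient"`, `"late_onset"`,
#'   `"unclassified"`.
#' @export
classify_pattern_label <- function(sig_baseline, sig_year2, ci_low, ci_high,
                                   beta_baseline = 1, beta_year2 = 1) {
  stopifnot(ci_low <= ci_high)
  excludes_zero <- ci_low > 0 || ci_high < 0
  if (sig_baseline && sig_year2) return("persistent")
  if (sig_baseline && !sig_year2) {
    attenuating <- if (sign(beta_baseline) >= 0) ci_high < 0 else ci_low > 0
    if (excludes_zero && attenuating) return("transient")
    return("unclassified")
  }
  if (!sig_baseline && sig_year2) {
    growing <- if (sign(beta_year2) >= 0) ci_low > 0 else ci_high < 0
    if (excludes_zero && growing) return("late_onset")
    return("unclassified")
  }
  "unclassified"
}

#' Pattern analysis over the robust association set
#'
#' For every association that is FDR-significant (context-adjusted) at either
#' wave, bootstraps the between-wave effect-size difference and assigns the
#' developmental-pattern label.
#'
#' @param cohort a `cohort_table`.
#' @param adjusted_baseline,adjusted_year2 context-adjusted
#'   `association_result` tables for the two waves.
#' @param alpha FDR level.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param mode covariate mode used for the bootstrap refits.
#' @return a `pattern_result` data.frame: `exposure`, `outcome`,
#'   `beta_baseline`, `beta_year2`, `delta`, `ci_low`, `ci_high`,
#'   `sig_baseline`, `sig_year2`, `label`.
#' @export
pattern_analysis <- function(cohort, adjusted_baseline, adjusted_year2,
                             alpha = 0.05, n_boot = 10000, seed = 1L,
                             mode = "context_adjusted") {
  key0 <- paste(adjusted_baseline$exposure, adjusted_baseline$outcome)
  key2 <- paste(adjusted_year2$exposure, adjusted_year2$outcome)
  sig0 <- !is.na(adjusted_baseline$p_fdr) & adjusted_baseline$p_fdr <= alpha
  sig2 <- !is.na(adjusted_year2$p_fdr) & adjusted_year2$p_fdr <= alpha
  cand <- union(key0[sig0], key2[sig2])
  rows <- lapply(cand, function(k) {
    i0 <- match(k, key0)
    i2 <- match(k, key2)
    e <- adjusted_baseline$exposure[i0] %||% adjusted_year2$exposure[i2]
    oc <- adjusted_baseline$outcome[i0] %||% adjusted_year2$outcome[i2]
    bd <- bootstrap_delta(cohort, e, oc, n_boot = n_boot,
                          seed = child_seed(seed, paste0("delta:", k)),
                          mode = mode)
    s0 <- !is.na(i0) && sig0[i0]
    s2 <- !is.na(i2) && sig2[i2]
    data.frame(exposure = e, outcome = oc,
               beta_baseline = bd$beta_baseline, beta_year2 = bd$beta_year2,
               delta = bd$delta, ci_low = bd$ci_low, ci_high = bd$ci_high,
               sig_baseline = as.integer(s0), sig_year2 = as.integer(s2),
               label = classify_pattern_label(s0, s2, bd$ci_low, bd$ci_high,
                                              bd$beta_baseline, bd$beta_year2),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exposure = character(), outcome = character(),
               beta_baseline = numeric(), beta_year2 = numeric(),
               delta = numeric(), ci_low = numeric(), ci_high = numeric(),
               sig_baseline = integer(), sig_year2 = integer(),
               label = character(), stringsAsFactors = FALSE)
  class(out) <- c("pattern_result", "data.frame")
  out
}

#' Linear dose-response association
#'
#' Fits the standard mixed model with the log1p-transformed pregnancy-total
#' consumption as a continuous predictor (unexposed children contribute 0
#' consumption), z-scored on the fit sample, under the context-adjusted
#' covariate set by default.
#'
#' @param cohort a `cohort_table` with derived `total_*` columns.
#' @param substance substance name.
#' @param outcome outcome column name.
#' @param wave `"baseline"` or `"year2"`.
#' @param mode covariate mode.
#' @return an `association_result` row (exposure = `dose_<substance>`).
#' @export
dose_response <- function(cohort, substance, outcome, wave = "year2",
                          mode = "context_adjusted") {
  col <- paste0("total_", substance)
  if (!col %in% names(cohort)) {
    pse_schema_error(sprintf("column '%s' missing; run derive_exposures first", col))
  }
  dcol <- paste0("dose_", substance)
  cohort[[dcol]] <- log1p(cohort[[col]])
  ## temporary column: register it so schema validation still holds
  dict <- attr(cohort, "dictionary")
  dict <- rbind(dict, data.frame(variable_name = dcol, role = "exposure",
                                 polarity = "neutral",
                                 value_domain = "numeric (log1p total)",
                                 domain = NA_character_,
                                 stringsAsFactors = FALSE))
  spec <- model_spec(outcome, dcol, wave = wave, mode = mode)
  fit_association(cohort, spec, dictionary = data_dictionary(dict))
}

#' Use-pattern contrasts against the no-exposure reference
#'
#' Contrasts each use-pattern level of a substance against unexposed children
#' within one model (dummy coding), FDR-adjusted across levels. Pattern levels
#' with no children are skipped.
#'
#' @param cohort a `cohort_table` with derived `pattern_*` and `pse_*`
#'   columns.
#' @param substance substance name.
#' @param outcome outcome column name.
#' @param wave `"baseline"` or `"year2"`.
#' @param mode covariate mode.
#' @param alpha FDR level.
#' @param min_cell minimum children per pattern level (smaller cells skipped).
#' @return an `association_result` with one row per pattern level, exposure
#'   labelled `<substance>:<pattern>`; empty (with a warning) if no children
#'   are exposed.
#' @export
pattern_contrasts <- function(cohort, substance, outcome, wave = "baseline",
                              mode = "context_adjusted", alpha = 0.05,
                              min_cell = 10) {
  pat_col <- paste0("pattern_", substance)
  pse_col <- paste0("pse_", substance)
  w <- cohort[cohort$wave == wave, , drop = FALSE]
  exposed <- !is.na(w[[pse_col]]) & w[[pse_col]] == 1L
  if (!any(exposed)) {
    warning(sprintf("no children exposed to %s; empty contrast set", substance))
    return(screen_battery(cohort, character(), character(), wave = wave))
  }
  levels_present <- table(w[[pat_col]][exposed])
  levels_used <- names(levels_present)[levels_present >= min_cell]
  skipped <- setdiff(names(levels_present), levels_used)
  if (length(skipped)) {
    message(sprintf("skipping sparse pattern cell(s): %s",
                    paste(skipped, collapse = ", ")))
  }
  if (length(levels_used) == 0L) {
    warning("all pattern cells below min_cell; empty contrast set")
    return(screen_battery(cohort, character(), character(), wave = wave))
  }
  d <- cohort
  dummies <- character()
  dict_extra <- list()
  for (lv in levels_used) {
    dcol <- paste0(".pat_", gsub("[^a-z_]", "_", lv))
    d[[dcol]] <- as.integer(!is.na(d[[pat_col]]) & d[[pat_col]] == lv)
    ## keep only pattern-level children and unexposed reference
    dummies <- c(dummies, dcol)
    dict_extra[[dcol]] <- data.frame(
      variable_name = dcol, role = "exposure", polarity = "neutral",
      value_domain = "binary 0/1", domain = NA_character_,
      stringsAsFactors = FALSE)
  }
  keep <- is.na(d[[pat_col]]) | d[[pat_col]] %in% levels_used
  keep <- keep & (!is.na(d[[pse_col]]))
  d <- d[keep, , drop = FALSE]
  dict <- rbind(attr(cohort, "dictionary"), do.call(rbind, dict_extra))
  dict <- data_dictionary(dict)
  d <- as_cohort_table(as.data.frame(d), dict)
  spec <- model_spec(outcome, dummies, wave = wave, mode = mode)
  res <- fit_association(d, spec, dictionary = dict)
  res$exposure <- paste0(substance, ":", levels_used)
  adj <- fdr_adjust(res$p, alpha)
  res$p_fdr <- adj$p_fdr
  res$significant <- adj$reject
  res
}
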