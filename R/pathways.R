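#' Randomly keep one child per family
#'
#' Removes sibling dependence by selecting one child uniformly at random from
#' each family (both waves of the selected child are kept). Deterministic
#' given the seed and invariant to the input record order.
#'
#' @param cohort a `cohort_table`.
#' @param seed integer seed.
#' @return the subsampled `cohort_table`; its number of distinct children
#'   equals the number of families.
#' @export
one_per_family <- function(cohort, seed = 1L) {
  kids <- unique(as.data.frame(cohort)[, c("child_id", "family_id")])
  kids <- kids[order(kids$family_id, kids$child_id), , drop = FALSE]
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  chosen <- unlist(lapply(split(kids$child_id, kids$family_id), function(ids) {
    if (length(ids) == 1L) ids else ids[sample.int(length(ids), 1L)]
  }), use.names = FALSE)
  out <- cohort[cohort$child_id %in% chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Assemble the mediation frame: exposure, mediator and covariates at
## baseline, outcome at year 2, one row per child, complete cases.
build_mediation_frame <- function(cohort, exposure, mediator, outcome) {
  b <- as.data.frame(cohort[cohort$wave == "baseline", , drop = FALSE])
  y2 <- as.data.frame(cohort[cohort$wave == "year2", , drop = FALSE])
  d <- b[, c("child_id", "site_id", exposure, mediator, "sex",
             "race_ethnicity", "age_months")]
  d$.outcome <- y2[[outcome]][match(d$child_id, y2$child_id)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10L) pse_design_error("too few complete cases for mediation")
  if (stats::sd(d[[mediator]]) == 0) {
    pse_design_error("mediator is constant on the fit sample")
  }
  d
}

#' Longitudinal mediation of a year-2 outcome by a baseline brain measure
#'
#' Product-of-coefficients mediation on a one-child-per-family sample: path
#' `a` from regressing the (z-scored) baseline mediator on the exposure plus
#' covariates (age, sex, race/ethnicity and site as fixed dummies), paths `b`
#' and `c'` from regressing the (z-scored) year-2 outcome on the mediator,
#' exposure and the same covariates. The indirect effect is `a*b`, the total
#' effect `a*b + c'` (an exact identity for nested linear models on one
#' sample), and the mediated proportion `100 * indirect / total` (negative
#' values indicate suppression). Inference on the indirect effect is by
#' percentile bootstrap over children, with a two-sided achieved level from
#' the sign proportion of the bootstrap distribution.
#'
#' @param cohort a `cohort_table`, typically after [one_per_family()].
#' @param exposure binary exposure column.
#' @param mediator baseline brain-measure column.
#' @param outcome year-2 outcome column.
#' @param n_boot bootstrap replicates (0 skips the bootstrap and reports point
#'   estimates only).
#' @param seed integer seed.
#' @return a one-row `mediation_result` data.frame.
#' @export
mediate <- function(cohort, exposure, mediator, outcome, n_boot = 10000,
                    seed = 1L) {
  d <- build_mediation_frame(cohort, exposure, mediator, outcome)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$race_ethnicity <- stats::relevel(
    factor(d$race_ethnicity,
           levels = c("Asian", "Black", "Hispanic", "White", "Other")),
    ref = "White")
  d$race_ethnicity <- droplevels(d$race_ethnicity)
  d$site_id <- factor(d$site_id)
  d$.age <- zscore(d$age_months)
  covs <- stats::model.matrix(~ sex + race_ethnicity + .age + site_id, data = d)
  x <- d[[exposure]]
  m_raw <- d[[mediator]]
  y_raw <- d$.outcome

  paths <- function(idx) {
    xx <- x[idx]
    mm <- m_raw[idx]
    yy <- y_raw[idx]
    sm <- stats::sd(mm); sy <- stats::sd(yy)
    if (!is.finite(sm) || sm == 0 || !is.finite(sy) || sy == 0 ||
        stats::sd(xx) == 0) return(c(NA_real_, NA_real_, NA_real_))
    mz <- (mm - mean(mm)) / sm
    yz <- (yy - mean(yy)) / sy
    A <- cbind(covs[idx, , drop = FALSE], x = xx)
    f1 <- stats::lm.fit(A, mz)
    a <- f1$coefficients[["x"]]
    B <- cbind(A, m = mz)
    f2 <- stats::lm.fit(B, yz)
    b <- f2$coefficients[["m"]]
    cp <- f2$coefficients[["x"]]
    c(a, b, cp)
  }

  full <- paths(seq_len(nrow(d)))
  if (anyNA(full)) pse_design_error("mediation paths not estimable")
  a <- full[1]; b <- full[2]; cp <- full[3]
  indirect <- a * b
  total <- indirect + cp
  ratio <- if (total != 0) 100 * indirect / total else NA_real_

  nn <- nrow(d)
  ci <- c(NA_real_, NA_real_)
  p_boot <- NA_real_
  n_used <- 0L
  if (n_boot > 0) {
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    boots <- rep(NA_real_, n_boot)
    for (r in seq_len(n_boot)) {
      p <- paths(sample.int(nn, nn, replace = TRUE))
      boots[r] <- p[1] * p[2]
    }
    ok <- boots[!is.na(boots)]
    if (length(ok) < 0.8 * n_boot) {
      pse_error("psecontext_bootstrap_error", "mediation bootstrap unstable")
    }
    ci <- unname(stats::quantile(ok, c(0.025, 0.975)))
    p_boot <- max(2 * min(mean(ok <= 0), mean(ok >= 0)), 2 / length(ok))
    n_used <- length(ok)
  }
  out <- data.frame(exposure = exposure, mediator = mediator,
                    outcome = outcome, a = a, b = b, indirect = indirect,
                    direct = cp, total = total, ratio_percent = ratio,
                    ci_low = ci[1], ci_high = ci[2], p_boot = p_boot,
                    n_fit = nn, n_boot_used = n_used,
                    stringsAsFactors = FALSE)
  class(out) <- c("mediation_result", "data.frame")
  out
}

#' Context moderation of an exposure-outcome association
#'
#' Fits the standard mixed model with an exposure-by-moderator interaction
#' (`outcome ~ exposure * moderator + covariates + (1 | site) + (1 | family in
#' site)`), the moderator taken at baseline and z-scored. Reports the
#' interaction coefficient `theta` with Wald and family-bootstrap p-values,
#' and the attenuation index `vr2 = 1 - (slope_favorable /
#' slope_reference)^2`, where `slope_reference` is the conditional exposure
#' effect at the moderator mean and `slope_favorable` at one SD in the
#' direction that weakens the association; clipped to `[0, 1]` and undefined
#' when the reference slope is zero. `vr2` is a reconstruction of the
#' attenuation statistic and reads as the proportion of the squared exposure
#' effect removed by a favorable context.
#'
#' @param cohort a `cohort_table`.
#' @param exposure binary exposure column.
#' @param moderator context-score or PRS column (measured at baseline).
#' @param outcome outcome column.
#' @param wave wave of the outcome (default `"year2"`).
#' @param n_boot bootstrap replicates for the bootstrap p-value (0 skips it).
#' @param seed integer seed.
#' @param dictionary dictionary (defaults to the cohort's).
#' @return a one-row `moderation_result` data.frame with the interaction
#'   estimate, its Wald p, bootstrap p, `vr2`, and the main-effect slope; the
#'   2x2 covariance of (slope, theta) is attached for [simple_slopes()].
#' @export
moderate <- function(cohort, exposure, moderator, outcome, wave = "year2",
                     n_boot = 1000, seed = 1L,
                     dictionary = attr(cohort, "dictionary")) {
  b <- as.data.frame(cohort[cohort$wave == "baseline", , drop = FALSE])
  d <- as.data.frame(cohort[cohort$wave == wave, , drop = FALSE])
  d$.mod <- b[[moderator]][match(d$child_id, b$child_id)]
  vars <- c(outcome, exposure, ".mod", essential_covariates,
            "site_id", "family_id")
  d <- d[, vars, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10L) pse_design_error("too few complete cases for moderation")
  d$.y <- zscore(d[[outcome]])
  d$.mod <- zscore(d$.mod)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$race_ethnicity <- droplevels(stats::relevel(
    factor(d$race_ethnicity,
           levels = c("Asian", "Black", "Hispanic", "White", "Other")),
    ref = "White"))
  d$age_months <- zscore(d$age_months)
  rhs <- paste0(exposure, " * .mod + sex + race_ethnicity + age_months")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fml <- stats::as.formula(paste(".y ~", rhs,
                                 "+ (1 | site_id) + (1 | site_id:family_id)"))
  m <- suppressMessages(lme4::lmer(fml, data = d, REML = TRUE, control = ctrl))
  fe <- lme4::fixef(m)
  V <- as.matrix(stats::vcov(m))
  int_term <- paste0(exposure, ":.mod")
  beta <- unname(fe[[exposure]])
  theta <- unname(fe[[int_term]])
  se_theta <- sqrt(V[int_term, int_term])
  p_wald <- 2 * stats::pnorm(-abs(theta / se_theta))
  vr2 <- if (beta == 0) NA_real_ else {
    lev_fav <- -sign(theta * beta)
    slope_fav <- beta + theta * lev_fav
    min(max(1 - (slope_fav / beta)^2, 0), 1)
  }

  p_boot <- NA_real_
  if (n_boot > 0) {
    mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = d)
    ci_idx <- match(int_term, colnames(mm))
    rows_by_fam <- split(seq_len(nrow(d)), d$family_id)
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    th <- rep(NA_real_, n_boot)
    nf <- length(rows_by_fam)
    yv <- d$.y
    for (r in seq_len(n_boot)) {
      idx <- unlist(rows_by_fam[sample.int(nf, nf, replace = TRUE)],
                    use.names = FALSE)
      f <- stats::lm.fit(mm[idx, , drop = FALSE], yv[idx])
      th[r] <- f$coefficients[ci_idx]
    }
    okb <- th[!is.na(th)]
    p_boot <- max(2 * min(mean(okb <= 0), mean(okb >= 0)), 2 / length(okb))
  }
  out <- data.frame(exposure = exposure, moderator = moderator,
                    outcome = outcome, wave = wave, beta_main = beta,
                    theta = theta, se_theta = se_theta, p = p_wald,
                    p_boot = p_boot, vr2 = vr2, n_fit = nrow(d),
                    stringsAsFactors = FALSE)
  v2 <- V[c(exposure, int_term), c(exposure, int_term)]
  attr(out, "vcov_slope_theta") <- v2
  class(out) <- c("moderation_result", "data.frame")
  out
}

#' Conditional exposure effects at chosen moderator levels
#'
#' Simple slopes `beta + theta * level` of a fitted moderation model at
#' moderator levels in SD units (default -1, 0, +1), with delta-method
#' standard errors from the joint covariance of the main effect and the
#' interaction.
#'
#' @param moderation a `moderation_result` from [moderate()].
#' @param levels numeric moderator levels in SD units.
#' @return data.frame with columns `level`, `slope`, `se`.
#' @export
simple_slopes <- function(moderation, levels = c(-1, 0, 1)) {
  stopifnot(inherits(moderation, "moderation_result"))
  V <- attr(moderation, "vcov_slope_theta")
  b <- moderation$beta_main
  t <- moderation$theta
  slope <- b + t * levels
  se <- sqrt(V[1, 1] + levels^2 * V[2, 2] + 2 * levels * V[1, 2])
  data.frame(level = levels, slope = slope, se = se)
}
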