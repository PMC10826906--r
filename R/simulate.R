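#' Specification for the synthetic cohort generator
#'
#' Describes an ABCD-like two-wave cohort with known ground truth: children
#' clustered in families (a fraction of families contribute a sibling pair)
#' within study sites; four correlated binary prenatal exposures drawn from a
#' Gaussian copula at fixed marginal prevalences, with optional logit-scale
#' loadings from latent context factors (confounding); context-score
#' components generated as noisy proxies of the latent contexts; outcomes with
#' site and family random intercepts and per-wave residuals; an optional
#' baseline brain mediator path; and optional exposure-by-context
#' interactions.
#'
#' Default prevalences are 59.8% (caffeine), 25.7% (alcohol), 13.2% (tobacco)
#' and 5.6% (marijuana). Default variance components are sigma2_site 0.02,
#' sigma2_family 0.20, sigma2_resid 0.78 (summing to 1 so that the
#' standardized coefficient recovered by the mixed model targets the
#' generator's `beta`). The default sibling fraction 0.19 reproduces a cohort
#' of ~9,838 children from ~8,260 families.
#'
#' @param n_children number of children.
#' @param n_sites number of study sites.
#' @param sibling_fraction fraction of families contributing two children.
#' @param exposure_prevalence named vector of marginal exposure prevalences.
#' @param exposure_latent_correlation 4x4 positive semi-definite latent
#'   correlation matrix (unit diagonal) for the copula.
#' @param confounding named list: for each latent context (`birth`, `family`,
#'   `society`, `genetic`), a list with `on_exposure` (named vector of
#'   logit-scale latent loadings per substance) and `on_outcome` (scalar
#'   effect of the latent context on every outcome).
#' @param true_beta data.frame with columns `substance`, `outcome`, `wave`,
#'   `beta`: direct standardized exposure effects.
#' @param dose_beta data.frame with columns `substance`, `outcome`, `wave`,
#'   `beta`: effects of the z-scored log1p pregnancy-total consumption.
#' @param mediation `NULL` or list with `exposure`, `mediator`, `outcome`,
#'   `a`, `b`, `c_prime`: baseline mediator `M = a X + e`, year-2 outcome
#'   `Y = b M + c' X + e` (residual variances chosen so both have unit
#'   variance).
#' @param moderation `NULL` or data.frame with columns `substance`, `context`,
#'   `outcome`, `theta`: interaction effects `theta * X * C` added at both
#'   waves.
#' @param sigma2_site,sigma2_family,sigma2_resid variance components of the
#'   outcome model.
#' @param continuation named vector: probability that an exposed mother
#'   continued use after pregnancy knowledge (alcohol low, tobacco higher).
#' @param component_noise_sd noise SD of the continuous context-score
#'   components around their latent context (small values make the built
#'   scores sharp proxies of the latents).
#' @param n_generic_outcomes number of additional independent generic outcomes
#'   (`y01`, `y02`, ...) for battery-level error-control experiments.
#' @param rng_seed integer seed.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_children = 9838,
                           n_sites = 22,
                           sibling_fraction = 0.19,
                           exposure_prevalence = c(caffeine = 0.598,
                                                   alcohol = 0.257,
                                                   tobacco = 0.132,
                                                   marijuana = 0.056),
                           exposure_latent_correlation = default_exposure_correlation(),
                           confounding = list(),
                           true_beta = empty_effects(),
                           dose_beta = empty_effects(),
                           mediation = NULL,
                           moderation = NULL,
                           sigma2_site = 0.02,
                           sigma2_family = 0.20,
                           sigma2_resid = 0.78,
                           continuation = c(alcohol = 0.2, tobacco = 0.5,
                                            marijuana = 0.4),
                           component_noise_sd = 0.2,
                           n_generic_outcomes = 0,
                           rng_seed = 1L) {
  if (any(exposure_prevalence <= 0 | exposure_prevalence >= 1)) {
    pse_domain_error("exposure prevalences must lie in (0, 1)")
  }
  R <- exposure_latent_correlation
  if (!isTRUE(all.equal(unname(diag(R)), rep(1, 4))) ||
      !isTRUE(all.equal(R, t(R))) || min(eigen(R, symmetric = TRUE,
                                               only.values = TRUE)$values) < -1e-8) {
    pse_domain_error("exposure_latent_correlation must be symmetric PSD with unit diagonal")
  }
  if (any(c(sigma2_site, sigma2_family, sigma2_resid) < 0)) {
    pse_domain_error("variance components must be nonnegative")
  }
  if (sibling_fraction < 0 || sibling_fraction >= 1) {
    pse_domain_error("sibling_fraction must lie in [0, 1)")
  }
  structure(list(n_children = n_children, n_sites = n_sites,
                 sibling_fraction = sibling_fraction,
                 exposure_prevalence = exposure_prevalence,
                 exposure_latent_correlation = R,
                 confounding = confounding, true_beta = true_beta,
                 dose_beta = dose_beta, mediation = mediation,
                 moderation = moderation, sigma2_site = sigma2_site,
                 sigma2_family = sigma2_family, sigma2_resid = sigma2_resid,
                 continuation = continuation,
                 component_noise_sd = component_noise_sd,
                 n_generic_outcomes = n_generic_outcomes,
                 rng_seed = rng_seed),
            class = "generator_spec")
}

#' Default latent correlation among the four exposures
#'
#' Moderate positive co-occurrence, strongest between tobacco and marijuana;
#' free parameters of the generator (the source cohort's full matrix is not
#' published).
#' @return 4x4 correlation matrix.
#' @export
default_exposure_correlation <- function() {
  s <- c("caffeine", "alcohol", "tobacco", "marijuana")
  R <- diag(4)
  dimnames(R) <- list(s, s)
  R["caffeine", "alcohol"] <- R["alcohol", "caffeine"] <- 0.25
  R["caffeine", "tobacco"] <- R["tobacco", "caffeine"] <- 0.10
  R["caffeine", "marijuana"] <- R["marijuana", "caffeine"] <- 0.10
  R["alcohol", "tobacco"] <- R["tobacco", "alcohol"] <- 0.30
  R["alcohol", "marijuana"] <- R["marijuana", "alcohol"] <- 0.25
  R["tobacco", "marijuana"] <- R["marijuana", "tobacco"] <- 0.45
  R
}

#' Empty effect table (no true effects)
#' @return zero-row data.frame with columns `substance`, `outcome`, `wave`,
#'   `beta`.
#' @export
empty_effects <- function() {
  data.frame(substance = character(), outcome = character(),
             wave = character(), beta = numeric(), stringsAsFactors = FALSE)
}

effect_row <- function(substance, outcome, wave, beta) {
  data.frame(substance = substance, outcome = outcome, wave = wave,
             beta = beta, stringsAsFactors = FALSE)
}

default_outcome_names <- function(n_generic = 0) {
  base <- c("sleep_problems", "upps_sensation_seeking", "cbcl_total",
            "cbcl_internalizing", "cbcl_externalizing", "cbcl_attention",
            "cog_crystallized", "cog_fluid", "brain_sa_global",
            "brain_vol_midtemporal", "rsfc_con_subc")
  c(base, if (n_generic > 0) sprintf("y%02d", seq_len(n_generic)))
}

#' Simulate a synthetic two-wave cohort with known ground truth
#'
#' Draws the cohort described by a [generator_spec()]: family/site structure,
#' demographics, four correlated binary exposures (Gaussian copula thresholded
#' at prevalence-matching quantiles of the shifted latent, so marginal
#' prevalences are preserved exactly even under confounding), exposure report
#' fields (before/after-knowledge flags and quantities), context-score
#' components, outcome battery at two waves with site and family random
#' intercepts, optional mediator path and interactions.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed (defaults to the spec's `rng_seed`).
#' @return list with elements `cohort` (a `cohort_table` with the matching
#'   dictionary attached) and `truth` (a `ground_truth` list carrying the
#'   realized latent contexts, exposures, random effects and the spec).
#' @export
simulate_cohort <- function(spec, seed = spec$rng_seed) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- spec$n_children
  substances <- c("caffeine", "alcohol", "tobacco", "marijuana")
  contexts <- c("birth", "family", "society", "genetic")

  ## family / site structure: a sibling_fraction of families have 2 children
  n_fam <- max(2L, round(n / (1 + spec$sibling_fraction)))
  n_two <- n - n_fam
  fam_sizes <- c(rep(2L, n_two), rep(1L, n_fam - n_two))
  family_of_child <- rep(seq_len(n_fam), times = fam_sizes)
  site_of_family <- sample.int(spec$n_sites, n_fam, replace = TRUE)
  site_of_child <- site_of_family[family_of_child]
  child_id <- sprintf("C%05d", seq_len(n))
  family_id <- sprintf("F%05d", family_of_child)
  site_id <- sprintf("S%02d", site_of_child)

  ## demographics
  sex <- ifelse(stats::runif(n) < 0.479, "female", "male")
  race <- sample(c("Asian", "Black", "Hispanic", "White", "Other"), n,
                 replace = TRUE, prob = c(0.021, 0.150, 0.200, 0.520, 0.109))
  age0 <- as.integer(round(stats::runif(n, 107, 131)))
  age2 <- age0 + 24L + sample(-2:2, n, replace = TRUE)

  ## latent contexts, shared within family
  ctx_fam <- matrix(stats::rnorm(n_fam * 4), n_fam, 4,
                    dimnames = list(NULL, contexts))
  C <- ctx_fam[family_of_child, , drop = FALSE]

  ## exposures: Gaussian copula + context logit shifts, prevalence-matching
  Z <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = spec$exposure_latent_correlation)
  colnames(Z) <- substances
  X <- matrix(0L, n, 4, dimnames = list(NULL, substances))
  for (s in substances) {
    shift <- rep(0, n)
    ssq <- 0
    for (ctx in names(spec$confounding)) {
      g <- spec$confounding[[ctx]]$on_exposure
      if (!is.null(g) && s %in% names(g)) {
        shift <- shift + g[[s]] * C[, ctx]
        ssq <- ssq + g[[s]]^2
      }
    }
    thr <- stats::qnorm(1 - spec$exposure_prevalence[[s]], sd = sqrt(1 + ssq))
    X[, s] <- as.integer(Z[, s] + shift > thr)
  }

  ## report fields
  d <- data.frame(child_id, family_id, site_id, sex, race_ethnicity = race,
                  stringsAsFactors = FALSE)
  d$caffeine_use <- ifelse(X[, "caffeine"] == 1L, "yes", "no")
  freq <- sample(c("daily", "weekly", "monthly"), n, replace = TRUE,
                 prob = c(0.55, 0.30, 0.15))
  d$caffeine_freq <- ifelse(X[, "caffeine"] == 1L, freq, NA_character_)
  qty <- ifelse(freq == "daily", sample(1:3, n, replace = TRUE),
                sample(1:10, n, replace = TRUE))
  d$caffeine_quantity <- ifelse(X[, "caffeine"] == 1L, qty, 0)
  for (s in c("alcohol", "tobacco", "marijuana")) {
    exposed <- X[, s] == 1L
    cont <- stats::rbinom(n, 1L, spec$continuation[[s]]) == 1L & exposed
    d[[paste0(s, "_before")]] <- ifelse(exposed, "yes", "no")
    d[[paste0(s, "_after")]]  <- ifelse(cont, "yes", "no")
    if (s == "alcohol") {
      rb <- sample(1:6, n, replace = TRUE)
      ra <- sample(1:3, n, replace = TRUE)
      d$alcohol_drinks_week_before <- ifelse(exposed, rb, 0)
      d$alcohol_drinks_week_after  <- ifelse(cont, ra, 0)
    } else {
      rb <- if (s == "tobacco") sample(1:10, n, replace = TRUE)
            else sample(1:3, n, replace = TRUE)
      ra <- pmax(1L, rb - sample(0:2, n, replace = TRUE))
      d[[paste0(s, "_per_day_before")]] <- ifelse(exposed, rb, 0)
      d[[paste0(s, "_per_day_after")]]  <- ifelse(cont, ra, 0)
    }
  }

  ## context-score components: noisy proxies of the family-level latents
  ns <- spec$component_noise_sd
  d$pse_cocaine <- stats::rbinom(n, 1L, stats::plogis(-4 + 1.2 * C[, "birth"]))
  p_yes <- stats::plogis(-1.5 + 0.8 * C[, "birth"])
  u <- stats::runif(n)
  d$obstetric_complications <- ifelse(u < p_yes, 1, ifelse(u < p_yes + 0.1, 0.5, 0))
  d$prenatal_vitamin <- stats::rbinom(n, 1L, stats::plogis(2 - 1.2 * C[, "birth"]))
  d$breastfeeding_months <- pmax(0, 6 - 2.5 * C[, "birth"] + stats::rnorm(n, 0, 2))
  d$family_conflict    <- C[, "family"] + stats::rnorm(n, 0, ns)
  d$parental_education <- 14 - 2 * C[, "family"] + stats::rnorm(n, 0, ns)
  d$family_income      <- 11 - 0.8 * C[, "family"] + stats::rnorm(n, 0, ns)
  d$lead_risk           <- C[, "society"] + stats::rnorm(n, 0, ns)
  d$area_deprivation    <- C[, "society"] + stats::rnorm(n, 0, ns)
  d$neighborhood_safety <- 3 - 0.9 * C[, "society"] + stats::rnorm(n, 0, ns)
  d$family_history_mental <- C[, "genetic"] + stats::rnorm(n, 0, ns)
  d$prs_adhd <- 0.8 * C[, "genetic"] + stats::rnorm(n, 0, ns)
  d$prs_edu  <- -0.7 * C[, "genetic"] + stats::rnorm(n, 0, ns)

  ## nuisance metrics
  icv <- stats::rnorm(n, 1.45e6, 1.2e5)

  ## pregnancy totals for dose effects (same rule as derive_exposures)
  thr_set <- threshold_set()
  totals <- list(
    caffeine = total_consumption("caffeine", quantity = d$caffeine_quantity,
                                 freq = ifelse(is.na(d$caffeine_freq), "daily",
                                               d$caffeine_freq),
                                 thresholds = thr_set) *
      (X[, "caffeine"] == 1L),
    alcohol = total_consumption("alcohol",
                                rate_before = d$alcohol_drinks_week_before,
                                rate_after = d$alcohol_drinks_week_after,
                                thresholds = thr_set),
    tobacco = total_consumption("tobacco",
                                rate_before = d$tobacco_per_day_before,
                                rate_after = d$tobacco_per_day_after,
                                thresholds = thr_set),
    marijuana = total_consumption("marijuana",
                                  rate_before = d$marijuana_per_day_before,
                                  rate_after = d$marijuana_per_day_after,
                                  thresholds = thr_set))

  ## outcomes
  outcome_names <- default_outcome_names(spec$n_generic_outcomes)
  med <- spec$mediation
  var_x <- function(s) {
    p <- spec$exposure_prevalence[[s]]
    p * (1 - p)
  }
  gamma_outcome <- vapply(contexts, function(ctx) {
    g <- spec$confounding[[ctx]]$on_outcome
    if (is.null(g)) 0 else g
  }, numeric(1))

  u_site <- matrix(stats::rnorm(spec$n_sites * length(outcome_names),
                                0, sqrt(spec$sigma2_site)),
                   spec$n_sites, length(outcome_names),
                   dimnames = list(NULL, outcome_names))
  u_fam <- matrix(stats::rnorm(n_fam * length(outcome_names),
                               0, sqrt(spec$sigma2_family)),
                  n_fam, length(outcome_names),
                  dimnames = list(NULL, outcome_names))
  re_truth <- list(u_site = u_site, u_family = u_fam)

  mediator_base <- NULL
  if (!is.null(med)) {
    vx <- var_x(med$exposure)
    s2m <- max(0.05, 1 - med$a^2 * vx)
    mediator_base <- med$a * X[, med$exposure] + stats::rnorm(n, 0, sqrt(s2m))
  }

  gen_outcome <- function(oc, wave) {
    if (!is.null(med) && oc == med$mediator) {
      if (wave == "baseline") return(mediator_base)
      return(mediator_base + stats::rnorm(n, 0, 0.1))
    }
    if (!is.null(med) && oc == med$outcome && wave == "year2") {
      vx <- var_x(med$exposure)
      vm <- stats::var(mediator_base)
      s2 <- max(0.05, 1 - med$b^2 * vm -
                  (med$c_prime^2 + 2 * med$a * med$b * med$c_prime) * vx -
                  spec$sigma2_site - spec$sigma2_family)
      return(med$b * mediator_base + med$c_prime * X[, med$exposure] +
               u_site[site_of_child, oc] + u_fam[family_of_child, oc] +
               stats::rnorm(n, 0, sqrt(s2)))
    }
    y <- u_site[site_of_child, oc] + u_fam[family_of_child, oc] +
      stats::rnorm(n, 0, sqrt(spec$sigma2_resid))
    tb <- spec$true_beta
    tb <- tb[tb$outcome == oc & tb$wave == wave, , drop = FALSE]
    for (i in seq_len(nrow(tb))) {
      y <- y + tb$beta[i] * X[, tb$substance[i]]
    }
    db <- spec$dose_beta
    db <- db[db$outcome == oc & db$wave == wave, , drop = FALSE]
    for (i in seq_len(nrow(db))) {
      y <- y + db$beta[i] * zscore(log1p(totals[[db$substance[i]]]))
    }
    for (ctx in contexts) {
      if (gamma_outcome[[ctx]] != 0) y <- y + gamma_outcome[[ctx]] * C[, ctx]
    }
    mo <- spec$moderation
    if (!is.null(mo)) {
      mo <- mo[mo$outcome == oc, , drop = FALSE]
      for (i in seq_len(nrow(mo))) {
        y <- y + mo$theta[i] * X[, mo$substance[i]] * C[, mo$context[i]]
      }
    }
    y
  }

  make_wave <- function(wave, age) {
    w <- d
    w$wave <- wave
    w$age_months <- age
    w$icv <- icv
    w$head_motion <- abs(stats::rnorm(n, 0.15, 0.05))
    w$image_quality <- stats::rnorm(n, 3, 0.5)
    for (oc in outcome_names) w[[oc]] <- gen_outcome(oc, wave)
    w
  }
  ## draw outcome residuals wave by wave (baseline first) for reproducibility
  base_rows <- make_wave("baseline", age0)
  year2_rows <- make_wave("year2", age2)
  out <- rbind(base_rows, year2_rows)
  out <- out[order(out$child_id, out$wave), , drop = FALSE]
  rownames(out) <- NULL

  dict <- default_dictionary(
    extra_outcomes = if (spec$n_generic_outcomes > 0)
      sprintf("y%02d", seq_len(spec$n_generic_outcomes)) else character())
  cohort <- as_cohort_table(out, dict)

  truth <- structure(list(spec = spec, seed = seed,
                          latent_contexts = ctx_fam,
                          family_of_child = family_of_child,
                          site_of_family = site_of_family,
                          exposures = X, random_effects = re_truth,
                          mediator_baseline = mediator_base),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Library of named generator scenarios
#'
#' Fixed ground-truth settings exercised by the test suite, all on the focal
#' pair PSE-alcohol and CBCL total problems unless stated: `null` (no effects
#' anywhere), `confounded` (no direct effect; the family latent context both
#' raises the alcohol-exposure propensity and the outcome), `persistent`
#' (equal effects 0.05 at both waves), `transient` (0.08 at baseline, 0 at
#' year 2), `late_onset` (0 at baseline, 0.08 at year 2), `mediated` (a = 0.5,
#' b = 0.4, c' = 0.3 through the global surface area, no site/family variance
#' since mediation works on one child per family), `moderated` (main effect
#' 0.10 with family-context interaction theta = 0.04), and `dose_response`
#' (slope 0.05 on z-scored log1p total alcohol consumption at year 2).
#'
#' @param n_children cohort size applied to every scenario.
#' @return named list of [generator_spec()] objects.
#' @export
scenario_library <- function(n_children = 9838) {
  both_waves <- function(substance, outcome, b0, b2) {
    rbind(effect_row(substance, outcome, "baseline", b0),
          effect_row(substance, outcome, "year2", b2))
  }
  list(
    null = generator_spec(n_children = n_children),
    confounded = generator_spec(
      n_children = n_children,
      confounding = list(family = list(on_exposure = c(alcohol = 0.5),
                                       on_outcome = 0.3))),
    persistent = generator_spec(
      n_children = n_children,
      true_beta = both_waves("alcohol", "cbcl_total", 0.05, 0.05)),
    transient = generator_spec(
      n_children = n_children,
      true_beta = both_waves("alcohol", "cbcl_total", 0.08, 0)),
    late_onset = generator_spec(
      n_children = n_children,
      true_beta = both_waves("alcohol", "cbcl_total", 0, 0.08)),
    mediated = generator_spec(
      n_children = n_children,
      sigma2_site = 0, sigma2_family = 0, sigma2_resid = 1,
      mediation = list(exposure = "alcohol", mediator = "brain_sa_global",
                       outcome = "cbcl_total", a = 0.5, b = 0.4,
                       c_prime = 0.3)),
    moderated = generator_spec(
      n_children = n_children,
      true_beta = both_waves("alcohol", "cbcl_total", 0.10, 0.10),
      moderation = data.frame(substance = "alcohol", context = "family",
                              outcome = "cbcl_total", theta = 0.04,
                              stringsAsFactors = FALSE)),
    dose_response = generator_spec(
      n_children = n_children,
      dose_beta = effect_row("alcohol", "cbcl_total", "year2", 0.05))
  )
}

#' Serialize a ground-truth object to JSON
#' @param truth a `ground_truth`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  x <- truth
  x$spec <- unclass(x$spec)
  x$spec$exposure_latent_correlation <-
    as.data.frame(x$spec$exposure_latent_correlation)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
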