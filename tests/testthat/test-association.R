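# Independent step-up implementation used as the BH oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

test_that("FDR adjustment matches a hand step-up computation", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(fdr_adjust(p)$p_fdr, c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(0.03)$p_fdr, 0.03)
  expect_equal(fdr_adjust(rep(1, 5))$p_fdr, rep(1, 5))
  expect_false(any(fdr_adjust(rep(1, 5))$reject))
  set.seed(1)
  for (r in 1:5) {
    pr <- stats::runif(20)^2
    adj <- fdr_adjust(pr)$p_fdr
    expect_equal(adj, bh_oracle(pr))
    expect_true(all(diff(adj[order(pr)]) >= -1e-12))  # monotone in rank
  }
  ## equal raw p-values get equal adjusted values
  pr <- c(0.2, 0.01, 0.2, 0.05)
  adj <- fdr_adjust(pr)$p_fdr
  expect_equal(adj[1], adj[3])
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "psecontext_domain_error")
  expect_error(fdr_adjust(0.5, alpha = 0), class = "psecontext_domain_error")
})

test_that("mixed-model beta equals the OLS beta when clusters are absent", {
  ## Under zero true variance components, the REML estimates sit on the zero
  ## boundary in a sizable share of datasets; whenever they do, the GLS fixed
  ## effects must coincide with plain OLS. Loop replicates, require the
  ## boundary case to occur, and demand 1e-6 relative agreement there.
  spec <- generator_spec(n_children = 1000, sigma2_site = 0,
                         sigma2_family = 0, sigma2_resid = 1)
  n_boundary <- 0L
  for (s in 1:8) {
    co <- derive_exposures(simulate_cohort(spec, seed = s)$cohort)
    res <- fit_association(co, model_spec("cbcl_total", "pse_alcohol"))
    ## OLS oracle with the same standardization convention
    d <- as.data.frame(co[co$wave == "baseline", ])
    d$y <- as.numeric(scale(d$cbcl_total))
    d$age <- as.numeric(scale(d$age_months))
    d$race_ethnicity <- stats::relevel(factor(d$race_ethnicity), ref = "White")
    m <- suppressMessages(lme4::lmer(
      y ~ pse_alcohol + sex + race_ethnicity + age +
        (1 | site_id) + (1 | site_id:family_id), data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    if (sum(as.data.frame(lme4::VarCorr(m))$vcov[1:2]) < 1e-10) {
      n_boundary <- n_boundary + 1L
      ols <- stats::lm(y ~ pse_alcohol + sex + race_ethnicity + age, data = d)
      b_ols <- stats::coef(ols)[["pse_alcohol"]]
      expect_lt(abs(res$beta - b_ols) / abs(b_ols), 1e-6)
    }
  }
  expect_gte(n_boundary, 1L)
})

test_that("standardized beta is invariant to affine outcome rescaling", {
  co <- small_cohort("persistent", n = 1200, seed = 19)
  r0 <- fit_association(co, model_spec("cbcl_total", "pse_alcohol"))
  co$cbcl_total <- 7.3 * co$cbcl_total - 42
  r1 <- fit_association(co, model_spec("cbcl_total", "pse_alcohol"))
  expect_equal(r1$beta, r0$beta, tolerance = 1e-8)
  expect_equal(r1$se, r0$se, tolerance = 1e-8)
})

test_that("design guards reject degenerate model inputs", {
  co <- small_cohort("null", n = 400, seed = 23)
  co2 <- co
  co2$cbcl_total <- 5
  expect_error(fit_association(co2, model_spec("cbcl_total", "pse_alcohol")),
               class = "psecontext_design_error")
  co3 <- co
  co3$pse_alcohol <- 0L
  expect_error(fit_association(co3, model_spec("cbcl_total", "pse_alcohol")),
               class = "psecontext_design_error")
})

test_that("screen_battery refit fast path agrees with direct fits", {
  co <- small_cohort("persistent", n = 1200, seed = 19)
  outs <- c("cbcl_total", "cbcl_internalizing", "sleep_problems")
  sb <- screen_battery(co, "pse_alcohol", outs, wave = "baseline")
  for (oc in outs) {
    direct <- fit_association(co, model_spec(oc, "pse_alcohol"))
    expect_equal(sb$beta[sb$outcome == oc], direct$beta, tolerance = 1e-6,
                 label = paste("beta for", oc))
    expect_equal(sb$se[sb$outcome == oc], direct$se, tolerance = 1e-6)
  }
})

test_that("screen_battery handles empty batteries and per-cell failures", {
  co <- small_cohort("null", n = 400, seed = 23)
  empty <- screen_battery(co, "pse_alcohol", character())
  expect_identical(nrow(empty), 0L)

  co$cog_fluid <- 1  # constant outcome: this cell must fail, others survive
  sb <- screen_battery(co, "pse_alcohol", c("cbcl_total", "cog_fluid"))
  expect_true(is.na(sb$beta[sb$outcome == "cog_fluid"]))
  expect_match(sb$fallback[sb$outcome == "cog_fluid"], "^failed:")
  expect_false(is.na(sb$beta[sb$outcome == "cbcl_total"]))
})

test_that("FDR families are exposure-by-domain: p_fdr never below raw p", {
  co <- small_cohort("persistent", n = 1200, seed = 19)
  sb <- screen_battery(co, c("pse_alcohol", "pse_caffeine"),
                       c("cbcl_total", "cbcl_attention", "sleep_problems",
                         "cog_fluid"), wave = "baseline")
  ok <- !is.na(sb$p)
  expect_true(all(sb$p_fdr[ok] >= sb$p[ok] - 1e-12))
  ## a domain with a single outcome is its own family: p_fdr == p there
  behav <- sb$domain == "behavioral"
  expect_equal(sb$p_fdr[behav], sb$p[behav])
})

test_that("adjusted-mode models include co-exposures and context scores", {
  co <- small_cohort("persistent", n = 1200, seed = 19)
  sb <- screen_battery(co, c("pse_alcohol", "pse_caffeine", "pse_tobacco",
                             "pse_marijuana"), "cbcl_total",
                       mode = "context_adjusted")
  expect_identical(nrow(sb), 4L)  # one joint model, one row per exposure
  expect_identical(unique(sb$n_fit), sb$n_fit[1])
})

test_that("robustness filter applies the verdict rules and reduction summary", {
  mk <- function(exposure, outcome, p_fdr, mode) {
    data.frame(exposure = exposure, outcome = outcome, wave = "baseline",
               beta = 0.1, se = 0.02, p = p_fdr / 2, p_fdr = p_fdr,
               n_fit = 100L, mode = mode, stringsAsFactors = FALSE)
  }
  unadj <- rbind(mk("pse_tobacco", "o1", 0.01, "unadjusted_context"),
                 mk("pse_tobacco", "o2", 0.02, "unadjusted_context"),
                 mk("pse_alcohol", "o1", 0.01, "unadjusted_context"),
                 mk("pse_alcohol", "o2", 0.60, "unadjusted_context"))
  adj <- rbind(mk("pse_tobacco", "o1", 0.20, "context_adjusted"),
               mk("pse_tobacco", "o2", 0.90, "context_adjusted"),
               mk("pse_alcohol", "o1", 0.01, "context_adjusted"),
               mk("pse_alcohol", "o2", 0.70, "context_adjusted"))
  v <- robustness_filter(unadj, adj, alpha = 0.05)
  get <- function(e, o) v$verdict[v$exposure == e & v$outcome == o]
  expect_identical(get("pse_tobacco", "o1"), "confounded")
  expect_identical(get("pse_alcohol", "o1"), "robust")
  expect_identical(get("pse_alcohol", "o2"), "never_significant")
  red <- reduction_summary(v)
  ## every tobacco association lost after adjustment -> 100% reduction
  expect_equal(red$reduction_percent[red$exposure == "pse_tobacco"], 100)
  expect_equal(red$reduction_percent[red$exposure == "pse_alcohol"], 0)
  expect_error(robustness_filter(unadj[-1, ], adj, alpha = 0.05),
               class = "psecontext_contract_error")
})
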