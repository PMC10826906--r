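# Literal transcription of the verbal rule table, kept independent of the
# implementation: persistent = significant at both waves; transient =
# baseline-only significance with a significant decrease (CI on the delta
# excluding zero opposite the baseline sign); late-onset = follow-up-only
# significance with a significant increase (CI excluding zero along the
# year-2 sign); everything else unclassified.
label_oracle <- function(s0, s2, ci, b0, b2) {
  ci_below <- ci[2] < 0
  ci_above <- ci[1] > 0
  if (s0 && s2) return("persistent")
  if (s0 && !s2) {
    if (b0 >= 0 && ci_below) return("transient")
    if (b0 < 0 && ci_above) return("transient")
    return("unclassified")
  }
  if (!s0 && s2) {
    if (b2 >= 0 && ci_above) return("late_onset")
    if (b2 < 0 && ci_below) return("late_onset")
    return("unclassified")
  }
  "unclassified"
}

test_that("pattern labels match the rule table over the full input space", {
  cis <- list(below = c(-0.3, -0.1), covers = c(-0.1, 0.1), above = c(0.1, 0.3))
  for (s0 in c(TRUE, FALSE)) for (s2 in c(TRUE, FALSE)) {
    for (ci in cis) for (b0 in c(0.05, -0.05)) for (b2 in c(0.05, -0.05)) {
      got <- classify_pattern_label(s0, s2, ci[1], ci[2], b0, b2)
      expect_identical(got, label_oracle(s0, s2, ci, b0, b2),
                       label = sprintf("s0=%s s2=%s ci=[%g,%g] b0=%g b2=%g",
                                       s0, s2, ci[1], ci[2], b0, b2))
    }
  }
  expect_error(classify_pattern_label(TRUE, TRUE, 0.2, -0.2))
})

test_that("published delta CIs map to the published labels", {
  ## baseline-significant association whose effect dropped: CI [-0.063,-0.008]
  expect_identical(classify_pattern_label(TRUE, FALSE, -0.063, -0.008,
                                          beta_baseline = 0.06),
                   "transient")
  ## follow-up-only association whose effect rose: CI [0.001, 0.067]
  expect_identical(classify_pattern_label(FALSE, TRUE, 0.001, 0.067,
                                          beta_year2 = 0.05),
                   "late_onset")
})

test_that("identical outcomes at both waves give a degenerate zero delta", {
  co <- small_cohort("null", n = 600, seed = 31, derived = TRUE)
  df <- as.data.frame(co)
  base <- df[df$wave == "baseline", ]
  twin <- base
  twin$wave <- "year2"
  twin$age_months <- base$age_months + 24L
  dup <- as_cohort_table(rbind(base, twin), attr(co, "dictionary"))
  dup <- dup[order(dup$child_id, dup$wave), ]
  bd <- bootstrap_delta(dup, "pse_alcohol", "cbcl_total", n_boot = 100,
                        seed = 5)
  expect_equal(bd$delta, 0, tolerance = 1e-10)
  expect_equal(bd$ci_low, 0, tolerance = 1e-10)
  expect_equal(bd$ci_high, 0, tolerance = 1e-10)
})

test_that("bootstrap_delta is reproducible given the seed", {
  co <- small_cohort("transient", n = 1000, seed = 37)
  a <- bootstrap_delta(co, "pse_alcohol", "cbcl_total", n_boot = 120, seed = 9)
  b <- bootstrap_delta(co, "pse_alcohol", "cbcl_total", n_boot = 120, seed = 9)
  expect_identical(a, b)
  c_ <- bootstrap_delta(co, "pse_alcohol", "cbcl_total", n_boot = 120,
                        seed = 10)
  expect_false(identical(a$ci_low, c_$ci_low))
  expect_error(bootstrap_delta(co, "pse_alcohol", "cbcl_total", n_boot = 50),
               class = "psecontext_domain_error")
})

test_that("a real effect drop is detected as a negative delta CI", {
  co <- small_cohort("transient", n = 9838, seed = 41)
  bd <- bootstrap_delta(co, "pse_alcohol", "cbcl_total", n_boot = 300,
                        seed = 11)
  expect_lt(bd$ci_high, 0)
  expect_lt(abs(bd$delta - (-0.08)), 0.10)
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  widths <- vapply(c(1000, 4000), function(n) {
    co <- small_cohort("persistent", n = n, seed = 43)
    bd <- bootstrap_delta(co, "pse_alcohol", "cbcl_total", n_boot = 200,
                          seed = 13)
    bd$ci_high - bd$ci_low
  }, numeric(1))
  expect_gt(widths[1] / widths[2], 1.4)
  expect_lt(widths[1] / widths[2], 2.9)
})

test_that("dose-response models recover a consumption slope and reject nulls", {
  co <- small_cohort("dose_response", n = 6000, seed = 47)
  res <- dose_response(co, "alcohol", "cbcl_total", wave = "year2",
                       mode = "unadjusted_context")
  expect_gt(res$beta, 0)
  expect_lt(res$p, 0.05)
  expect_lt(abs(res$beta - 0.05), 3 * res$se)

  ## permuting the dose across children kills the association
  co2 <- co
  set.seed(1)
  perm <- sample(length(unique(co2$child_id)))
  for (w in c("baseline", "year2")) {
    idx <- which(co2$wave == w)
    co2$total_alcohol[idx] <- co2$total_alcohol[idx][perm]
  }
  res2 <- dose_response(co2, "alcohol", "cbcl_total", wave = "year2",
                        mode = "unadjusted_context")
  expect_lt(abs(res2$beta), 2 * res2$se)

  co3 <- co
  co3$total_alcohol <- 0
  expect_error(dose_response(co3, "alcohol", "cbcl_total", wave = "year2",
                             mode = "unadjusted_context"),
               class = "psecontext_design_error")
})

test_that("pattern contrasts run per level and handle empty exposure sets", {
  co <- small_cohort("persistent", n = 4000, seed = 49)
  res <- pattern_contrasts(co, "alcohol", "cbcl_total", wave = "baseline",
                           mode = "unadjusted_context")
  expect_gt(nrow(res), 1)
  expect_true(all(grepl("^alcohol:", res$exposure)))
  expect_true(all(res$p_fdr >= res$p - 1e-12))

  co2 <- co
  co2$pse_alcohol <- 0L
  co2$pattern_alcohol <- NA_character_
  expect_warning(
    out <- pattern_contrasts(co2, "alcohol", "cbcl_total",
                             mode = "unadjusted_context"),
    "no children exposed")
  expect_identical(nrow(out), 0L)
})
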