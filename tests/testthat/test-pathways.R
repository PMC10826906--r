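test_that("one_per_family keeps exactly one child per family", {
  df <- data.frame(
    child_id = c("C1", "C2", "C3", "C4", "C5"),
    family_id = c("F1", "F2", "F2", "F3", "F3"),
    site_id = "S1", wave = "baseline", stringsAsFactors = FALSE)
  out <- one_per_family(df, seed = 3)
  expect_identical(nrow(out), 3L)
  expect_identical(anyDuplicated(out$family_id), 0L)

  all_single <- data.frame(child_id = c("A", "B"), family_id = c("F1", "F2"),
                           site_id = "S1", wave = "baseline",
                           stringsAsFactors = FALSE)
  expect_identical(one_per_family(all_single, seed = 1)$child_id, c("A", "B"))

  expect_identical(one_per_family(df, seed = 7)$child_id,
                   one_per_family(df, seed = 7)$child_id)
  ## invariant to record order
  shuf <- df[c(4, 2, 5, 1, 3), ]
  expect_identical(sort(one_per_family(df, seed = 7)$child_id),
                   sort(one_per_family(shuf, seed = 7)$child_id))
})

test_that("mediation decomposition is an exact linear identity", {
  co <- small_cohort("mediated", n = 2500, seed = 61)
  single <- one_per_family(co, seed = 2)
  res <- mediate(single, "pse_alcohol", "brain_sa_global", "cbcl_total",
                 n_boot = 0)
  expect_equal(res$total, res$indirect + res$direct, tolerance = 1e-10)
  ## oracle: the total effect from the reduced-form regression on one sample
  b <- as.data.frame(single[single$wave == "baseline", ])
  y2 <- as.data.frame(single[single$wave == "year2", ])
  b$.y <- as.numeric(scale(y2$cbcl_total[match(b$child_id, y2$child_id)]))
  b$.age <- as.numeric(scale(b$age_months))
  b$race_ethnicity <- stats::relevel(factor(b$race_ethnicity), ref = "White")
  red <- stats::lm(.y ~ pse_alcohol + sex + race_ethnicity + .age +
                     factor(site_id), data = b)
  expect_equal(res$total, stats::coef(red)[["pse_alcohol"]],
               tolerance = 1e-8)
})

test_that("mediated-scenario paths and ratio are recovered", {
  co <- small_cohort("mediated", n = 4000, seed = 63)
  single <- one_per_family(co, seed = 2)
  res <- mediate(single, "pse_alcohol", "brain_sa_global", "cbcl_total",
                 n_boot = 300, seed = 5)
  expect_lt(abs(res$a - 0.5), 0.12)
  expect_lt(abs(res$b - 0.4), 0.06)
  expect_lt(abs(res$indirect - 0.20), 0.06)
  expect_lt(abs(res$ratio_percent - 40), 9)
  expect_gt(res$ci_low, 0)  # indirect clearly positive here
  expect_lte(res$p_boot, 0.05)
})

test_that("ratio is invariant to affine rescaling of the outcome", {
  co <- small_cohort("mediated", n = 2500, seed = 61)
  single <- one_per_family(co, seed = 2)
  r0 <- mediate(single, "pse_alcohol", "brain_sa_global", "cbcl_total",
                n_boot = 0)
  single$cbcl_total <- 12 * single$cbcl_total + 100
  r1 <- mediate(single, "pse_alcohol", "brain_sa_global", "cbcl_total",
                n_boot = 0)
  expect_equal(r1$ratio_percent, r0$ratio_percent, tolerance = 1e-8)
  expect_equal(r1$indirect, r0$indirect, tolerance = 1e-8)
})

test_that("an unrelated mediator yields a near-zero indirect effect", {
  co <- small_cohort("null", n = 2500, seed = 65)
  single <- one_per_family(co, seed = 2)
  res <- mediate(single, "pse_alcohol", "brain_sa_global", "cbcl_total",
                 n_boot = 200, seed = 7)
  expect_lt(abs(res$indirect), 0.02)
  expect_lte(res$ci_low, 0)
  expect_gte(res$ci_high, 0)

  single$brain_sa_global <- 1
  expect_error(mediate(single, "pse_alcohol", "brain_sa_global",
                       "cbcl_total", n_boot = 0),
               class = "psecontext_design_error")
})

test_that("moderation recovers the interaction and its attenuation index", {
  co <- small_cohort("moderated", n = 9838, seed = 67)
  res <- moderate(co, "pse_alcohol", "ctx_family", "cbcl_total",
                  wave = "year2", n_boot = 300, seed = 9)
  expect_gt(res$theta, 0)  # family risk amplifies the association
  expect_lt(abs(res$theta - 0.04), 3 * res$se_theta)
  expect_true(res$vr2 >= 0 && res$vr2 <= 1)
  expect_true(res$p_boot > 0 && res$p_boot <= 1)
  ## vr2 agrees with the simple-slopes route: favorable level is the one
  ## that shrinks the conditional slope
  ss <- simple_slopes(res, levels = c(-1, 0, 1))
  fav <- ss$slope[which.min(abs(ss$slope[c(1, 3)]))[1] * 2 - 1]
  expect_equal(res$vr2, 1 - (fav / ss$slope[2])^2, tolerance = 1e-8)
})

test_that("simple slopes follow the linear arithmetic of the fit", {
  mk_mod <- function(beta, theta, V = diag(c(4e-4, 1e-4))) {
    out <- data.frame(exposure = "x", moderator = "m", outcome = "y",
                      wave = "year2", beta_main = beta, theta = theta,
                      se_theta = sqrt(V[2, 2]), p = NA_real_,
                      p_boot = NA_real_, vr2 = NA_real_, n_fit = 100L,
                      stringsAsFactors = FALSE)
    attr(out, "vcov_slope_theta") <- V
    class(out) <- c("moderation_result", "data.frame")
    out
  }
  ## beta 0.10, theta 0.03 at level -1 -> slope 0.07
  ss <- simple_slopes(mk_mod(0.10, 0.03), levels = c(-1, 0, 1))
  expect_equal(ss$slope, c(0.07, 0.10, 0.13))
  ## no interaction -> identical slopes everywhere
  ss0 <- simple_slopes(mk_mod(0.10, 0), levels = c(-2, 0, 2))
  expect_true(all(ss0$slope == 0.10))
  ## slopes at +/-1 SD are symmetric about the slope at 0
  ss1 <- simple_slopes(mk_mod(0.08, 0.02), levels = c(-1, 0, 1))
  expect_equal(mean(ss1$slope[c(1, 3)]), ss1$slope[2])
})

test_that("a null moderator produces no interaction signal", {
  co <- small_cohort("persistent", n = 3000, seed = 69)
  res <- moderate(co, "pse_alcohol", "ctx_society", "cbcl_total",
                  wave = "baseline", n_boot = 0, seed = 1)
  expect_lt(abs(res$theta), 2.5 * res$se_theta)
})
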