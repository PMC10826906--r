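# Oracle for the binary-exposure rule, enumerated over all 9 flag pairs:
# 1 iff either flag is yes; missing iff both flags missing; else 0.
binary_rule_oracle <- function(before, after) {
  if (identical(before, "yes") || identical(after, "yes")) return(1L)
  if (is.na(before) && is.na(after)) return(NA_integer_)
  0L
}

test_that("binary exposure matches the rule oracle on all 9 flag pairs", {
  lv <- c("yes", "no", NA)
  grid <- expand.grid(before = lv, after = lv, stringsAsFactors = FALSE)
  got <- derive_binary_exposure(grid$before, grid$after)
  want <- mapply(binary_rule_oracle, grid$before, grid$after)
  expect_identical(got, as.integer(want))
  expect_error(derive_binary_exposure("maybe", "no"),
               class = "psecontext_domain_error")
})

test_that("knowledge groups refine the binary exposure", {
  expect_identical(derive_knowledge_groups("yes", "yes"), "after")
  expect_identical(derive_knowledge_groups("yes", "no"), "before_only")
  expect_identical(derive_knowledge_groups("no", "no"), "no_exposure")
  expect_identical(derive_knowledge_groups(NA, "yes"), "after")
  lv <- c("yes", "no", NA)
  grid <- expand.grid(before = lv, after = lv, stringsAsFactors = FALSE)
  any_exp <- derive_binary_exposure(grid$before, grid$after)
  grp <- derive_knowledge_groups(grid$before, grid$after)
  both <- !is.na(any_exp) & !is.na(grp)
  expect_identical(any_exp[both] == 1L, grp[both] != "no_exposure")
})

test_that("total consumption follows the stated scaling arithmetic", {
  thr <- threshold_set()  # knowledge week 8, pregnancy 40 weeks
  expect_equal(total_consumption("caffeine", quantity = 1, freq = "daily"),
               280)
  expect_equal(total_consumption("caffeine", quantity = 2, freq = "weekly"),
               80)
  expect_equal(total_consumption("alcohol", rate_before = 2, rate_after = 0,
                                 thresholds = thr), 16)
  expect_equal(total_consumption("alcohol", rate_before = 0, rate_after = 0),
               0)
  expect_equal(total_consumption("tobacco", rate_before = 1, rate_after = 1),
               280)
  expect_error(total_consumption("alcohol", rate_before = -1, rate_after = 0),
               class = "psecontext_domain_error")
})

test_that("total consumption is monotone in every quantity field", {
  base <- total_consumption("alcohol", rate_before = 2, rate_after = 1)
  for (bump in list(c(1, 0), c(0, 1))) {
    expect_gte(total_consumption("alcohol", rate_before = 2 + bump[1],
                                 rate_after = 1 + bump[2]), base)
  }
  expect_gte(total_consumption("caffeine", quantity = 3, freq = "monthly"),
             total_consumption("caffeine", quantity = 2, freq = "monthly"))
})

test_that("use-pattern classification applies the five-level rule table", {
  thr <- threshold_set()  # alcohol heavier cutoff 36
  expect_identical(classify_use_pattern("alcohol", 16, 0, thresholds = thr),
                   "light_reducing")
  expect_identical(classify_use_pattern("alcohol", 10, 30, thresholds = thr),
                   "increasing")
  expect_identical(classify_use_pattern("tobacco", 150, 150,
                                        thresholds = threshold_set()),
                   "heavier_stable")
  expect_identical(classify_use_pattern("alcohol", 10, 10.5, thresholds = thr),
                   "light_stable")  # within the 10% stability band
  expect_identical(classify_use_pattern("alcohol", 100, 20, thresholds = thr),
                   "heavier_reducing")
  expect_identical(classify_use_pattern("marijuana", 5, 5), "any")
  expect_identical(classify_use_pattern("caffeine", freq = "weekly"), "weekly")
  expect_error(classify_use_pattern("caffeine", freq = "hourly"),
               class = "psecontext_domain_error")
})

test_that("pattern classification partitions the exposed children", {
  co <- small_cohort("null", n = 1500, seed = 5)
  for (s in c("alcohol", "tobacco", "caffeine", "marijuana")) {
    exposed <- !is.na(co[[paste0("pse_", s)]]) & co[[paste0("pse_", s)]] == 1L
    pat <- co[[paste0("pattern_", s)]]
    expect_true(all(!is.na(pat[exposed])), label = paste(s, "exposed labelled"))
    expect_true(all(is.na(pat[!exposed])), label = paste(s, "unexposed NA"))
  }
  pa <- co$pattern_alcohol[!is.na(co$pattern_alcohol)]
  expect_true(all(pa %in% c("light_reducing", "light_stable",
                            "heavier_reducing", "heavier_stable",
                            "increasing")))
})

test_that("prevalence arithmetic counts exposed children at baseline", {
  n <- 200
  df <- data.frame(child_id = sprintf("C%03d", 1:n), wave = "baseline",
                   pse_alcohol = c(rep(1L, 40), rep(0L, 150), rep(NA, 10)),
                   stringsAsFactors = FALSE)
  out <- exposure_prevalence(df, substances = "alcohol")
  expect_equal(out$n_exposed, 40)
  expect_equal(out$n_total, 190)
  expect_equal(out$percent, 21.1)

  df$pse_alcohol <- 0L
  expect_equal(exposure_prevalence(df, substances = "alcohol")$percent, 0.0)
})

test_that("demographics_table reproduces printed percent cells", {
  n_f <- 1244; n_m <- 1280
  df <- data.frame(
    child_id = sprintf("C%04d", seq_len(n_f + n_m)), wave = "baseline",
    sex = c(rep("female", n_f), rep("male", n_m)),
    pse_alcohol = 1L, stringsAsFactors = FALSE)
  tab <- demographics_table(df, by = "sex", exposures = "pse_alcohol")
  expect_equal(tab$percent[tab$level == "female"], 49)
  expect_equal(tab$percent[tab$level == "male"], 51)
})
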