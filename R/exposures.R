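#' Thresholds for use-pattern classification
#'
#' Heavier-use cutoffs on pregnancy-total consumption, the stability band for
#' reducing/stable/increasing classification, and the assumed gestational week
#' of pregnancy knowledge used to scale per-week/per-day rates to totals.
#' The heavier cutoffs follow commonly used literature values but are
#' deliberately configuration, not constants: they should be replaced when a
#' study's instruments imply different ones.
#'
#' @param alcohol_heavier total drinks separating light from heavier use
#'   (default 36).
#' @param tobacco_heavier total instances separating light from heavier use
#'   (default 200).
#' @param stable_tolerance relative band around the before-knowledge total
#'   within which use counts as stable (default 0.10).
#' @param knowledge_week gestational week at which pregnancy knowledge is
#'   assumed (default 8; used because retrospective instruments typically do
#'   not record timing).
#' @param pregnancy_weeks length of pregnancy used for scaling (default 40).
#' @return a `threshold_set` list.
#' @export
threshold_set <- function(alcohol_heavier = 36, tobacco_heavier = 200,
                          stable_tolerance = 0.10, knowledge_week = 8,
                          pregnancy_weeks = 40) {
  stopifnot(alcohol_heavier > 0, tobacco_heavier > 0, stable_tolerance >= 0,
            knowledge_week > 0, knowledge_week < pregnancy_weeks)
  structure(list(alcohol_heavier = alcohol_heavier,
                 tobacco_heavier = tobacco_heavier,
                 stable_tolerance = stable_tolerance,
                 knowledge_week = knowledge_week,
                 pregnancy_weeks = pregnancy_weeks),
            class = "threshold_set")
}

#' Binary prenatal exposure from before/after-knowledge report flags
#'
#' A child is coded as exposed if the mother reported use either before or
#' after knowledge of the pregnancy. If either flag is "yes" the result is 1
#' regardless of the other flag; if both flags are missing the result is
#' missing; otherwise 0.
#'
#' @param before,after character vectors in `{"yes","no",NA}`.
#' @return integer vector in `{0, 1, NA}`.
#' @export
derive_binary_exposure <- function(before, after) {
  stopifnot(length(before) == length(after))
  chk <- c(before, after)
  bad <- setdiff(unique(chk[!is.na(chk)]), c("yes", "no"))
  if (length(bad)) {
    pse_domain_error(sprintf("exposure flags must be yes/no/NA, got: %s",
                             paste(bad, collapse = ", ")))
  }
  out <- ifelse(!is.na(before) & before == "yes", 1L,
         ifelse(!is.na(after) & after == "yes", 1L,
         ifelse(is.na(before) & is.na(after), NA_integer_, 0L)))
  as.integer(out)
}

#' Three-level exposure-timing groups
#'
#' Classifies each child as `no_exposure`, `before_only` (use stopped at
#' pregnancy knowledge) or `after` (use after knowledge, with or without use
#' before knowledge).
#'
#' @inheritParams derive_binary_exposure
#' @return character vector in `{"no_exposure","before_only","after", NA}`.
#' @export
derive_knowledge_groups <- function(before, after) {
  any_exp <- derive_binary_exposure(before, after)
  out <- rep(NA_character_, length(before))
  yes_after <- !is.na(after) & after == "yes"
  out[yes_after] <- "after"
  out[!yes_after & !is.na(before) & before == "yes" &
        !is.na(after) & after == "no"] <- "before_only"
  out[!is.na(any_exp) & any_exp == 0L] <- "no_exposure"
  out
}

#' Total pregnancy consumption of a substance
#'
#' Scales reported rates to a whole-pregnancy total. Caffeine: the reported
#' quantity per frequency unit is scaled to the full pregnancy (daily =
#' quantity x 7 x pregnancy weeks; weekly = quantity x pregnancy weeks;
#' monthly = quantity x pregnancy weeks / 4.345). Alcohol: weekly drinks
#' before knowledge x weeks before + weekly drinks after x weeks after.
#' Tobacco/marijuana: daily instances before x days before + daily instances
#' after x days after. Units: cups (caffeine), drinks (alcohol), instances
#' (tobacco, marijuana).
#'
#' @param substance one of `"caffeine"`, `"alcohol"`, `"tobacco"`,
#'   `"marijuana"`.
#' @param quantity caffeine only: cups per frequency unit.
#' @param freq caffeine only: `"daily"`, `"weekly"` or `"monthly"`.
#' @param rate_before,rate_after alcohol: drinks/week; tobacco/marijuana:
#'   instances/day, before and after pregnancy knowledge.
#' @param thresholds a [threshold_set()] supplying the knowledge week and
#'   pregnancy length.
#' @return nonnegative numeric vector (NA where inputs are missing).
#' @export
total_consumption <- function(substance, quantity = NULL, freq = NULL,
                              rate_before = NULL, rate_after = NULL,
                              thresholds = threshold_set()) {
  substance <- match.arg(substance,
                         c("caffeine", "alcohol", "tobacco", "marijuana"))
  wk <- thresholds$pregnancy_weeks
  kw <- thresholds$knowledge_week
  neg <- function(x) any(!is.na(x) & x < 0)
  if (substance == "caffeine") {
    if (neg(quantity)) pse_domain_error("negative caffeine quantity")
    mult <- c(daily = 7 * wk, weekly = wk, monthly = wk / 4.345)
    m <- unname(mult[freq])
    return(quantity * m)
  }
  if (neg(rate_before) || neg(rate_after)) {
    pse_domain_error(sprintf("negative %s quantity", substance))
  }
  rb <- ifelse(is.na(rate_before), 0, rate_before)
  ra <- ifelse(is.na(rate_after), 0, rate_after)
  both_na <- is.na(rate_before) & is.na(rate_after)
  tot <- if (substance == "alcohol") {
    rb * kw + ra * (wk - kw)
  } else {
    rb * kw * 7 + ra * (wk - kw) * 7
  }
  tot[both_na] <- NA_real_
  tot
}

#' Use-pattern classification for exposed children
#'
#' Crosses light/heavier use (pregnancy-total consumption against the heavier
#' cutoff) with reducing/stable/increasing use (after-knowledge vs
#' before-knowledge totals, with a relative stability band), collapsed to five
#' patterns for alcohol and tobacco: `light_reducing`, `light_stable`,
#' `heavier_reducing`, `heavier_stable`, and a single `increasing` level.
#' Caffeine is classified by reported frequency (`daily`/`weekly`/`monthly`);
#' marijuana carries the single level `any`.
#'
#' @param total_before,total_after pregnancy-phase totals (alcohol/tobacco).
#' @param substance substance name.
#' @param thresholds a [threshold_set()].
#' @param freq caffeine reported frequency.
#' @return character vector of pattern labels.
#' @export
classify_use_pattern <- function(substance, total_before = NULL,
                                 total_after = NULL, freq = NULL,
                                 thresholds = threshold_set()) {
  substance <- match.arg(substance,
                         c("caffeine", "alcohol", "tobacco", "marijuana"))
  if (substance == "caffeine") {
    bad <- setdiff(unique(freq[!is.na(freq)]), c("daily", "weekly", "monthly"))
    if (length(bad)) {
      pse_domain_error(sprintf("unknown caffeine frequency: %s",
                               paste(bad, collapse = ", ")))
    }
    return(as.character(freq))
  }
  if (substance == "marijuana") {
    return(rep("any", max(length(total_before), length(total_after))))
  }
  if (is.null(total_before) || is.null(total_after)) {
    pse_contract_error("total_before and total_after required for alcohol/tobacco")
  }
  cutoff <- if (substance == "alcohol") thresholds$alcohol_heavier
            else thresholds$tobacco_heavier
  tol <- thresholds$stable_tolerance
  total <- total_before + total_after
  heavier <- total > cutoff
  stable <- abs(total_after - total_before) <= tol * total_before
  increasing <- !stable & total_after > total_before
  trend <- ifelse(stable, "stable", ifelse(increasing, "increasing", "reducing"))
  out <- ifelse(trend == "increasing", "increasing",
                paste(ifelse(heavier, "heavier", "light"), trend, sep = "_"))
  out[is.na(total_before) | is.na(total_after)] <- NA_character_
  out
}

#' Derive all exposure variables on a cohort table
#'
#' Adds, per substance: the binary exposure (`pse_*`), the three-level
#' knowledge-timing group (`kg_*`, not defined for caffeine, whose
#' before/after split is not collected), the pregnancy-total consumption
#' (`total_*`), and the use pattern (`pattern_*`, defined only for exposed
#' children). Also adds `pse_polysubstance` (exposure to two or more
#' substances).
#'
#' @param cohort a `cohort_table`.
#' @param thresholds a [threshold_set()].
#' @return the cohort with derived columns added.
#' @export
derive_exposures <- function(cohort, thresholds = threshold_set()) {
  d <- cohort
  d$pse_caffeine <- ifelse(is.na(d$caffeine_use), NA_integer_,
                           as.integer(d$caffeine_use == "yes"))
  for (s in c("alcohol", "tobacco", "marijuana")) {
    b <- d[[paste0(s, "_before")]]
    a <- d[[paste0(s, "_after")]]
    d[[paste0("pse_", s)]] <- derive_binary_exposure(b, a)
    d[[paste0("kg_", s)]]  <- derive_knowledge_groups(b, a)
  }
  d$total_caffeine <- total_consumption("caffeine",
                                        quantity = d$caffeine_quantity,
                                        freq = d$caffeine_freq,
                                        thresholds = thresholds)
  d$total_caffeine[!is.na(d$pse_caffeine) & d$pse_caffeine == 0L] <- 0
  d$total_alcohol <- total_consumption("alcohol",
                                       rate_before = d$alcohol_drinks_week_before,
                                       rate_after  = d$alcohol_drinks_week_after,
                                       thresholds = thresholds)
  for (s in c("tobacco", "marijuana")) {
    d[[paste0("total_", s)]] <- total_consumption(
      s, rate_before = d[[paste0(s, "_per_day_before")]],
      rate_after = d[[paste0(s, "_per_day_after")]], thresholds = thresholds)
  }
  for (s in c("alcohol", "tobacco", "marijuana")) {
    d[[paste0("total_", s)]][!is.na(d[[paste0("pse_", s)]]) &
                               d[[paste0("pse_", s)]] == 0L] <- 0
  }
  ## patterns: only defined for exposed children
  kw <- thresholds$knowledge_week
  wk <- thresholds$pregnancy_weeks
  d$pattern_caffeine <- ifelse(!is.na(d$pse_caffeine) & d$pse_caffeine == 1L,
                               classify_use_pattern("caffeine",
                                                    freq = d$caffeine_freq,
                                                    thresholds = thresholds),
                               NA_character_)
  for (s in c("alcohol", "tobacco")) {
    if (s == "alcohol") {
      tb <- ifelse(is.na(d$alcohol_drinks_week_before), 0,
                   d$alcohol_drinks_week_before) * kw
      ta <- ifelse(is.na(d$alcohol_drinks_week_after), 0,
                   d$alcohol_drinks_week_after) * (wk - kw)
    } else {
      tb <- ifelse(is.na(d[[paste0(s, "_per_day_before")]]), 0,
                   d[[paste0(s, "_per_day_before")]]) * kw * 7
      ta <- ifelse(is.na(d[[paste0(s, "_per_day_after")]]), 0,
                   d[[paste0(s, "_per_day_after")]]) * (wk - kw) * 7
    }
    pat <- classify_use_pattern(s, total_before = tb, total_after = ta,
                                thresholds = thresholds)
    exposed <- !is.na(d[[paste0("pse_", s)]]) & d[[paste0("pse_", s)]] == 1L
    d[[paste0("pattern_", s)]] <- ifelse(exposed, pat, NA_character_)
  }
  exposed_mj <- !is.na(d$pse_marijuana) & d$pse_marijuana == 1L
  d$pattern_marijuana <- ifelse(exposed_mj, "any", NA_character_)
  ## polysubstance: two or more substances with any exposure
  flags <- cbind(d$pse_caffeine, d$pse_alcohol, d$pse_tobacco, d$pse_marijuana)
  n_yes <- rowSums(flags == 1L, na.rm = TRUE)
  n_na  <- rowSums(is.na(flags))
  d$pse_polysubstance <- ifelse(n_yes >= 2L, 1L,
                                ifelse(n_na > 0L, NA_integer_, 0L))
  d
}

#' Exposure prevalence table
#'
#' Counts exposed children at baseline (one record per child) and the percent
#' of children with non-missing exposure status, rounded to one decimal.
#'
#' @param cohort a `cohort_table` with derived `pse_*` columns.
#' @param substances character vector of substance names.
#' @return data.frame with columns `substance`, `n_exposed`, `n_total`,
#'   `percent`.
#' @export
exposure_prevalence <- function(cohort,
                                substances = c("caffeine", "alcohol",
                                               "tobacco", "marijuana",
                                               "polysubstance")) {
  base <- cohort[cohort$wave == "baseline", , drop = FALSE]
  base <- base[!duplicated(base$child_id), , drop = FALSE]
  rows <- lapply(substances, function(s) {
    col <- paste0("pse_", s)
    if (!col %in% names(base)) {
      pse_schema_error(sprintf("derived exposure column missing: %s", col))
    }
    x <- base[[col]]
    n_total <- sum(!is.na(x))
    n_exposed <- sum(x == 1L, na.rm = TRUE)
    pct <- if (n_total > 0) round(100 * n_exposed / n_total, 1) else NA_real_
    data.frame(substance = s, n_exposed = n_exposed, n_total = n_total,
               percent = pct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Demographic composition within exposure groups
#'
#' Table-1-style counts and percentages of a demographic variable within each
#' exposure column (baseline wave, one record per child), percentages rounded
#' to whole numbers as conventionally printed.
#'
#' @param cohort a `cohort_table` with derived `pse_*` columns (plain
#'   data.frames with the needed columns are accepted).
#' @param by demographic column name (default `"sex"`).
#' @param exposures exposure columns to tabulate within.
#' @return data.frame with columns `exposure`, `level`, `n`, `percent`.
#' @export
demographics_table <- function(cohort, by = "sex",
                               exposures = c("pse_caffeine", "pse_alcohol",
                                             "pse_tobacco", "pse_marijuana")) {
  base <- cohort[cohort$wave == "baseline", , drop = FALSE]
  base <- base[!duplicated(base$child_id), , drop = FALSE]
  rows <- lapply(exposures, function(e) {
    g <- base[!is.na(base[[e]]) & base[[e]] == 1L, , drop = FALSE]
    counts <- table(g[[by]])
    data.frame(exposure = e, level = names(counts), n = as.integer(counts),
               percent = round(100 * as.integer(counts) / nrow(g)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
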