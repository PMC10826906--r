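# Shared fixtures built in code. Small cohorts are cached per session so the
# cost of simulating and deriving is paid once across test files.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(scenario = "persistent", n = 2000, seed = 101,
                         derived = TRUE) {
  key <- paste(scenario, n, seed, derived, sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  spec <- scenario_library(n_children = n)[[scenario]]
  co <- simulate_cohort(spec, seed = seed)$cohort
  if (derived) {
    co <- derive_exposures(co)
    co <- derive_context_scores(co)
  }
  .fixture_env[[key]] <- co
  co
}

# Minimal two-child cohort table for IO tests.
tiny_cohort_df <- function() {
  data.frame(
    child_id = c("C1", "C1", "C2", "C2"),
    family_id = c("F1", "F1", "F2", "F2"),
    site_id = c("S1", "S1", "S2", "S2"),
    wave = c("baseline", "year2", "baseline", "year2"),
    sex = c("female", "female", "male", "male"),
    race_ethnicity = c("White", "White", "Black", "Black"),
    age_months = c(110L, 134L, 120L, 144L),
    stringsAsFactors = FALSE)
}

write_tiny_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
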