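## FNV-1a string hash; used to fingerprint configurations in the manifest.
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full health-in-context pipeline
#'
#' Executes the four analyses in order on a cohort table (supplied or
#' simulated from a generator spec): (1) exposure derivation, context scores
#' and exposure-context associations; (2) baseline association screening in
#' unadjusted and context-adjusted modes with the robustness filter; (3)
#' developmental-pattern classification of the robust set via the cluster
#' bootstrap; (4) mediation and moderation pathway analyses on the
#' persistent/late-onset set. All intermediate tables are written as TSV to
#' the configured output directory, so any stage can be re-examined in
#' isolation; a JSON run manifest and a plain-text log with per-stage timing
#' are written alongside.
#'
#' @param config an [analysis_config()].
#' @param cohort optional `cohort_table`; if `NULL`, a cohort is simulated
#'   from `generator`.
#' @param generator optional [generator_spec()] used when `cohort` is `NULL`
#'   (default: the `"persistent"` scenario).
#' @param mediators character vector of candidate mediator columns for the
#'   pathway stage.
#' @param moderators character vector of candidate moderator columns.
#' @return a `run_manifest` list (invisibly written as JSON too).
#' @export
run_pipeline <- function(config, cohort = NULL, generator = NULL,
                         mediators = "brain_sa_global",
                         moderators = c("ctx_birth", "ctx_family",
                                        "ctx_society", "ctx_genetic")) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$output_dir, "run.log")
  cat("", file = log_file)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      cat(pse_log(sprintf("stage %s FAILED: %s", name, conditionMessage(e))),
          "\n", file = log_file, append = TRUE)
      pse_error("psecontext_stage_error",
                sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    cat(pse_log(sprintf("stage %-12s done in %.1fs", name,
                        as.numeric(difftime(Sys.time(), t0, units = "secs")))),
        "\n", file = log_file, append = TRUE)
    out
  }
  seed <- config$rng_seed
  counts <- list()

  if (is.null(cohort)) {
    generator <- generator %||% scenario_library()[["persistent"]]
    sim <- stage("simulate",
                 simulate_cohort(generator, seed = child_seed(seed, "simulate")))
    cohort <- sim$cohort
  }
  dict <- attr(cohort, "dictionary")
  findings <- validate_config(config, dict)
  if (nrow(findings) > 0) {
    pse_error("psecontext_stage_error",
              paste("configuration not runnable:",
                    paste(findings$problem, collapse = "; ")))
  }

  cohort <- stage("exposures", derive_exposures(cohort, config$thresholds))
  cohort <- stage("scores", derive_context_scores(cohort, dict))
  write_results(as.data.frame(cohort), file.path(config$output_dir, "cohort.tsv"))
  prev <- exposure_prevalence(cohort)
  write_results(prev, file.path(config$output_dir, "prevalence.tsv"))
  counts$n_children <- length(unique(cohort$child_id))
  counts$n_records <- nrow(cohort)

  outcomes <- config$outcomes %||%
    dict$variable_name[dict$role %in% c("outcome", "brain_structure",
                                        "brain_function")]
  alpha <- config$fdr_alpha
  screens <- list()
  for (w in c("baseline", "year2")) {
    for (md in c("unadjusted_context", "context_adjusted")) {
      nm <- paste(w, md, sep = "_")
      screens[[nm]] <- stage(paste0("screen:", substr(nm, 1, 10)),
        screen_battery(cohort, config$exposures, outcomes, wave = w,
                       mode = md, alpha = alpha))
      write_results(screens[[nm]],
                    file.path(config$output_dir, paste0("assoc_", nm, ".tsv")))
    }
  }
  verdicts <- stage("robustness",
    robustness_filter(screens$baseline_unadjusted_context,
                      screens$baseline_context_adjusted, alpha))
  write_results(as.data.frame(verdicts),
                file.path(config$output_dir, "robustness.tsv"))
  red <- reduction_summary(verdicts)
  write_results(red, file.path(config$output_dir, "reduction.tsv"))
  counts$significant_unadjusted <- sum(verdicts$significant_unadjusted)
  counts$significant_adjusted <- sum(verdicts$significant_adjusted)

  patt <- stage("patterns",
    pattern_analysis(cohort, screens$baseline_context_adjusted,
                     screens$year2_context_adjusted, alpha = alpha,
                     n_boot = config$n_bootstrap,
                     seed = child_seed(seed, "patterns")))
  write_results(as.data.frame(patt), file.path(config$output_dir, "patterns.tsv"))
  counts$patterns <- as.list(table(patt$label))

  ## pathway stage on the persistent/late-onset set
  focal <- patt[patt$label %in% c("persistent", "late_onset"), , drop = FALSE]
  focal <- focal[!focal$outcome %in% c(mediators), , drop = FALSE]
  med_rows <- list()
  mod_rows <- list()
  if (nrow(focal) > 0) {
    single <- one_per_family(cohort, seed = child_seed(seed, "one_per_family"))
    for (i in seq_len(nrow(focal))) {
      for (m in mediators) {
        med_rows[[length(med_rows) + 1L]] <- tryCatch(
          mediate(single, focal$exposure[i], m, focal$outcome[i],
                  n_boot = config$n_bootstrap,
                  seed = child_seed(seed, paste0("mediate", i, m))),
          error = function(e) NULL)
      }
      for (m in moderators) {
        mod_rows[[length(mod_rows) + 1L]] <- tryCatch(
          moderate(cohort, focal$exposure[i], m, focal$outcome[i],
                   n_boot = min(config$n_bootstrap, 1000),
                   seed = child_seed(seed, paste0("moderate", i, m))),
          error = function(e) NULL)
      }
    }
  }
  med <- if (length(med_rows)) do.call(rbind, med_rows) else NULL
  mod <- if (length(mod_rows)) do.call(rbind, mod_rows) else NULL
  if (!is.null(med)) {
    write_results(as.data.frame(med), file.path(config$output_dir, "mediation.tsv"))
  }
  if (!is.null(mod)) {
    mod2 <- as.data.frame(mod)
    adj <- fdr_adjust(mod2$p, alpha)
    mod2$p_fdr <- adj$p_fdr
    write_results(mod2, file.path(config$output_dir, "moderation.tsv"))
  }
  counts$n_mediation <- length(med_rows)
  counts$n_moderation <- length(mod_rows)

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("psecontext")),
    config_hash = config_hash(unclass(config)),
    seed = seed, alpha = alpha, counts = counts,
    reduction = red), class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

#' Render a markdown run report
#'
#' Summarizes a completed pipeline run from its written artifacts: exposure
#' prevalences, robust associations and per-exposure reduction percentages,
#' developmental-pattern labels, mediation ratios and moderation attenuation
#' indices. Missing stage tables are noted rather than failing. Effect sizes
#' are displayed to 3 decimals and percentages to 1 decimal.
#'
#' @param output_dir the pipeline's output directory.
#' @param path output markdown path (default `report.md` in `output_dir`).
#' @return the report path, invisibly.
#' @export
render_report <- function(output_dir, path = file.path(output_dir, "report.md")) {
  lines <- c("# Health-in-context run report", "")
  tbl <- function(file) {
    f <- file.path(output_dir, file)
    if (file.exists(f)) read_results(f) else NULL
  }
  md_table <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("(empty)")
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) {
      df[[j]] <- ifelse(grepl("percent", names(df)[j]),
                        sprintf("%.1f", df[[j]]), sprintf("%.3f", df[[j]]))
    }
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    paste(c(header, sep, body), collapse = "\n")
  }
  prev <- tbl("prevalence.tsv")
  lines <- c(lines, "## Exposure prevalence", "",
             if (is.null(prev)) "Stage output missing." else md_table(prev), "")
  red <- tbl("reduction.tsv")
  rob <- tbl("robustness.tsv")
  lines <- c(lines, "## Robust associations", "")
  if (is.null(rob)) {
    lines <- c(lines, "Stage output missing.", "")
  } else {
    robust <- rob[rob$verdict == "robust", , drop = FALSE]
    lines <- c(lines,
               sprintf("%d robust association(s) of %d screened cells.",
                       nrow(robust), nrow(rob)), "",
               "Per-exposure reduction after context adjustment:", "",
               md_table(red), "")
  }
  patt <- tbl("patterns.tsv")
  lines <- c(lines, "## Developmental patterns", "")
  if (is.null(patt)) {
    lines <- c(lines, "Stage output missing.", "")
  } else if (nrow(patt) == 0) {
    lines <- c(lines, "No robust associations to classify.", "")
  } else {
    lines <- c(lines, md_table(patt[, c("exposure", "outcome", "beta_baseline",
                                        "beta_year2", "delta", "ci_low",
                                        "ci_high", "label")]), "")
  }
  med <- tbl("mediation.tsv")
  lines <- c(lines, "## Mediation pathways", "",
             if (is.null(med)) "Stage output missing or not run." else
               md_table(med[, c("exposure", "mediator", "outcome", "indirect",
                                "ratio_percent", "ci_low", "ci_high",
                                "p_boot")]), "")
  mod <- tbl("moderation.tsv")
  lines <- c(lines, "## Moderation pathways", "",
             if (is.null(mod)) "Stage output missing or not run." else
               md_table(mod[, c("exposure", "moderator", "outcome", "theta",
                                "vr2", "p", "p_boot")]), "")
  writeLines(lines, path)
  invisible(path)
}

#' @exportS3Method base::print
print.robustness_verdict <- function(x, ...) {
  cat("Robustness verdicts:", nrow(x), "cells\n")
  print(table(x$verdict))
  red <- attr(x, "reduction")
  if (!is.null(red)) {
    cat("\nReduction in significant associations after context adjustment:\n")
    print(red, row.names = FALSE)
  }
  invisible(x)
}

#' @exportS3Method base::print
print.generator_spec <- function(x, ...) {
  cat("Synthetic cohort generator spec\n")
  cat(sprintf("  children: %d in %d sites (sibling fraction %.2f)\n",
              x$n_children, x$n_sites, x$sibling_fraction))
  cat("  prevalences:",
      paste(sprintf("%s %.1f%%", names(x$exposure_prevalence),
                    100 * x$exposure_prevalence), collapse = ", "), "\n")
  cat(sprintf("  variance components: site %.2f, family %.2f, residual %.2f\n",
              x$sigma2_site, x$sigma2_family, x$sigma2_resid))
  cat(sprintf("  true effects: %d; confounded contexts: %s\n",
              nrow(x$true_beta),
              if (length(x$confounding)) paste(names(x$confounding),
                                               collapse = ", ") else "none"))
  invisible(x)
}
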