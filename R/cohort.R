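#' Validate a data frame as a cohort table
#'
#' Checks the structural invariants of a long-format child-by-wave cohort:
#' every column declared in the dictionary, at most one record per
#' (child, wave), stable family and site membership per child, known wave
#' levels, and increasing age across waves within child.
#'
#' @param df data.frame in long child-by-wave format.
#' @param dictionary a [data_dictionary()].
#' @return the validated data.frame with class `cohort_table` and the
#'   dictionary attached as an attribute.
#' @export
as_cohort_table <- function(df, dictionary) {
  stopifnot(inherits(dictionary, "pse_dictionary"))
  undeclared <- setdiff(names(df), dictionary$variable_name)
  if (length(undeclared)) {
    pse_schema_error(sprintf("undeclared column(s): %s",
                             paste(undeclared, collapse = ", ")),
                     columns = undeclared)
  }
  for (col in c("child_id", "family_id", "site_id", "wave")) {
    if (!col %in% names(df)) pse_schema_error(sprintf("missing id column: %s", col))
  }
  bad_wave <- setdiff(unique(df$wave), c("baseline", "year2"))
  if (length(bad_wave)) {
    pse_integrity_error(sprintf("unknown wave level(s): %s",
                                paste(bad_wave, collapse = ", ")))
  }
  key <- paste(df$child_id, df$wave, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), c("child_id", "wave"), drop = FALSE][1, ]
    pse_integrity_error(sprintf("duplicate record for child %s at wave %s",
                                d$child_id, d$wave))
  }
  fam_per_child <- tapply(df$family_id, df$child_id,
                          function(x) length(unique(x)))
  if (any(fam_per_child > 1)) {
    pse_integrity_error(sprintf(
      "child %s mapped to more than one family",
      names(fam_per_child)[fam_per_child > 1][1]))
  }
  site_per_child <- tapply(df$site_id, df$child_id,
                           function(x) length(unique(x)))
  if (any(site_per_child > 1)) {
    pse_integrity_error(sprintf(
      "child %s mapped to more than one site",
      names(site_per_child)[site_per_child > 1][1]))
  }
  if ("age_months" %in% names(df)) {
    both <- intersect(df$child_id[df$wave == "baseline"],
                      df$child_id[df$wave == "year2"])
    if (length(both)) {
      a0 <- df$age_months[match(paste(both, "baseline", sep = "\r"), key)]
      a2 <- df$age_months[match(paste(both, "year2", sep = "\r"), key)]
      bad <- which(!is.na(a0) & !is.na(a2) & a2 <= a0)
      if (length(bad)) {
        pse_integrity_error(sprintf(
          "age_months at year2 not greater than at baseline for child %s",
          both[bad[1]]))
      }
    }
  }
  structure(df, dictionary = dictionary,
            class = c("cohort_table", "data.frame"))
}

#' Read a cohort table from delimited text
#'
#' Reads a TSV (canonical) or CSV (detected by sniffing the header line)
#' cohort file, validates it against the data dictionary, and coerces columns
#' to their declared types. Empty strings and `NA` are treated as explicit
#' missing values.
#'
#' @param path path to a UTF-8 delimited text file with a header row.
#' @param dictionary a [data_dictionary()].
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, dictionary) {
  if (!file.exists(path)) pse_io_error(sprintf("no such file: %s", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", na.strings = c("", "NA"),
                           check.names = FALSE, quote = "\"",
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  undeclared <- setdiff(names(raw), dictionary$variable_name)
  if (length(undeclared)) {
    pse_schema_error(sprintf("undeclared column(s): %s",
                             paste(undeclared, collapse = ", ")),
                     columns = undeclared)
  }
  types <- stats::setNames(dict_type(dictionary$value_domain),
                           dictionary$variable_name)
  for (col in names(raw)) {
    if (types[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(v) & !is.na(raw[[col]]))
      if (length(bad)) {
        pse_parse_error(sprintf(
          "non-numeric value '%s' in numeric column '%s' at data row %d",
          raw[[col]][bad[1]], col, bad[1]),
          row = bad[1], column = col)
      }
      raw[[col]] <- v
    }
  }
  as_cohort_table(raw, dictionary)
}

#' Write a cohort table or result table to TSV
#'
#' Numeric columns are written with 12 significant digits so that tables
#' round-trip losslessly through [read_results()] at that precision.
#'
#' @param x data.frame (a cohort table or any stage's result records). A list
#'   of homogeneous single-row records is also accepted; an empty list or
#'   zero-row data.frame yields a header-only file (pass `columns` to name the
#'   header for an empty list).
#' @param path output path.
#' @param columns optional character vector of column names used when `x` is
#'   an empty list.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path, columns = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0L) {
      x <- stats::setNames(
        as.data.frame(matrix(nrow = 0, ncol = length(columns %||% character()))),
        columns %||% character())
    } else {
      if (!all(vapply(x, is.data.frame, logical(1)))) {
        pse_contract_error("records must all be data.frames")
      }
      nm <- lapply(x, names)
      if (!all(vapply(nm, identical, logical(1), nm[[1]]))) {
        pse_contract_error("records are not homogeneous: column sets differ")
      }
      x <- do.call(rbind, x)
    }
  }
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           formatC(out[[col]], digits = 12, format = "g"))
    }
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) pse_io_error(sprintf("no such directory: %s", dir))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pse_io_error(sprintf("cannot write: %s", path))
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path path to the TSV file.
#' @return data.frame with numeric columns restored.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) pse_io_error(sprintf("no such file: %s", path))
  utils::read.delim(path, na.strings = c("", "NA"), check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: the FDR level, the number
#' of bootstrap replicates, the master seed (all random stages derive child
#' seeds from it via [child_seed()]), the exposure and outcome sets, pattern
#' thresholds, and the output directory.
#'
#' @param fdr_alpha FDR level in (0,1); default 0.05.
#' @param n_bootstrap bootstrap replicates; default 10000.
#' @param rng_seed integer master seed.
#' @param exposures character vector of binary exposure column names.
#' @param outcomes character vector of outcome column names (default: all
#'   variables with role `outcome`, `brain_structure` or `brain_function` in
#'   the dictionary at run time).
#' @param thresholds a [threshold_set()].
#' @param output_dir directory for stage artifacts.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(fdr_alpha = 0.05, n_bootstrap = 10000,
                            rng_seed = 20260101,
                            exposures = c("pse_caffeine", "pse_alcohol",
                                          "pse_tobacco", "pse_marijuana"),
                            outcomes = NULL,
                            thresholds = threshold_set(),
                            output_dir = tempdir()) {
  structure(list(fdr_alpha = fdr_alpha, n_bootstrap = n_bootstrap,
                 rng_seed = rng_seed, exposures = exposures,
                 outcomes = outcomes, thresholds = thresholds,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#' @param path path to a YAML file whose keys match [analysis_config()]
#'   arguments.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  if ("thresholds" %in% names(vals)) {
    vals$thresholds <- do.call(threshold_set, vals$thresholds)
  }
  do.call(analysis_config, vals[intersect(names(vals), known)])
}

#' Validate an analysis configuration against a data dictionary
#'
#' A reporting operation: never throws. Returns one finding per problem
#' (out-of-bounds parameter, referenced-but-undeclared variable); an empty
#' report means the configuration is runnable against the dictionary.
#'
#' @param config an [analysis_config()].
#' @param dictionary a [data_dictionary()].
#' @return data.frame with columns `field`, `problem`.
#' @export
validate_config <- function(config, dictionary) {
  findings <- list()
  note <- function(field, problem) {
    findings[[length(findings) + 1L]] <<-
      data.frame(field = field, problem = problem, stringsAsFactors = FALSE)
  }
  if (!is.numeric(config$fdr_alpha) || config$fdr_alpha <= 0 ||
      config$fdr_alpha >= 1) {
    note("fdr_alpha", sprintf("must lie in (0,1), got %s",
                              format(config$fdr_alpha)))
  }
  if (!is.numeric(config$n_bootstrap) || config$n_bootstrap < 1 ||
      config$n_bootstrap != round(config$n_bootstrap)) {
    note("n_bootstrap", "must be a positive integer")
  }
  declared <- dictionary$variable_name
  for (v in setdiff(config$exposures, declared)) {
    note("exposures", sprintf("variable '%s' not declared in dictionary", v))
  }
  for (v in setdiff(config$outcomes %||% character(), declared)) {
    note("outcomes", sprintf("variable '%s' not declared in dictionary", v))
  }
  if (length(findings) == 0L) {
    return(data.frame(field = character(), problem = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
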