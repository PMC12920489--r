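# Cohort schema, CSV/TSV readers and writers, YAML configuration files and
# the report writer.

#' Cohort column registry
#'
#' @return List with `columns` (canonical column order), `mandatory`
#'   (columns required by [read_cohort()]), `biomarkers`, `clinical_vocab`
#'   (named list of controlled vocabularies), `outcomes` and
#'   `schema_version`.
#' @export
cohort_schema <- function() {
  clinical_vocab <- list(
    age_group = c("<=55", ">55"),
    sex = c("male", "female"),
    primary_site = c("oral_oropharynx", "larynx_hypopharynx"),
    cps = c("<1", ">=1"),
    differentiation = c("well", "moderate", "poor"),
    stage = c("III", "IV"),
    radiologic_response = c("CR", "PR", "SD"),
    pathologic_response = c("pCR", "mPR_not_pCR", "no_mPR"),
    pni = c("no", "yes"),
    lvi = c("no", "yes"),
    ene = c("no", "yes"),
    margin_class = c("close", "clear")
  )
  biomarkers <- c("tls_density", "panck_foci", "ki67_pct",
                  "n_driver_mutations", "pdl1_fold", "cd8_foxp3_ratio",
                  "gzmb_density", "margin_mm")
  outcomes <- c("lrc_time_months", "lrc_event",
                "dmfs_time_months", "dmfs_event")
  derived <- c("histopathology_score", "tumor_burden_score",
               "molecular_score", "immune_score", "mrix_score",
               "mrix_category", "override_applied")
  list(columns = c("patient_id", biomarkers, names(clinical_vocab),
                   outcomes, derived),
       mandatory = c("patient_id", biomarkers, names(clinical_vocab),
                     outcomes),
       biomarkers = biomarkers,
       clinical_vocab = clinical_vocab,
       outcomes = outcomes,
       derived = derived,
       schema_version = "1.0")
}

.sep_for <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read and validate a cohort table
#'
#' Reads a CSV (or, by extension, TSV) cohort file and validates it against
#' [cohort_schema()]: mandatory columns present, clinical categories within
#' their controlled vocabularies, positive times and 0/1 event flags.
#' Unknown columns are preserved but flagged with a message.
#'
#' @param path Path to a `.csv` or `.tsv` file with a header row.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  sc <- cohort_schema()
  df <- read.csv(path, sep = .sep_for(path), stringsAsFactors = FALSE,
                 check.names = FALSE)
  missing_cols <- setdiff(sc$mandatory, names(df))
  if (length(missing_cols)) {
    stop("cohort file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(df), c(sc$columns))
  if (length(unknown)) {
    message("unknown column(s) preserved: ", paste(unknown, collapse = ", "))
  }
  for (v in names(sc$clinical_vocab)) {
    bad <- which(!df[[v]] %in% sc$clinical_vocab[[v]])
    if (length(bad)) {
      stop("column ", v, " has value(s) outside its vocabulary at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  for (tc in c("lrc_time_months", "dmfs_time_months")) {
    bad <- which(!is.finite(df[[tc]]) | df[[tc]] <= 0)
    if (length(bad)) {
      stop("column ", tc, " must be positive; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  for (ec in c("lrc_event", "dmfs_event")) {
    bad <- which(!df[[ec]] %in% c(0, 1))
    if (length(bad)) {
      stop("column ", ec, " must be 0/1; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  # stabilize storage modes so write -> read round-trips exactly
  for (v in intersect(c(sc$biomarkers, "lrc_time_months", "dmfs_time_months",
                        "mrix_score"), names(df))) {
    df[[v]] <- as.double(df[[v]])
  }
  for (v in intersect(c("lrc_event", "dmfs_event", "histopathology_score",
                        "tumor_burden_score", "molecular_score",
                        "immune_score"), names(df))) {
    df[[v]] <- as.integer(df[[v]])
  }
  message("read cohort: ", nrow(df), " rows, ", ncol(df),
          " columns (schema ", sc$schema_version, ")")
  df
}

#' Write a cohort table
#'
#' Deterministic column order (schema order, then extras) and full-precision
#' numeric formatting (`%.17g`), so write-then-read round-trips exactly and
#' re-runs are byte-identical.
#'
#' @param cohort Cohort data frame.
#' @param path Output `.csv` or `.tsv` path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sc <- cohort_schema()
  ord <- c(intersect(sc$columns, names(cohort)),
           setdiff(names(cohort), sc$columns))
  out <- cohort[, ord, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.table(out, path, sep = .sep_for(path), row.names = FALSE,
              quote = TRUE, qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a simulation configuration to YAML
#'
#' @param config A [sim_config()].
#' @param path Output `.yaml` path.
#' @return The path, invisibly.
#' @export
write_sim_config <- function(config, path) {
  ser <- unclass(config)
  ser$true_log_hr <- lapply(ser$true_log_hr, function(ep) {
    lapply(ep, as.list)
  })
  ser$clinical_marginals <- lapply(ser$clinical_marginals, as.list)
  ser$references <- as.list(ser$references)
  ser$baseline$target_event_rate <- as.list(ser$baseline$target_event_rate)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path A YAML file written by [write_sim_config()] (or hand-edited
#'   in the same key tree).
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_config(
    n_patients = raw$n_patients,
    biomarker_marginals = lapply(raw$biomarker_marginals, unlist),
    clinical_marginals = lapply(raw$clinical_marginals, unlist),
    true_log_hr = lapply(raw$true_log_hr, function(ep) lapply(ep, unlist)),
    baseline = within(raw$baseline, {
      target_event_rate <- unlist(target_event_rate)
    }),
    censoring = raw$censoring,
    band_intervals = if (is.null(raw$band_intervals)) {
      default_band_intervals()
    } else {
      lapply(raw$band_intervals, function(b) lapply(b, unlist))
    },
    references = unlist(raw$references),
    seed = raw$seed
  )
}

#' Write a scoring configuration to YAML
#' @param config A [mrix_scoring_config()].
#' @param path Output `.yaml` path.
#' @return The path, invisibly.
#' @export
write_scoring_config <- function(config, path) {
  yaml::write_yaml(list(weights = as.list(config$weights),
                        low_max = config$low_max,
                        intermediate_max = config$intermediate_max,
                        override_margin_mm = config$override_margin_mm),
                   path, precision = 15)
  invisible(path)
}

#' Read a scoring configuration from YAML
#' @param path A YAML file written by [write_scoring_config()].
#' @return A [mrix_scoring_config()].
#' @export
read_scoring_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mrix_scoring_config(weights = unlist(raw$weights),
                      low_max = raw$low_max,
                      intermediate_max = raw$intermediate_max,
                      override_margin_mm = raw$override_margin_mm)
}

.hr_table <- function(fit) {
  cbind(fit$hr, coef = unname(fit$coef), se = unname(fit$se))
}

#' Write a study report to files
#'
#' One CSV per table analog (baseline characteristics, domain tests,
#' adjusted-model hazard ratios, model comparison) plus a JSON summary and a
#' manifest listing the files written; empty or absent sections are omitted
#' and noted in the manifest.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  omitted <- character(0)
  emit_csv <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) {
      omitted <<- c(omitted, name)
      return(invisible(NULL))
    }
    path <- file.path(dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  emit_csv(report$baseline_table, "baseline_table.csv")
  emit_csv(report$domain_km$tests, "domain_tests.csv")
  for (ep in names(report$table3_analog)) {
    emit_csv(.hr_table(report$table3_analog[[ep]]),
             paste0("adjusted_model_", ep, ".csv"))
  }
  for (ep in names(report$table4_analog)) {
    cmp <- report$table4_analog[[ep]]
    emit_csv(cmp$models, paste0("model_comparison_", ep, ".csv"))
    emit_csv(cmp$lrt, paste0("model_lrt_", ep, ".csv"))
  }
  vb <- report$validation_block
  if (!is.null(vb)) {
    summ <- lapply(vb[intersect(c("lrc", "dmfs"), names(vb))], function(e) {
      list(logrank_p = e$logrank$p,
           c_index = e$c_index,
           hr = setNames(as.list(e$cox$hr$hr), e$cox$hr$term),
           hl_chi2 = e$calibration$hl_chi2,
           hl_p = e$calibration$hl_p)
    })
    jsonlite::write_json(summ, file.path(dir, "validation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "validation_summary.json")
  } else {
    omitted <- c(omitted, "validation_summary.json")
  }
  manifest <- list(files = files, omitted = omitted,
                   schema_version = cohort_schema()$schema_version,
                   created = "deterministic")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(c(files, "manifest.json"))
}
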