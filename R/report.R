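#' Write a fit report
#'
#' Writes the coefficient table as CSV (term, estimate, std_error, z, p)
#' plus a JSON sidecar with the log-likelihood, BIC, sample size,
#' parameter count, and convergence flag.
#'
#' @param fit an `extinction_fit`.
#' @param dir output directory (created if absent).
#' @param basename file stem for the two outputs.
#' @return paths of the written files, invisibly.
#' @export
write_fit_report <- function(fit, dir, basename = "fit") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(basename, "_coefficients.csv"))
  tab <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    std_error = unname(fit$std_errors),
                    z = unname(fit$z_scores),
                    p = unname(fit$p_values))
  utils::write.csv(tab, csv, row.names = FALSE)
  json <- file.path(dir, paste0(basename, "_summary.json"))
  jsonlite::write_json(list(log_likelihood = fit$log_likelihood,
                            bic = fit$bic, n = fit$n, k = fit$k,
                            converged = fit$converged,
                            terms = as.character(unclass(fit$terms))),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Write the model-selection ranking table
#'
#' @param selection a `model_selection` from [select_model()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_ranking <- function(selection, path) {
  utils::write.csv(selection$ranking[, c("terms", "k", "logLik", "BIC",
                                         "delta_BIC", "converged")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an extrapolation report
#'
#' Writes the per-record persistence CSV (record id, survival
#' probability, covariates), a summary JSON (point estimate, quantiles,
#' extinction rate, settings, seed), and optionally the full vector of
#' bootstrap iteration sums.
#'
#' @param result an `extrapolation` from [bootstrap_extrapolation()].
#' @param records the database records the extrapolation used.
#' @param dir output directory.
#' @param write_sums also write every bootstrap iteration sum as CSV.
#' @return paths of the written files, invisibly.
#' @export
write_extrapolation_report <- function(result, records, dir,
                                       write_sums = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- file.path(dir, "persistence.csv")
  utils::write.csv(
    data.frame(record_id = records$record_id,
               survival_probability = result$per_record_survival,
               size = records$size,
               years_since = records$years_since,
               elevation_m = records$elevation_m,
               group = if ("group" %in% names(records)) records$group
                       else NA_character_),
    per, row.names = FALSE)
  summary_path <- file.path(dir, "extrapolation_summary.json")
  jsonlite::write_json(list(
    point_extant = result$point_extant,
    lower_q = result$lower_q, upper_q = result$upper_q,
    extinction_rate = result$extinction_rate,
    rate_lower = result$rate_lower, rate_upper = result$rate_upper,
    n_database = result$n_database,
    n_effective_reps = result$n_effective_reps,
    settings = list(n_reps = result$settings$n_reps,
                    confidence_level = result$settings$confidence_level,
                    seed = result$settings$seed,
                    nonconvergence_policy =
                      result$settings$nonconvergence_policy)),
    summary_path, auto_unbox = TRUE, digits = NA)
  out <- c(per, summary_path)
  if (write_sums) {
    sums_path <- file.path(dir, "bootstrap_sums.csv")
    utils::write.csv(data.frame(iteration = seq_along(result$sums),
                                extant_sum = result$sums),
                     sums_path, row.names = FALSE)
    out <- c(out, sums_path)
  }
  invisible(out)
}

#' Run the model-fitting pipeline over a resurvey CSV
#'
#' Reads and validates the resurvey table, selects the extinction model
#' by BIC over all candidates (or fits a fixed term set), and writes the
#' coefficient table, the selection ranking, and the JSON sidecar to
#' `out_dir`.
#'
#' @param resurvey_path resurvey CSV.
#' @param out_dir output directory.
#' @param terms `"auto"` for BIC selection, or a [model_terms()] set.
#' @param col_map,permissive passed to [read_resurvey_table()].
#' @return the `model_selection` (or single-fit equivalent), invisibly.
#' @export
run_fit_pipeline <- function(resurvey_path, out_dir, terms = "auto",
                             col_map = resurvey_columns(),
                             permissive = FALSE) {
  records <- read_resurvey_table(resurvey_path, col_map = col_map,
                                 permissive = permissive)
  if (identical(terms, "auto")) {
    sel <- select_model(records)
  } else {
    tm <- as_model_terms(terms)
    fit <- fit_logistic(records, tm)
    ranking <- data.frame(
      terms = if (length(tm)) paste(unclass(tm), collapse = "+")
              else "(intercept)",
      k = fit$k, logLik = fit$log_likelihood, BIC = fit$bic,
      converged = fit$converged, delta_BIC = 0,
      stringsAsFactors = FALSE)
    sel <- structure(list(terms = tm, fit = fit, ranking = ranking),
                     class = "model_selection")
  }
  write_fit_report(sel$fit, out_dir)
  write_selection_ranking(sel, file.path(out_dir, "model_ranking.csv"))
  invisible(sel)
}

#' Run the full extrapolation pipeline
#'
#' Ingests both tables, filters the database, selects (or fixes) the
#' model, runs the coefficient bootstrap, and writes the per-record
#' persistence CSV, summary JSON, group table, and a provenance record to
#' `out_dir`.
#'
#' @param resurvey_path,database_path input CSVs.
#' @param out_dir output directory.
#' @param terms `"auto"` or a [model_terms()] set.
#' @param settings a [bootstrap_settings()].
#' @param reference_year passed to [read_occurrence_table()].
#' @param permissive passed to both readers.
#' @return list with the selection, the extrapolation, and the group
#'   table, invisibly.
#' @export
run_extrapolation_pipeline <- function(resurvey_path, database_path, out_dir,
                                       terms = "auto",
                                       settings = bootstrap_settings(),
                                       reference_year = 2016,
                                       permissive = FALSE) {
  sel <- run_fit_pipeline(resurvey_path, out_dir, terms = terms,
                          permissive = permissive)
  db <- read_occurrence_table(database_path, reference_year = reference_year,
                              permissive = permissive)
  db <- filter_occurrences(db)
  warn_extrapolation_range(sel$fit, db)
  resurvey <- read_resurvey_table(resurvey_path, permissive = permissive,
                                  quiet = TRUE)
  extrap <- bootstrap_extrapolation(resurvey, db, sel$terms, settings)
  write_extrapolation_report(extrap, db, out_dir, write_sums = TRUE)
  groups <- summarize_by_group(extrap, db)
  utils::write.csv(groups, file.path(out_dir, "group_rates.csv"),
                   row.names = FALSE)
  write_provenance(out_dir,
                   inputs = c(resurvey = resurvey_path,
                              database = database_path),
                   settings = settings)
  invisible(list(selection = sel, extrapolation = extrap, groups = groups))
}

# note (not block) predictions outside the training covariate range
warn_extrapolation_range <- function(fit, db) {
  tr <- attr(fit, "training_ranges")
  out <- character(0)
  if (max(db$years_since) > 29) {
    out <- c(out, sprintf("years_since up to %d exceeds the resurvey range",
                          max(db$years_since)))
  }
  if (length(out)) {
    message("extrapolation-range note: ", paste(out, collapse = "; "))
  }
  invisible(out)
}

#' Generate and write synthetic fixture files
#'
#' Writes a synthetic resurvey CSV and occurrence-database CSV in the
#' schemas the readers expect, plus a manifest JSON recording the seed
#' and the true coefficients, so the run can be reproduced exactly.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory.
#' @return paths of the three files, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  resurvey <- generate_resurvey_dataset(config)
  db <- generate_database(config)
  rp <- file.path(out_dir, "synthetic_resurvey.csv")
  dp <- file.path(out_dir, "synthetic_database.csv")
  write_resurvey_table(resurvey, rp)
  write_occurrence_table(db, dp)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = config$seed,
                            true_coefficients = config$true_coefficients,
                            n_resurvey = config$n_resurvey,
                            n_database = config$n_database,
                            files = c(resurvey = "synthetic_resurvey.csv",
                                      database = "synthetic_database.csv")),
                       mp, auto_unbox = TRUE, digits = NA)
  invisible(c(resurvey = rp, database = dp, manifest = mp))
}

write_provenance <- function(dir, inputs, settings) {
  jsonlite::write_json(list(
    package = "extantr",
    version = as.character(utils::packageVersion("extantr")),
    r_version = as.character(getRversion()),
    inputs = as.list(inputs),
    settings = list(n_reps = settings$n_reps,
                    confidence_level = settings$confidence_level,
                    seed = settings$seed,
                    nonconvergence_policy = settings$nonconvergence_policy)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
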