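#' Run the full analysis pipeline
#'
#' Orchestrates the multi-step design end to end: simulate (or load) a
#' cohort, detect and group bradycardia episodes, extract windowed features,
#' assign personalized relative glucose tertiles, run the statistical battery
#' (tertile shares and Mann-Whitney comparisons, hourly HR-glucose
#' correlation, time-banded bootstrap Fisher enrichment, bootstrap Wilcoxon
#' feature tests), and evaluate the balanced Random-Forest forecaster. The
#' whole run is a pure function of `(config, ranges, n_patients, seed)`.
#'
#' @param config An [analysis_config()].
#' @param n_patients Cohort size when simulating.
#' @param seed Master seed (default `config$rng_seed`).
#' @param records Optional list of [patient_record()]s; when `NULL` a cohort
#'   is simulated from `ranges`.
#' @param ranges [cohort_param_ranges()] for simulation.
#' @param days Recording length in days for simulation.
#' @param out_dir Optional directory; when given, per-stage JSON/CSV outputs
#'   and a run manifest (config snapshot, seed, file digests) are written.
#' @return A list (class `bg_report`) with `episode_summaries`, `shares`,
#'   `utests`, `correlation`, `fisher_bands`, `wilcoxon`, `cv`,
#'   `importances`, `pr_curve`, `notes` and `manifest`.
#' @export
run_full_analysis <- function(config = analysis_config(), n_patients = 20,
                              seed = config$rng_seed, records = NULL,
                              ranges = cohort_param_ranges(),
                              days = config$recording_days, out_dir = NULL) {
  notes <- character(0)
  if (is.null(records)) {
    log_stage("simulating cohort of ", n_patients, " patients x ", days, " days")
    cohort <- simulate_cohort(n_patients, config, seed, ranges, days)
    records <- lapply(cohort, `[[`, "record")
  }
  log_stage("detecting episodes")
  episodes <- lapply(records, function(r) detect_bradycardia(r$rr, config))
  names(episodes) <- vapply(records, `[[`, character(1), "patient_id")
  groups <- lapply(episodes, group_episodes, config = config)
  summaries <- mapply(function(g, r) {
    episode_summary(g, days = rr_duration_s(r$rr) / 86400,
                    start_clock_h = r$metadata$start_clock_h)
  }, groups, records, SIMPLIFY = FALSE)
  n_with <- sum(vapply(groups, nrow, integer(1)) > 0)

  log_stage("extracting features")
  table <- build_feature_table(records, episodes, config)

  bounds <- lapply(records, function(r) {
    compute_tertile_bounds(impute_glucose(r$glucose, config$cgm_max_gap_slots),
                           mode = config$tertile_mode)
  })
  names(bounds) <- names(episodes)
  table <- annotate_table(table, bounds)

  shares <- utests <- correlation <- fisher_bands <- wilcoxon <- NULL
  cv <- importances <- pr <- NULL
  if (n_with == 0 || !any(table$contains_brady_event)) {
    notes <- c(notes, "no bradycardia episodes detected; association statistics and forecasting skipped")
  } else {
    log_stage("association statistics")
    shares <- tertile_event_shares(table, config$timeband_h)
    utests <- tryCatch(
      mannwhitney_tertile_comparison(tertile_event_frequencies(table), config),
      error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
    correlation <- tryCatch(hourly_hr_glucose_correlation(table),
      error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
    fisher_bands <- bootstrap_fisher_by_timeband(table, config,
                                                 derive_seed(seed, "fisher"))
    wilcoxon <- tryCatch(
      suppressWarnings(wilcoxon_hrv_bootstrap(table, config,
                                              derive_seed(seed, "wilcoxon"))),
      error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })

    log_stage("forecasting")
    labeled <- label_windows(table, groups, config)
    if (config$zscore) labeled <- zscore_per_patient(labeled)
    cv <- tryCatch(
      balanced_cv_evaluate(labeled, config, derive_seed(seed, "cv")),
      error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
    if (!is.null(cv)) {
      importances <- feature_importance_summary(cv)
      pr <- precision_recall_curve(cv)
    }
  }

  report <- structure(list(
    n_patients = length(records),
    n_patients_with_brady = n_with,
    episode_summaries = summaries,
    n_windows = nrow(table),
    shares = shares, utests = utests, correlation = correlation,
    fisher_bands = fisher_bands, wilcoxon = wilcoxon,
    cv = cv, importances = importances, pr_curve = pr,
    notes = notes,
    manifest = list(seed = seed, config = unclass(config),
                    n_patients = length(records), days = days)
  ), class = "bg_report")

  if (!is.null(out_dir)) write_report(report, table, records, out_dir)
  report
}

#' @export
print.bg_report <- function(x, ...) {
  cat("<bg_report>", x$n_patients, "patients,", x$n_patients_with_brady,
      "with bradycardia;", x$n_windows, "feature windows\n")
  if (!is.null(x$cv)) print(x$cv)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "cv_report"))
      x <- list(summary = x$summary, iterations = x$iterations,
                settings = x$settings)
    if (is.data.frame(x)) {
      x$samples <- NULL
      x$members <- NULL
      return(x)
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- strip(unclass(report))
  out$pr_curve <- if (!is.null(report$pr_curve))
    list(area = report$pr_curve$area) else NULL
  out
}

#' Serialize a report (and stage outputs) to a directory
#'
#' Writes `report.json` (the consolidated result), `features.csv`, per-stage
#' JSONs, and `manifest.json` with md5 digests of every written file so a
#' re-run can be checked for byte-identical outputs.
#'
#' @param report A `bg_report`.
#' @param table The annotated feature table.
#' @param records The patient records analysed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(report, table, records, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jfile <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_to_list(report), jfile, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  ffile <- file.path(out_dir, "features.csv")
  tbl <- table
  tbl$interval_idx <- NULL
  write_csv_exact(tbl, ffile)
  files <- c(jfile, ffile)
  manifest <- c(report$manifest,
                list(files = lapply(stats::setNames(as.list(files),
                                                    basename(files)),
                                    function(f) unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
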