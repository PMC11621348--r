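# CSV dialect: comma-separated, UTF-8, mandatory header, "." decimal mark,
# missing values as empty fields. Numbers are written with %.17g so that
# write -> read round-trips doubles bit-exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v),
                character(1))
  out
}

write_csv_exact <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col)
    else if (is.logical(col)) ifelse(is.na(col), "", ifelse(col, "TRUE", "FALSE"))
    else ifelse(is.na(col), "", as.character(col))
  })
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_csv_exact <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                        colClasses = NA, stringsAsFactors = FALSE)
  df
}

#' Read / write RR interval files
#'
#' The file must have a header with columns `time_s` and/or `rr_ms`; the
#' absent one is derived (beat times from cumulated intervals starting at 0,
#' or intervals from successive beat times). In files with both columns,
#' `rr_ms` on a beat row is the interval *ending* at that beat, so the first
#' row has an empty `rr_ms` field.
#'
#' @param path CSV file path.
#' @param patient_id Patient id to attach (defaults to the file name).
#' @return `read_rr` returns an [rr_series()].
#' @export
read_rr <- function(path, patient_id = NULL) {
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read_csv_exact(path)
  if (nrow(df) == 0) stop("empty RR file: ", path, call. = FALSE)
  has_t <- "time_s" %in% names(df)
  has_rr <- "rr_ms" %in% names(df)
  if (!has_t && !has_rr)
    stop("RR file needs a 'time_s' and/or 'rr_ms' column: ", path, call. = FALSE)
  if (has_t) {
    beat_times <- as.numeric(df$time_s)
    rr_ms <- if (has_rr) as.numeric(df$rr_ms)[-1] else NULL
  } else {
    rr <- as.numeric(df$rr_ms)
    rr <- rr[!is.na(rr)]
    beat_times <- cumsum(c(0, rr)) / 1000
    rr_ms <- rr
  }
  rr_series(patient_id, beat_times, rr_ms)
}

#' @rdname read_rr
#' @param rr An [rr_series()].
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  write_csv_exact(data.frame(time_s = rr$beat_times,
                             rr_ms = c(NA, rr$rr_ms)), path)
}

#' Read / write 5-minute-grid glucose files
#'
#' Columns `time_s` and `glucose_mgdl`; missing values are empty fields (or
#' `NA`). Timestamps must sit on a 300-s grid and present values must lie in
#' [20, 600] mg/dL; violations raise an error naming the offending rows.
#'
#' @param path CSV file path.
#' @param patient_id Patient id to attach (defaults to the file name).
#' @return `read_glucose` returns a [glucose_series()].
#' @export
read_glucose <- function(path, patient_id = NULL) {
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read_csv_exact(path)
  if (nrow(df) == 0) stop("empty glucose file: ", path, call. = FALSE)
  if (!all(c("time_s", "glucose_mgdl") %in% names(df)))
    stop("glucose file needs columns 'time_s' and 'glucose_mgdl': ", path,
         call. = FALSE)
  glucose_series(patient_id, as.numeric(df$time_s), as.numeric(df$glucose_mgdl))
}

#' @rdname read_glucose
#' @param glucose A [glucose_series()].
#' @export
write_glucose <- function(glucose, path) {
  stopifnot(inherits(glucose, "glucose_series"))
  write_csv_exact(data.frame(time_s = glucose$timestamps,
                             glucose_mgdl = glucose$glucose_mgdl), path)
}

#' Read / write feature tables
#'
#' Losslessly round-trips the per-window feature table produced by
#' [build_feature_table()]: the 29 HRV features, glucose, clock features,
#' bradycardia flags and window timestamps. Files missing any schema column
#' are rejected; extra columns (tertile, zone, ...) are preserved.
#'
#' @param path CSV file path.
#' @return `read_feature_table` returns a feature-table `data.frame`.
#' @export
read_feature_table <- function(path) {
  df <- read_csv_exact(path)
  required <- feature_table_schema()
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df$contains_brady_event <- as.logical(df$contains_brady_event)
  for (nm in setdiff(required, c("patient_id", "contains_brady_event")))
    df[[nm]] <- as.numeric(df[[nm]])
  if ("tertile" %in% names(df)) df$tertile <- as.character(df$tertile)
  if ("zone" %in% names(df)) df$zone <- as.character(df$zone)
  df
}

#' @rdname read_feature_table
#' @param table A feature-table `data.frame`.
#' @export
write_feature_table <- function(table, path) {
  missing <- setdiff(feature_table_schema(), names(table))
  if (length(missing))
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  write_csv_exact(table, path)
}

#' Declared column schema of a feature table
#'
#' The window identity columns, the measured glucose value, the two 24-hour
#' clock features, the 29 HRV features and the bradycardia flag.
#'
#' @return Character vector of required column names.
#' @export
feature_table_schema <- function() {
  c("patient_id", "window_start_s", "clock_h", "n_beats", "glucose_mgdl",
    "c24_sin", "c24_cos", hrv_feature_names(), "contains_brady_event")
}
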