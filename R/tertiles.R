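#' Personalized relative glucose tertile bounds
#'
#' Each patient's observed glucose range `[g_min, g_max]` is divided into
#' three *equal-width* levels: low on `[g_min, b1)`, medium on `[b1, b2)`,
#' high on `[b2, g_max]`. The default mode computes one range over the whole
#' recording; `"per_day"` recomputes the range per calendar day (day k =
#' `[k*86400, (k+1)*86400)` seconds from the recording start) for
#' sensitivity analysis.
#'
#' @param glucose A [glucose_series()] (ideally after [impute_glucose()]).
#' @param mode `"recording"` (default) or `"per_day"`.
#' @param min_samples Minimum number of non-missing samples required.
#' @return An object of class `tertile_bounds`: patient id, mode, and a
#'   `data.frame` with columns `day` (`NA` in recording mode), `g_min`, `b1`,
#'   `b2`, `g_max`.
#' @export
compute_tertile_bounds <- function(glucose, mode = c("recording", "per_day"),
                                   min_samples = 12) {
  mode <- match.arg(mode)
  stopifnot(inherits(glucose, "glucose_series"))
  one <- function(v, day) {
    v <- v[!is.na(v)]
    if (length(v) < min_samples)
      stop("fewer than ", min_samples, " non-missing glucose samples",
           if (!is.na(day)) paste0(" on day ", day), call. = FALSE)
    lo <- min(v); hi <- max(v)
    if (hi <= lo)
      stop("degenerate glucose range: g_max == g_min (", lo, " mg/dL)",
           call. = FALSE)
    w <- (hi - lo) / 3
    data.frame(day = day, g_min = lo, b1 = lo + w, b2 = lo + 2 * w, g_max = hi)
  }
  tab <- if (mode == "recording") {
    one(glucose$glucose_mgdl, NA_integer_)
  } else {
    day <- floor(glucose$timestamps / 86400)
    do.call(rbind, lapply(sort(unique(day)), function(d) {
      one(glucose$glucose_mgdl[day == d], d)
    }))
  }
  structure(list(patient_id = glucose$patient_id, mode = mode, table = tab),
            class = "tertile_bounds")
}

#' @export
print.tertile_bounds <- function(x, ...) {
  cat("<tertile_bounds> patient", x$patient_id, "mode", x$mode, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Assign relative glucose levels
#'
#' Maps glucose values to `"low"`, `"medium"` or `"high"` using a patient's
#' [compute_tertile_bounds()]. Bins are left-closed with the maximum included
#' in `"high"`; values outside the observed range clamp to the nearest
#' extreme level; missing values stay missing.
#'
#' @param values Numeric glucose values (mg/dL), `NA` allowed.
#' @param bounds A `tertile_bounds`.
#' @param timestamps Required in `"per_day"` mode to locate each value's day.
#' @return Character vector of levels (`NA` for missing input).
#' @export
assign_tertile <- function(values, bounds, timestamps = NULL) {
  stopifnot(inherits(bounds, "tertile_bounds"))
  out <- rep(NA_character_, length(values))
  tab <- bounds$table
  if (bounds$mode == "recording") {
    row_for <- rep(1L, length(values))
  } else {
    if (is.null(timestamps))
      stop("per_day bounds need timestamps to assign levels", call. = FALSE)
    day <- floor(timestamps / 86400)
    row_for <- match(day, tab$day)
  }
  ok <- !is.na(values) & !is.na(row_for)
  b1 <- tab$b1[row_for]; b2 <- tab$b2[row_for]
  out[ok & values < b1] <- "low"
  out[ok & values >= b1 & values < b2] <- "medium"
  out[ok & values >= b2] <- "high"
  out
}

#' Annotate a feature table with relative glucose tertiles
#'
#' Adds a `tertile` column to every window with non-missing glucose, using
#' each patient's personalized bounds. Patients present in the table but
#' absent from `bounds_list` raise an error.
#'
#' @param table Feature table from [build_feature_table()].
#' @param bounds_list Named list (by patient id) of `tertile_bounds`, or a
#'   single `tertile_bounds` for a one-patient table.
#' @return The table with a `tertile` column; per-patient level counts in
#'   attribute `tertile_counts`.
#' @export
annotate_table <- function(table, bounds_list) {
  if (inherits(bounds_list, "tertile_bounds"))
    bounds_list <- stats::setNames(list(bounds_list), bounds_list$patient_id)
  pts <- unique(table$patient_id)
  missing <- setdiff(pts, names(bounds_list))
  if (length(missing))
    stop("no tertile bounds for patient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  table$tertile <- NA_character_
  for (p in pts) {
    i <- table$patient_id == p
    table$tertile[i] <- assign_tertile(table$glucose_mgdl[i], bounds_list[[p]],
                                       timestamps = table$window_start_s[i])
  }
  counts <- table(table$patient_id,
                  factor(table$tertile, levels = c("low", "medium", "high")),
                  useNA = "ifany")
  attr(table, "tertile_counts") <- counts
  table
}
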