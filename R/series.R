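#' Beat-to-beat RR interval series
#'
#' Timestamped RR intervals for one patient. `beat_times` are seconds since
#' the recording start (strictly increasing); `rr_ms` holds one interval per
#' beat after the first, so `rr_ms[i]` is the time from beat `i` to beat
#' `i + 1` in milliseconds.
#'
#' @param patient_id Character scalar.
#' @param beat_times Numeric vector of beat times in seconds, strictly
#'   increasing, starting at or after 0.
#' @param rr_ms Optional interval durations in ms (length
#'   `length(beat_times) - 1`); derived from `beat_times` when omitted.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(patient_id, beat_times, rr_ms = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2)
    stop("an RR series needs at least two beats", call. = FALSE)
  if (is.null(rr_ms)) rr_ms <- diff(beat_times) * 1000
  rr_ms <- as.numeric(rr_ms)
  x <- structure(list(patient_id = as.character(patient_id),
                      beat_times = beat_times, rr_ms = rr_ms),
                 class = "rr_series")
  validate_rr_series(x)
}

validate_rr_series <- function(x) {
  n <- length(x$beat_times)
  d <- diff(x$beat_times)
  bad <- which(d <= 0)
  if (length(bad))
    stop("beat times not strictly increasing; first offending beat at row ",
         bad[1] + 1, " (t = ", x$beat_times[bad[1] + 1], " s)", call. = FALSE)
  if (length(x$rr_ms) != n - 1)
    stop("rr_ms must have one value per beat after the first", call. = FALSE)
  if (any(x$rr_ms <= 0))
    stop("all RR intervals must be positive; first offending interval at row ",
         which(x$rr_ms <= 0)[1], call. = FALSE)
  err <- abs(x$rr_ms - d * 1000)
  if (any(err > 1))
    stop("rr_ms inconsistent with beat times (> 1 ms) at row ",
         which(err > 1)[1], call. = FALSE)
  x
}

#' @export
print.rr_series <- function(x, ...) {
  cat("<rr_series> patient", x$patient_id, "-", length(x$beat_times), "beats over",
      round(rr_duration_s(x) / 3600, 2), "h; mean RR",
      round(mean(x$rr_ms), 1), "ms\n")
  invisible(x)
}

#' Duration of an RR series in seconds
#' @param rr An `rr_series`.
#' @export
rr_duration_s <- function(rr) {
  utils::tail(rr$beat_times, 1) - rr$beat_times[1] +
    utils::tail(rr$rr_ms, 1) / 1000
}

#' Interstitial glucose series on a 5-minute grid
#'
#' @param patient_id Character scalar.
#' @param timestamps Seconds since recording start; strictly increasing and
#'   congruent to a 300-s grid (within 1 s).
#' @param glucose_mgdl Glucose in mg/dL; `NA` marks gaps. Present values must
#'   lie in [20, 600].
#' @param grid_s Grid spacing in seconds (default 300).
#' @return An object of class `glucose_series`.
#' @export
glucose_series <- function(patient_id, timestamps, glucose_mgdl, grid_s = 300) {
  x <- structure(list(patient_id = as.character(patient_id),
                      timestamps = as.numeric(timestamps),
                      glucose_mgdl = as.numeric(glucose_mgdl),
                      grid_s = grid_s),
                 class = "glucose_series")
  validate_glucose_series(x)
}

validate_glucose_series <- function(x) {
  if (length(x$timestamps) != length(x$glucose_mgdl))
    stop("timestamps and glucose values must have equal length", call. = FALSE)
  if (length(x$timestamps) == 0)
    stop("empty glucose series", call. = FALSE)
  d <- diff(x$timestamps)
  bad <- which(d <= 0)
  if (length(bad))
    stop("glucose timestamps not strictly increasing; first offending row ",
         bad[1] + 1, call. = FALSE)
  off <- (x$timestamps - x$timestamps[1]) %% x$grid_s
  off <- pmin(off, x$grid_s - off)
  if (any(off > 1))
    stop("timestamp off the ", x$grid_s, "-s grid at row ",
         which(off > 1)[1], " (t = ", x$timestamps[which(off > 1)[1]], " s)",
         call. = FALSE)
  v <- x$glucose_mgdl
  oob <- which(!is.na(v) & (v < 20 | v > 600))
  if (length(oob))
    stop("glucose outside [20, 600] mg/dL at row(s) ",
         paste(utils::head(oob, 5), collapse = ", "), call. = FALSE)
  x
}

#' @export
print.glucose_series <- function(x, ...) {
  cat("<glucose_series> patient", x$patient_id, "-", length(x$timestamps),
      "samples,", sum(is.na(x$glucose_mgdl)), "missing; mean",
      round(mean(x$glucose_mgdl, na.rm = TRUE), 1), "mg/dL\n")
  invisible(x)
}

#' Paired RR and glucose recording for one patient
#'
#' Both streams share the patient id and the time origin (recording start);
#' `metadata$start_clock_h` holds the wall-clock hour of that origin so clock
#' features can be computed.
#'
#' @param rr An `rr_series`.
#' @param glucose A `glucose_series`.
#' @param metadata Named list (e.g. age, dialysis flag, `start_clock_h`).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(rr, glucose, metadata = list()) {
  stopifnot(inherits(rr, "rr_series"), inherits(glucose, "glucose_series"))
  if (rr$patient_id != glucose$patient_id)
    stop("rr and glucose belong to different patients (", rr$patient_id,
         " vs ", glucose$patient_id, ")", call. = FALSE)
  if (is.null(metadata$start_clock_h)) metadata$start_clock_h <- 0
  structure(list(patient_id = rr$patient_id, rr = rr, glucose = glucose,
                 metadata = metadata),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$patient_id, "\n")
  print(x$rr)
  print(x$glucose)
  invisible(x)
}
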