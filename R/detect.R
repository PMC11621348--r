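#' Detect bradycardia episodes in an RR stream
#'
#' A bradycardia episode is a maximal run of at least `min_run_beats`
#' (default 5, i.e. "more than 4") consecutive intervals whose instantaneous
#' heart rate `60000 / rr_ms` is strictly below `hr_threshold_bpm` (default
#' 45 bpm, equivalently RR > 1333.3 ms). Detection runs on the raw stream,
#' before any feature-stage cleaning.
#'
#' @param rr An [rr_series()].
#' @param config An [analysis_config()].
#' @return A `data.frame` ordered by start time with columns `start_s`,
#'   `end_s` (time of first/last beat bounding the run), `n_beats` (number of
#'   slow intervals) and `min_hr_bpm`. Zero rows when nothing is found.
#' @export
detect_bradycardia <- function(rr, config = analysis_config()) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_beats = integer(0), min_hr_bpm = numeric(0))
  if (is.null(rr) || length(rr$rr_ms) == 0) return(empty)
  slow <- 60000 / rr$rr_ms < config$hr_threshold_bpm
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= config$min_run_beats)
  if (!length(hit)) return(empty)
  data.frame(
    start_s = rr$beat_times[starts[hit]],
    end_s = rr$beat_times[ends[hit] + 1],
    n_beats = r$lengths[hit],
    min_hr_bpm = vapply(hit, function(i) {
      min(60000 / rr$rr_ms[starts[i]:ends[i]])
    }, numeric(1))
  )
}

#' Merge nearby bradycardia episodes into groups
#'
#' Single-linkage chaining: consecutive episodes whose gap (end of the
#' earlier to start of the later) is strictly less than
#' `episode_merge_gap_s` (default 300 s) fall in one group; a gap of exactly
#' 5 minutes separates groups.
#'
#' @param episodes Episode `data.frame` from [detect_bradycardia()], sorted
#'   by start time and non-overlapping.
#' @param config An [analysis_config()].
#' @return A `data.frame` with `start_s`, `end_s`, `episode_count` and a list
#'   column `members` holding each group's member episodes.
#' @export
group_episodes <- function(episodes, config = analysis_config()) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      episode_count = integer(0))
  empty$members <- list()
  if (is.null(episodes) || nrow(episodes) == 0) return(empty)
  if (is.unsorted(episodes$start_s, strictly = FALSE))
    stop("episodes must be sorted by start time", call. = FALSE)
  if (nrow(episodes) > 1 &&
      any(episodes$start_s[-1] < episodes$end_s[-nrow(episodes)] - 1e-9))
    stop("episodes must be non-overlapping", call. = FALSE)
  gap <- episodes$start_s[-1] - episodes$end_s[-nrow(episodes)]
  new_group <- c(TRUE, gap >= config$episode_merge_gap_s)
  gid <- cumsum(new_group)
  out <- data.frame(
    start_s = tapply(episodes$start_s, gid, min),
    end_s = tapply(episodes$end_s, gid, max),
    episode_count = as.integer(tapply(gid, gid, length))
  )
  out$members <- split(episodes, gid)
  rownames(out) <- NULL
  out
}

#' Per-patient episode summary
#'
#' Group count, hour-of-day histogram of group onsets, and the frequency
#' category used to describe the cohort: fewer than 10 groups, 10 to 50, or
#' more than 50 over the recording.
#'
#' @param groups Group `data.frame` from [group_episodes()].
#' @param days Recording length in days (for the per-day rate).
#' @param start_clock_h Wall-clock hour of the recording start.
#' @return List with `n_groups`, `per_day`, `category` and `hourly` (24
#'   counts, hour 0 first).
#' @export
episode_summary <- function(groups, days = 7, start_clock_h = 0) {
  n <- nrow(groups)
  hourly <- rep(0L, 24)
  if (n) {
    h <- floor((start_clock_h + groups$start_s / 3600) %% 24)
    tab <- table(factor(h, levels = 0:23))
    hourly <- as.integer(tab)
  }
  category <- if (n < 10) "<10" else if (n <= 50) "10-50" else ">50"
  list(n_groups = n, per_day = n / days, category = category,
       hourly = stats::setNames(hourly, 0:23))
}
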