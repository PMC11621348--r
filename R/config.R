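#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline. Defaults encode the
#' study design: bradycardia = more than 4 consecutive beats below 45 bpm,
#' 5-minute non-overlapping windows matched to the CGM reporting grid,
#' 5-minute episode merging, 100 bootstrap iterations for the Fisher and
#' Wilcoxon resampling schemes (200 windows per class for the latter), and
#' 50 iterations of balanced 5-fold stratified cross-validation.
#'
#' @param hr_threshold_bpm Bradycardia heart-rate threshold in beats per
#'   minute; a beat counts as slow when its instantaneous HR (60000/RR in ms)
#'   is strictly below this value.
#' @param min_run_beats Minimum number of consecutive slow intervals that
#'   constitutes an episode ("more than 4" = at least 5).
#' @param window_len_s Analysis window length in seconds; must divide 86400.
#' @param episode_merge_gap_s Episodes closer than this (end to next start)
#'   are merged into one group.
#' @param risk_lead_s Lead time before a group start in which a window is
#'   labeled a risk zone.
#' @param normal_buffer_s Minimum clearance from any episode group required
#'   for a normal-zone window.
#' @param n_boot_fisher,n_boot_wilcoxon Bootstrap iteration counts.
#' @param wilcoxon_sample_n Windows drawn per class per Wilcoxon iteration.
#' @param cv_iterations,cv_folds Balanced cross-validation design.
#' @param rng_seed Default seed used when a function is not given one.
#' @param tertile_mode "recording" (one glucose range per patient) or
#'   "per_day" (range recomputed per calendar day).
#' @param sampen_r_factor Sample-entropy tolerance as a fraction of the
#'   window's RR standard deviation.
#' @param interp_hz Resampling frequency (Hz) for spectral analysis.
#' @param rr_min_ms,rr_max_ms Plausibility bounds for RR cleaning; intervals
#'   outside are treated as artifacts and dropped before feature extraction.
#' @param min_window_beats,min_window_coverage Window validity rules: at
#'   least this many retained intervals and this fraction of the window
#'   spanned by retained intervals.
#' @param cgm_max_gap_slots CGM gaps up to this many 5-minute slots are
#'   linearly interpolated; longer gaps stay missing.
#' @param rf_num_trees Trees per Random-Forest fit.
#' @param zscore Whether to per-patient z-score features before classification.
#' @param recording_days Nominal recording length in days.
#' @param timeband_h Width (hours) of the clock bands for the Fisher
#'   enrichment analysis.
#' @param timeband_min_windows Bands with fewer usable windows are flagged
#'   unreliable.
#' @param exact_u_max_n Mann-Whitney switches from the exact to the normal
#'   approximation above this combined sample size.
#'
#' @return An object of class `analysis_config` (a validated named list).
#' @export
analysis_config <- function(hr_threshold_bpm = 45,
                            min_run_beats = 5,
                            window_len_s = 300,
                            episode_merge_gap_s = 300,
                            risk_lead_s = 300,
                            normal_buffer_s = 300,
                            n_boot_fisher = 100,
                            n_boot_wilcoxon = 100,
                            wilcoxon_sample_n = 200,
                            cv_iterations = 50,
                            cv_folds = 5,
                            rng_seed = 1L,
                            tertile_mode = c("recording", "per_day"),
                            sampen_r_factor = 0.2,
                            interp_hz = 4,
                            rr_min_ms = 300,
                            rr_max_ms = 3000,
                            min_window_beats = 10,
                            min_window_coverage = 0.5,
                            cgm_max_gap_slots = 3,
                            rf_num_trees = 500,
                            zscore = TRUE,
                            recording_days = 7,
                            timeband_h = 3,
                            timeband_min_windows = 20,
                            exact_u_max_n = 20) {
  tertile_mode <- match.arg(tertile_mode)
  cfg <- list(
    hr_threshold_bpm = hr_threshold_bpm, min_run_beats = min_run_beats,
    window_len_s = window_len_s, episode_merge_gap_s = episode_merge_gap_s,
    risk_lead_s = risk_lead_s, normal_buffer_s = normal_buffer_s,
    n_boot_fisher = n_boot_fisher, n_boot_wilcoxon = n_boot_wilcoxon,
    wilcoxon_sample_n = wilcoxon_sample_n, cv_iterations = cv_iterations,
    cv_folds = cv_folds, rng_seed = as.integer(rng_seed),
    tertile_mode = tertile_mode, sampen_r_factor = sampen_r_factor,
    interp_hz = interp_hz, rr_min_ms = rr_min_ms, rr_max_ms = rr_max_ms,
    min_window_beats = min_window_beats,
    min_window_coverage = min_window_coverage,
    cgm_max_gap_slots = cgm_max_gap_slots, rf_num_trees = rf_num_trees,
    zscore = isTRUE(zscore), recording_days = recording_days,
    timeband_h = timeband_h, timeband_min_windows = timeband_min_windows,
    exact_u_max_n = exact_u_max_n
  )
  counts <- c("hr_threshold_bpm", "min_run_beats", "window_len_s",
              "episode_merge_gap_s", "risk_lead_s", "normal_buffer_s",
              "n_boot_fisher", "n_boot_wilcoxon", "wilcoxon_sample_n",
              "cv_iterations", "cv_folds", "sampen_r_factor", "interp_hz",
              "rr_min_ms", "rr_max_ms", "min_window_beats", "rf_num_trees",
              "recording_days", "timeband_h")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be a positive scalar", call. = FALSE)
  }
  if (86400 %% cfg$window_len_s != 0)
    stop("window_len_s must divide 86400 seconds", call. = FALSE)
  if (cfg$min_window_coverage < 0 || cfg$min_window_coverage > 1)
    stop("min_window_coverage must lie in [0, 1]", call. = FALSE)
  class(cfg) <- "analysis_config"
  cfg
}

#' Convert a heart-rate threshold to its RR-interval equivalent
#'
#' A beat is slower than `hr_bpm` exactly when its RR interval exceeds
#' `60000 / hr_bpm` milliseconds; 45 bpm corresponds to 1333.3 ms.
#'
#' @param hr_bpm Heart rate in beats per minute.
#' @return RR interval in milliseconds.
#' @export
hr_to_rr_ms <- function(hr_bpm) 60000 / hr_bpm

#' @rdname hr_to_rr_ms
#' @param rr_ms RR interval in milliseconds.
#' @export
rr_ms_to_hr <- function(rr_ms) 60000 / rr_ms

#' Derive a reproducible child seed from a parent seed and labels
#'
#' Counter-based scheme: the child seed depends only on the parent seed and
#' the label path, so adding patients or stages never perturbs the random
#' draws of existing ones.
#'
#' @param seed Integer parent seed.
#' @param ... Labels (strings or integers) identifying the substream.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (b in utf8ToInt(labels)) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Read or write an analysis configuration as JSON
#'
#' @param path File path.
#' @return `read_config` returns an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, vals[names(vals) %in% names(formals(analysis_config))])
}

#' @rdname read_config
#' @param config An `analysis_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

log_stage <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [bradyglucose] ", ...)
}
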