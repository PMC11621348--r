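#' Parameters of one simulated patient
#'
#' The generator emulates the structure of 7-day paired CGM/Holter
#' recordings: a circadian cosine glucose profile with AR(1) noise, an RR
#' stream with circadian heart-rate modulation plus sinusoidal LF (0.1 Hz)
#' and HF (0.25 Hz) variability and beat-to-beat noise, and injected
#' bradycardia runs whose hourly intensity can depend on the patient's
#' relative glucose tertile and on the time of day (nocturnal excess), with
#' an optional pre-episode heart-rate drift that gives the forecasting stage
#' a learnable signal.
#'
#' @param glucose_mesor,glucose_amplitude Circadian mean and half-range of
#'   glucose (mg/dL).
#' @param glucose_acrophase_h Clock hour of the glucose maximum.
#' @param glucose_ar1_phi AR(1) coefficient of the glucose noise per 5-min
#'   step (0-1).
#' @param glucose_noise_sd Marginal SD of the glucose noise (mg/dL).
#' @param hr_mesor,hr_amplitude,hr_acrophase_h Circadian heart-rate profile
#'   (bpm / clock hour of maximum).
#' @param rr_lf_mod_ms,rr_hf_mod_ms Depth (ms) of sinusoidal RR modulation at
#'   0.1 Hz and 0.25 Hz.
#' @param rr_noise_sd_ms Beat-to-beat Gaussian RR noise SD (ms).
#' @param brady_base_rate Baseline bradycardia injection intensity, episodes
#'   per hour.
#' @param brady_odds_low,brady_odds_high Rate multipliers while the current
#'   glucose sits in the patient's low / high tertile.
#' @param brady_nocturnal_mult Rate multiplier on clock hours [0, 6).
#' @param brady_tertile_band_h Optional `c(start_h, end_h)`; when set, the
#'   tertile multipliers apply only inside this clock band (elsewhere 1).
#' @param pre_episode_hr_drift_bpm Linear heart-rate decline (bpm) reached at
#'   episode onset over the `pre_episode_drift_len_s` seconds before it; 0
#'   disables the drift.
#' @param pre_episode_drift_len_s Length of the pre-episode drift span (s).
#' @param episode_len_beats Range (2 values) of slow intervals per injected
#'   run.
#' @param episode_hr_bpm Range (2 values) of the episode heart rate; must lie
#'   strictly below the detection threshold.
#' @param start_clock_h Wall-clock hour of the recording start.
#' @return An object of class `sim_patient_params`.
#' @export
sim_patient_params <- function(glucose_mesor = 165, glucose_amplitude = 30,
                               glucose_acrophase_h = 16,
                               glucose_ar1_phi = 0.8, glucose_noise_sd = 8,
                               hr_mesor = 73, hr_amplitude = 8,
                               hr_acrophase_h = 15,
                               rr_lf_mod_ms = 20, rr_hf_mod_ms = 15,
                               rr_noise_sd_ms = 25,
                               brady_base_rate = 0.5,
                               brady_odds_low = 3, brady_odds_high = 1,
                               brady_nocturnal_mult = 2,
                               brady_tertile_band_h = NULL,
                               pre_episode_hr_drift_bpm = 15,
                               pre_episode_drift_len_s = 600,
                               episode_len_beats = c(5, 15),
                               episode_hr_bpm = c(35, 44),
                               start_clock_h = 0) {
  p <- as.list(environment())
  rates <- c(p$brady_base_rate, p$brady_odds_low, p$brady_odds_high,
             p$brady_nocturnal_mult)
  if (any(rates < 0)) stop("rates and multipliers must be >= 0", call. = FALSE)
  if (p$glucose_ar1_phi < 0 || p$glucose_ar1_phi >= 1)
    stop("glucose_ar1_phi must lie in [0, 1)", call. = FALSE)
  if (length(p$episode_len_beats) != 2 || length(p$episode_hr_bpm) != 2)
    stop("episode_len_beats and episode_hr_bpm must be 2-value ranges",
         call. = FALSE)
  class(p) <- "sim_patient_params"
  p
}

#' Simulate a circadian CGM glucose series
#'
#' `value(t) = mesor + amplitude * cos(2*pi*(clock_h - acrophase)/24)` plus
#' stationary AR(1) noise with marginal SD `glucose_noise_sd`, sampled on the
#' 300-s reporting grid and clipped to the physiological CGM range
#' [20, 600] mg/dL.
#'
#' @param params A [sim_patient_params()].
#' @param days Number of simulated days (>= 1).
#' @param seed Integer seed; the series is a pure function of
#'   `(params, days, seed)`.
#' @param patient_id Patient id for the resulting series.
#' @return A [glucose_series()] of length `days * 288`.
#' @export
simulate_glucose <- function(params, days, seed, patient_id = "sim") {
  stopifnot(inherits(params, "sim_patient_params"), days >= 1)
  n <- as.integer(days * 86400 / 300)
  t <- (seq_len(n) - 1) * 300
  clock_h <- params$start_clock_h + t / 3600
  mu <- params$glucose_mesor + params$glucose_amplitude *
    cos(2 * pi * (clock_h - params$glucose_acrophase_h) / 24)
  noise <- with_seed(seed, {
    phi <- params$glucose_ar1_phi
    innov_sd <- params$glucose_noise_sd * sqrt(1 - phi^2)
    e <- rnorm(n, 0, innov_sd)
    as.numeric(stats::filter(e, phi, method = "recursive",
                             init = rnorm(1, 0, params$glucose_noise_sd)))
  })
  v <- mu + noise
  if (all(v <= 20) || all(v >= 600))
    stop("glucose parameters produce an all-clipped series; check mesor/amplitude",
         call. = FALSE)
  v <- pmin(600, pmax(20, v))
  glucose_series(patient_id, t, v)
}

#' Simulate a beat-to-beat RR stream
#'
#' Beats are laid down sequentially with instantaneous RR(t) =
#' 60000 / HR_circadian(t) + lf_mod * sin(2*pi*0.1*t) + hf_mod *
#' sin(2*pi*0.25*t) + Gaussian noise, where HR_circadian follows the
#' patient's cosine profile. Parameter sets driving RR to 200 ms or below
#' raise an error.
#'
#' @param params A [sim_patient_params()].
#' @param glucose A [glucose_series()] covering the simulated span; the RR
#'   stream is generated over the same duration.
#' @param seed Integer seed.
#' @param patient_id Patient id.
#' @return An [rr_series()].
#' @export
simulate_rr <- function(params, glucose, seed, patient_id = glucose$patient_id) {
  stopifnot(inherits(params, "sim_patient_params"),
            inherits(glucose, "glucose_series"))
  duration <- utils::tail(glucose$timestamps, 1) + glucose$grid_s
  hr_max <- params$hr_mesor + abs(params$hr_amplitude)
  min_rr_s <- max(0.21, (60000 / hr_max - abs(params$rr_lf_mod_ms) -
                           abs(params$rr_hf_mod_ms) -
                           6 * params$rr_noise_sd_ms) / 1000)
  n_max <- ceiling(duration / min_rr_s) + 16
  noise <- with_seed(seed, rnorm(n_max, 0, params$rr_noise_sd_ms))
  beats <- gen_beat_times_cpp(duration, params$hr_mesor, params$hr_amplitude,
                              params$hr_acrophase_h, params$rr_lf_mod_ms,
                              params$rr_hf_mod_ms, noise,
                              params$start_clock_h)
  rr_series(patient_id, beats)
}

#' Inject bradycardia runs into an RR stream
#'
#' Ground-truth generator for the detector and the downstream statistics.
#' Candidate onsets are drawn per 5-minute slot from a Poisson law with
#' intensity `brady_base_rate` x tertile multiplier x nocturnal multiplier
#' (per hour). Each accepted run *replaces* the beats in a time span of
#' `n_beats` slow intervals with evenly spaced beats at the drawn episode
#' heart rate, so the total timeline (and hence the glucose alignment) is
#' preserved. When `pre_episode_hr_drift_bpm > 0` the span before the onset
#' is likewise rewritten with a linearly declining heart rate. Overlapping
#' candidates are dropped; an expected occupancy above half the recording
#' raises an error.
#'
#' @param rr An [rr_series()].
#' @param glucose The matching [glucose_series()].
#' @param params A [sim_patient_params()].
#' @param tertile_bounds [tertile_bounds()] computed from the same glucose
#'   series.
#' @param seed Integer seed.
#' @param config An [analysis_config()]; episode heart rates must lie below
#'   `config$hr_threshold_bpm`.
#' @return List with `rr` (modified [rr_series()]) and `truth`, a
#'   `data.frame` of injected runs (`start_s`, `end_s`, `n_beats`,
#'   `tertile`, `hr_bpm`), non-overlapping and ordered.
#' @export
inject_bradycardia <- function(rr, glucose, params, tertile_bounds, seed,
                               config = analysis_config()) {
  stopifnot(inherits(rr, "rr_series"), inherits(glucose, "glucose_series"))
  empty_truth <- data.frame(start_s = numeric(0), end_s = numeric(0),
                            n_beats = integer(0), tertile = character(0),
                            hr_bpm = numeric(0))
  if (params$brady_base_rate == 0)
    return(list(rr = rr, truth = empty_truth))
  if (max(params$episode_hr_bpm) >= config$hr_threshold_bpm)
    stop("episode_hr_bpm must lie strictly below the detection threshold (",
         config$hr_threshold_bpm, " bpm)", call. = FALSE)

  slot_len <- glucose$grid_s
  tert <- assign_tertile(glucose$glucose_mgdl, tertile_bounds,
                         timestamps = glucose$timestamps)
  clock_h <- (params$start_clock_h + glucose$timestamps / 3600) %% 24
  mult <- rep(1, length(tert))
  in_band <- if (is.null(params$brady_tertile_band_h)) rep(TRUE, length(tert))
             else clock_h >= params$brady_tertile_band_h[1] &
                  clock_h < params$brady_tertile_band_h[2]
  mult[in_band & !is.na(tert) & tert == "low"] <- params$brady_odds_low
  mult[in_band & !is.na(tert) & tert == "high"] <- params$brady_odds_high
  mult[clock_h < 6] <- mult[clock_h < 6] * params$brady_nocturnal_mult
  lambda <- params$brady_base_rate * mult * slot_len / 3600

  mean_rr_ep <- 60000 / mean(params$episode_hr_bpm)
  mean_span <- mean(params$episode_len_beats) * mean_rr_ep / 1000
  drift_len <- if (params$pre_episode_hr_drift_bpm > 0)
    params$pre_episode_drift_len_s else 0
  duration <- rr_duration_s(rr)
  if (sum(lambda) * (mean_span + drift_len + 2) > 0.5 * duration)
    stop("requested bradycardia rate is too high: injected runs would overlap",
         call. = FALSE)

  seg <- with_seed(seed, {
    counts <- rpois(length(lambda), lambda)
    onsets <- rep(glucose$timestamps, counts) +
      runif(sum(counts), 0, slot_len)
    onset_tert <- rep(as.character(tert), counts)
    ord <- order(onsets)
    onsets <- onsets[ord]; onset_tert <- onset_tert[ord]
    segs <- list(); truth <- list()
    last_end <- -Inf
    for (i in seq_along(onsets)) {
      t0 <- onsets[i]
      L <- sample(params$episode_len_beats[1]:params$episode_len_beats[2], 1)
      hr_ep <- runif(1, params$episode_hr_bpm[1], params$episode_hr_bpm[2])
      rr_t <- 60000 / hr_ep
      span <- L * rr_t / 1000
      lo <- t0 - drift_len
      hi <- t0 + span
      if (lo < 1 || hi > duration - 1) next
      if (lo < last_end + 2) next
      new_beats <- t0 + (0:L) * rr_t / 1000
      if (drift_len > 0) {
        # rewrite the pre-onset span with the same circadian/LF/HF/noise
        # structure as ordinary beats, but with the heart rate smoothly
        # depressed: the drop saturates a quarter of the way into the span,
        # so the pre-episode state is a genuinely lower heart rate rather
        # than a steep within-window ramp
        tb <- lo; drift_beats <- numeric(0)
        while (tb < t0 - 0.4) {
          drift_beats <- c(drift_beats, tb)
          u <- (tb - lo) / drift_len
          h <- params$hr_mesor + params$hr_amplitude *
            cos(2 * pi * ((params$start_clock_h + tb / 3600) -
                            params$hr_acrophase_h) / 24) -
            params$pre_episode_hr_drift_bpm * min(1, u / 0.25)
          rr_d <- 60000 / h +
            params$rr_lf_mod_ms * sin(2 * pi * 0.1 * tb) +
            params$rr_hf_mod_ms * sin(2 * pi * 0.25 * tb) +
            rnorm(1, 0, params$rr_noise_sd_ms)
          tb <- tb + max(0.25, rr_d / 1000)
        }
        new_beats <- c(drift_beats, new_beats)
      }
      segs[[length(segs) + 1]] <- list(lo = lo, hi = hi, beats = new_beats)
      truth[[length(truth) + 1]] <-
        data.frame(start_s = t0, end_s = hi, n_beats = L,
                   tertile = onset_tert[i], hr_bpm = hr_ep)
      last_end <- hi
    }
    list(segs = segs, truth = truth)
  })
  if (!length(seg$segs)) return(list(rr = rr, truth = empty_truth))

  keep <- rep(TRUE, length(rr$beat_times))
  inserted <- numeric(0)
  for (s in seg$segs) {
    keep[rr$beat_times > s$lo - 0.30 & rr$beat_times < s$hi + 0.30] <- FALSE
    inserted <- c(inserted, s$beats)
  }
  beats <- sort(c(rr$beat_times[keep], inserted))
  beats <- beats[c(TRUE, diff(beats) > 0.2)]
  truth <- do.call(rbind, seg$truth)
  rownames(truth) <- NULL
  list(rr = rr_series(rr$patient_id, beats), truth = truth)
}

#' Parameter ranges for a simulated cohort
#'
#' Between-patient heterogeneity of the generator: ranged entries (2 values)
#' are drawn uniformly per patient, scalars are shared. Defaults mirror the
#' study cohort's published marginals: mean glucose around 165 +/- 40 mg/dL,
#' mean heart rate around 73 +/- 11 bpm, roughly 22% of patients with
#' bradycardia, tertile-dependent injection odds (low 3x), a 2x nocturnal
#' excess and a 15-bpm pre-episode heart-rate drift.
#'
#' @param ... Named overrides of any range or scalar.
#' @return A named list of ranges/scalars (class `cohort_ranges`).
#' @export
cohort_param_ranges <- function(...) {
  r <- list(
    glucose_mesor = c(120, 210), glucose_amplitude = c(15, 45),
    glucose_acrophase_h = c(13, 18), glucose_ar1_phi = 0.8,
    glucose_noise_sd = c(5, 12),
    hr_mesor = c(60, 88), hr_amplitude = c(5, 12),
    hr_acrophase_h = c(13, 17),
    rr_lf_mod_ms = c(10, 30), rr_hf_mod_ms = c(8, 25),
    rr_noise_sd_ms = c(15, 35),
    brady_prevalence = 0.22, brady_base_rate = c(0.2, 1.2),
    brady_odds_low = 3, brady_odds_high = 1, brady_nocturnal_mult = 2,
    brady_tertile_band_h = NULL,
    pre_episode_hr_drift_bpm = 15, pre_episode_drift_len_s = 600,
    episode_len_beats = c(5, 15), episode_hr_bpm = c(35, 44),
    start_clock_h = 0
  )
  over <- list(...)
  bad <- setdiff(names(over), names(r))
  if (length(bad)) stop("unknown range name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  r[names(over)] <- over
  class(r) <- "cohort_ranges"
  r
}

draw_patient_params <- function(ranges, seed) {
  ranged <- c("glucose_mesor", "glucose_amplitude", "glucose_acrophase_h",
              "glucose_noise_sd", "hr_mesor", "hr_amplitude",
              "hr_acrophase_h", "rr_lf_mod_ms", "rr_hf_mod_ms",
              "rr_noise_sd_ms", "brady_base_rate")
  with_seed(seed, {
    vals <- lapply(ranged, function(nm) {
      v <- ranges[[nm]]
      if (length(v) == 2) runif(1, v[1], v[2]) else v
    })
    names(vals) <- ranged
    has_brady <- runif(1) < ranges$brady_prevalence
    if (!has_brady) vals$brady_base_rate <- 0
    do.call(sim_patient_params, c(vals, list(
      glucose_ar1_phi = ranges$glucose_ar1_phi,
      brady_odds_low = ranges$brady_odds_low,
      brady_odds_high = ranges$brady_odds_high,
      brady_nocturnal_mult = ranges$brady_nocturnal_mult,
      brady_tertile_band_h = ranges$brady_tertile_band_h,
      pre_episode_hr_drift_bpm = ranges$pre_episode_hr_drift_bpm,
      pre_episode_drift_len_s = ranges$pre_episode_drift_len_s,
      episode_len_beats = ranges$episode_len_beats,
      episode_hr_bpm = ranges$episode_hr_bpm,
      start_clock_h = ranges$start_clock_h)))
  })
}

#' Simulate a multi-patient cohort with known ground truth
#'
#' Per-patient parameters are drawn from `ranges` with a per-patient derived
#' seed (see [derive_seed()]), so the cohort is a pure function of
#' `(config, ranges, seed)` and adding patients never perturbs existing ones.
#'
#' @param n_patients Number of patients (>= 1).
#' @param config An [analysis_config()].
#' @param seed Integer master seed.
#' @param ranges A [cohort_param_ranges()].
#' @param days Recording length in days (default `config$recording_days`).
#' @return List of per-patient lists with elements `record`
#'   ([patient_record()]), `truth` (injected-run `data.frame`) and `params`.
#' @export
simulate_cohort <- function(n_patients, config = analysis_config(),
                            seed = config$rng_seed,
                            ranges = cohort_param_ranges(),
                            days = config$recording_days) {
  stopifnot(n_patients >= 1)
  lapply(seq_len(n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    ps <- derive_seed(seed, "patient", i)
    params <- draw_patient_params(ranges, derive_seed(ps, "params"))
    glucose <- simulate_glucose(params, days, derive_seed(ps, "glucose"), pid)
    rr <- simulate_rr(params, glucose, derive_seed(ps, "rr"), pid)
    if (params$brady_base_rate > 0) {
      bounds <- compute_tertile_bounds(glucose, mode = config$tertile_mode)
      inj <- inject_bradycardia(rr, glucose, params, bounds,
                                derive_seed(ps, "inject"), config)
    } else {
      inj <- list(rr = rr,
                  truth = data.frame(start_s = numeric(0), end_s = numeric(0),
                                     n_beats = integer(0),
                                     tertile = character(0),
                                     hr_bpm = numeric(0)))
    }
    record <- patient_record(inj$rr, glucose,
                             metadata = list(start_clock_h = params$start_clock_h,
                                             sim_seed = ps))
    list(record = record, truth = inj$truth, params = params)
  })
}
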