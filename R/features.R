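#' Names of the 29 short-term HRV features
#'
#' 14 time-domain features on RR intervals and instantaneous heart rates,
#' 9 spectral features over the VLF/LF/HF bands, and 6 nonlinear features
#' from the Poincare plot and entropy analysis.
#'
#' @return Character vector of length 29.
#' @export
hrv_feature_names <- function() {
  c("RR-sdnn", "RR-pnn50", "RR-pnn20", "RR-rmssd",
    "HR-mean", "HR-median", "HR-std", "HR-max", "HR-min", "HR-p2p",
    "HR-kurtosis", "HR-skewness", "HR-mad", "HR-zcr",
    "RR-vlf-power", "RR-lf-power", "RR-hf-power", "RR-total-power",
    "RR-lf-norm", "RR-hf-norm", "RR-lf-peak", "RR-hf-peak", "RR-lfhf-ratio",
    "RR-sd1", "RR-sd2", "RR-s-area", "RR-sd-ratio",
    "RR-sample-ent", "RR-perm-ent")
}

# frequency bands (Hz)
band_vlf <- c(0.0033, 0.04)
band_lf  <- c(0.04, 0.15)
band_hf  <- c(0.15, 0.40)

pop_var <- function(x) mean((x - mean(x))^2)

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

na_map <- function(names) stats::setNames(rep(NA_real_, length(names)), names)

#' Time-domain HRV features of one window
#'
#' Computes the 14 time-domain features: RR dispersion (sdnn with the sample
#' SD, pNN50/pNN20 as the percentage of successive differences exceeding
#' 50/20 ms, rmssd) and instantaneous heart-rate statistics (HR = 60000/RR
#' per beat): mean, median, SD, max, min, peak-to-peak, excess kurtosis,
#' skewness, median absolute successive change (HR-mad), and the normalized
#' zero-crossing rate of the mean-centered HR series.
#'
#' @param rr_ms Numeric vector of RR intervals in ms (cleaned window).
#' @param min_n Minimum number of intervals; below it all values are `NA`.
#' @return Named numeric vector of length 14.
#' @export
time_domain_features <- function(rr_ms, min_n = 10) {
  nms <- hrv_feature_names()[1:14]
  n <- length(rr_ms)
  if (n < min_n) return(na_map(nms))
  d <- diff(rr_ms)
  hr <- 60000 / rr_ms
  dhr <- diff(hr)
  mu <- mean(hr)
  m2 <- mean((hr - mu)^2)
  sk <- if (m2 > 0) mean((hr - mu)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((hr - mu)^4) / m2^2 - 3 else 0
  s <- hr - mu
  zcr <- sum(s[-1] * s[-n] < 0) / (n - 1)
  out <- c(stats::sd(rr_ms),
           100 * mean(abs(d) > 50),
           100 * mean(abs(d) > 20),
           sqrt(mean(d^2)),
           mu, stats::median(hr), stats::sd(hr), max(hr), min(hr),
           max(hr) - min(hr), ku, sk, stats::median(abs(dhr)), zcr)
  stats::setNames(out, nms)
}

#' Frequency-domain HRV features of one window
#'
#' The unevenly sampled tachogram (RR vs beat time) is interpolated with a
#' cubic spline onto a uniform `interp_hz` grid over the window, mean-
#' removed, Hann-tapered, and its one-sided periodogram integrated
#' (trapezoidally) over the VLF (0.0033-0.04 Hz), LF (0.04-0.15 Hz) and HF
#' (0.15-0.40 Hz) bands. Normalized powers are relative to LF + HF (percent),
#' peaks are the frequency of maximal density within each band, and the
#' LF/HF ratio is expressed in percent.
#'
#' @param rr_ms RR intervals in ms (cleaned window).
#' @param beat_times Start time (s) of each interval, same length as `rr_ms`.
#' @param window_start_s,window_len_s Window extent in seconds.
#' @param interp_hz Resampling frequency, default 4 Hz.
#' @param min_n Minimum number of intervals.
#' @return Named numeric vector of length 9.
#' @export
frequency_domain_features <- function(rr_ms, beat_times, window_start_s,
                                      window_len_s = 300, interp_hz = 4,
                                      min_n = 10) {
  nms <- hrv_feature_names()[15:23]
  if (length(rr_ms) < max(4, min_n)) return(na_map(nms))
  n_out <- round(window_len_s * interp_hz)
  xout <- window_start_s + (seq_len(n_out) - 1) / interp_hz
  xout <- pmin(pmax(xout, min(beat_times)), max(beat_times))
  x <- stats::spline(beat_times, rr_ms, xout = xout, method = "fmm",
                     ties = mean)$y
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_out) - 1) / (n_out - 1))
  X <- stats::fft(x * w)
  k <- seq_len(floor(n_out / 2))           # positive frequencies
  f <- k * interp_hz / n_out
  psd <- 2 * Mod(X[k + 1])^2 / (interp_hz * sum(w^2))
  bandpow <- function(b) {
    i <- which(f >= b[1] & f <= b[2])
    trapz(f[i], psd[i])
  }
  bandpeak <- function(b) {
    i <- which(f >= b[1] & f <= b[2])
    f[i][which.max(psd[i])]
  }
  vlf <- bandpow(band_vlf); lf <- bandpow(band_lf); hf <- bandpow(band_hf)
  tot <- bandpow(c(band_vlf[1], band_hf[2]))
  lfn <- if (lf + hf > 0) 100 * lf / (lf + hf) else NA_real_
  hfn <- if (lf + hf > 0) 100 * hf / (lf + hf) else NA_real_
  ratio <- if (hf > 0) 100 * lf / hf else NA_real_
  stats::setNames(c(vlf, lf, hf, tot, lfn, hfn,
                    bandpeak(band_lf), bandpeak(band_hf), ratio), nms)
}

#' Nonlinear HRV features of one window
#'
#' Poincare-plot geometry and entropies: SD1 = sqrt(Var0(diff(RR))/2) and
#' SD2 = sqrt(2 Var0(RR) - Var0(diff(RR))/2) with population variances (so
#' SD1 = RMSSD/sqrt(2) exactly for zero-mean successive differences), ellipse
#' area pi*SD1*SD2, SD1/SD2 ratio, sample entropy (m = 2, Chebyshev tolerance
#' `r_factor` times the window's RR standard deviation) and permutation
#' entropy (order 3, lag 1, normalized by log 3! to [0, 1]).
#'
#' @param rr_ms RR intervals in ms (cleaned window).
#' @param r_factor Sample-entropy tolerance factor (default 0.2).
#' @param min_n Minimum number of intervals.
#' @return Named numeric vector of length 6.
#' @export
nonlinear_features <- function(rr_ms, r_factor = 0.2, min_n = 10) {
  nms <- hrv_feature_names()[24:29]
  n <- length(rr_ms)
  if (n < min_n) return(na_map(nms))
  vd <- pop_var(diff(rr_ms))
  vr <- pop_var(rr_ms)
  sd1 <- sqrt(vd / 2)
  sd2 <- sqrt(max(0, 2 * vr - vd / 2))
  area <- pi * sd1 * sd2
  ratio <- if (sd2 > 0) sd1 / sd2 else NA_real_
  r <- r_factor * stats::sd(rr_ms)
  samp <- if (r > 0) sampen_cpp(rr_ms, 2L, r) else NA_real_
  stats::setNames(c(sd1, sd2, area, ratio, samp, permutation_entropy(rr_ms)),
                  nms)
}

#' Permutation entropy of a numeric series (order 3, lag 1)
#'
#' Shannon entropy of the distribution of ordinal patterns of consecutive
#' triples, normalized by log(3!) so a single repeating pattern gives 0 and
#' a uniform pattern distribution gives 1. Ties are broken by order of
#' appearance.
#'
#' @param x Numeric vector.
#' @param order Embedding dimension (default 3).
#' @return Normalized permutation entropy in [0, 1].
#' @export
permutation_entropy <- function(x, order = 3) {
  n <- length(x) - order + 1
  if (n < 1) return(NA_real_)
  if (order == 3) {
    # vectorized ordinal coding; ties broken by order of appearance, which
    # matches base order(): an earlier equal value sorts first
    a <- x[seq_len(n)]; b <- x[seq_len(n) + 1]; c <- x[seq_len(n) + 2]
    code <- (b < a) + 2 * (c < a) + 4 * (c < b)
    counts <- tabulate(code + 1, nbins = 8)
  } else {
    pat <- vapply(seq_len(n), function(i) {
      paste(order(x[i:(i + order - 1)]), collapse = "")
    }, character(1))
    counts <- as.integer(table(pat))
  }
  p <- counts[counts > 0] / n
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

#' 24-hour clock features
#'
#' Continuous encoding of the time of day: `sin(2*pi*h/24)` and
#' `cos(2*pi*h/24)`, so midnight maps to (0, 1), 06:00 to (1, 0) and 18:00
#' to (-1, 0).
#'
#' @param clock_h Clock hour in [0, 24) (fractional hours allowed).
#' @return Named vector `c24_sin`, `c24_cos` (or a 2-column matrix for
#'   vector input).
#' @export
clock_features <- function(clock_h) {
  h <- clock_h %% 24
  s <- sin(2 * pi * h / 24)
  co <- cos(2 * pi * h / 24)
  if (length(h) == 1) c(c24_sin = s, c24_cos = co)
  else cbind(c24_sin = s, c24_cos = co)
}

#' Clean the RR intervals of one window
#'
#' Artifact rule: intervals outside `[rr_min_ms, rr_max_ms]` (defaults
#' 300-3000 ms) are dropped. The window is valid only if the retained
#' intervals span at least `min_window_coverage` of the window length and at
#' least `min_window_beats` intervals remain. Invalid windows are excluded
#' from feature extraction.
#'
#' Cleaning happens *after* episode detection, which runs on the raw stream,
#' so slow (bradycardic) beats are never filtered out of the phenomenon under
#' study; 3000 ms comfortably exceeds the 45-bpm threshold (1333 ms).
#'
#' @param rr_ms,beat_times Interval durations (ms) and interval start times
#'   (s) of the raw window.
#' @param config An [analysis_config()].
#' @return List with `rr_ms`, `beat_times`, and logical `valid`.
#' @export
clean_rr_window <- function(rr_ms, beat_times, config = analysis_config()) {
  keep <- rr_ms >= config$rr_min_ms & rr_ms <= config$rr_max_ms
  rr <- rr_ms[keep]
  bt <- beat_times[keep]
  coverage <- sum(rr) / 1000
  valid <- coverage >= config$min_window_coverage * config$window_len_s &&
    length(rr) >= config$min_window_beats
  list(rr_ms = rr, beat_times = bt, valid = valid)
}

#' Impute short CGM gaps
#'
#' Linear interpolation across runs of missing values no longer than
#' `max_gap_slots` grid slots (default 3, i.e. 15 minutes); longer gaps stay
#' missing.
#'
#' @param glucose A [glucose_series()].
#' @param max_gap_slots Maximum gap length to interpolate.
#' @return A [glucose_series()] with short gaps filled.
#' @export
impute_glucose <- function(glucose, max_gap_slots = 3) {
  v <- glucose$glucose_mgdl
  if (!anyNA(v) || sum(!is.na(v)) < 2) return(glucose)
  filled <- stats::approx(glucose$timestamps[!is.na(v)], v[!is.na(v)],
                          xout = glucose$timestamps, rule = 1)$y
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] <= max_gap_slots) {
      idx <- starts[i]:ends[i]
      v[idx] <- filled[idx]
    }
  }
  glucose$glucose_mgdl <- v
  validate_glucose_series(glucose)
}

#' Tile a recording into non-overlapping analysis windows
#'
#' Half-open bins `[k*L, (k+1)*L)` covering `[0, duration)`; each window
#' carries the indices of the RR intervals whose *starting* beat falls in
#' the bin, the CGM grid value whose slot matches the window, and a flag for
#' overlap with any detected bradycardia episode.
#'
#' @param record A [patient_record()].
#' @param episodes Episode `data.frame` from [detect_bradycardia()] (may be
#'   empty).
#' @param config An [analysis_config()].
#' @return A `data.frame` with one row per tiled window: `window_start_s`,
#'   `clock_h`, `glucose_mgdl`, `contains_brady_event`, `n_raw_beats`, and a
#'   list column `interval_idx`.
#' @export
segment_windows <- function(record, episodes = NULL,
                            config = analysis_config()) {
  L <- config$window_len_s
  dur <- rr_duration_s(record$rr)
  n_win <- ceiling(dur / L)
  starts <- (seq_len(n_win) - 1) * L
  # interval i runs from beat_times[i]; assign it to the bin of its start
  t0 <- record$rr$beat_times[-length(record$rr$beat_times)]
  bin <- floor(t0 / L) + 1
  idx_by_bin <- split(seq_along(t0), factor(bin, levels = seq_len(n_win)))
  # glucose slot lookup on the shared grid
  g <- record$glucose
  slot <- round(g$timestamps / L)
  gval <- rep(NA_real_, n_win)
  hit <- slot >= 0 & slot < n_win & abs(g$timestamps - slot * L) <= 1
  gval[slot[hit] + 1] <- g$glucose_mgdl[hit]
  flag <- rep(FALSE, n_win)
  if (!is.null(episodes) && nrow(episodes)) {
    for (i in seq_len(nrow(episodes))) {
      lo <- max(1, floor(episodes$start_s[i] / L) + 1)
      hi <- min(n_win, floor((episodes$end_s[i] - 1e-9) / L) + 1)
      if (hi >= lo) flag[lo:hi] <- TRUE
    }
  }
  clock_h <- (record$metadata$start_clock_h + starts / 3600) %% 24
  out <- data.frame(window_start_s = starts, clock_h = clock_h,
                    glucose_mgdl = gval, contains_brady_event = flag,
                    n_raw_beats = lengths(idx_by_bin))
  out$interval_idx <- unname(idx_by_bin)
  out
}

#' Build the per-window feature table for a cohort
#'
#' For every patient: detected episodes flag the windows they overlap, the
#' RR stream is tiled into 5-minute windows, each raw window is cleaned, and
#' the 29 HRV features plus glucose and clock features are extracted from
#' valid windows. Short CGM gaps are interpolated first (see
#' [impute_glucose()]). Feature extraction is deterministic.
#'
#' @param records List of [patient_record()]s (or a single record).
#' @param episodes Named list (by patient id) of episode `data.frame`s from
#'   [detect_bradycardia()]; computed on the fly when `NULL`.
#' @param config An [analysis_config()].
#' @param compute `"all"` computes every feature; `"labels"` skips the 29
#'   HRV features (left `NA`) for analyses that only need window labels,
#'   glucose and clock values.
#' @return A `data.frame` with the [feature_table_schema()] columns, one row
#'   per *valid* window, with attributes `n_windows_total` and `n_invalid`.
#' @export
build_feature_table <- function(records, episodes = NULL,
                                config = analysis_config(),
                                compute = c("all", "labels")) {
  compute <- match.arg(compute)
  if (inherits(records, "patient_record")) records <- list(records)
  feats <- hrv_feature_names()
  out <- vector("list", length(records))
  n_total <- 0L
  n_invalid <- 0L
  for (p in seq_along(records)) {
    rec <- records[[p]]
    ep <- if (is.null(episodes)) detect_bradycardia(rec$rr, config)
          else episodes[[rec$patient_id]]
    rec$glucose <- impute_glucose(rec$glucose, config$cgm_max_gap_slots)
    win <- segment_windows(rec, ep, config)
    n_total <- n_total + nrow(win)
    rows <- vector("list", nrow(win))
    keep <- logical(nrow(win))
    rr_all <- rec$rr$rr_ms
    bt_all <- rec$rr$beat_times
    for (i in seq_len(nrow(win))) {
      idx <- win$interval_idx[[i]]
      cl <- clean_rr_window(rr_all[idx], bt_all[idx], config)
      if (!cl$valid) next
      keep[i] <- TRUE
      if (compute == "all") {
        fv <- c(time_domain_features(cl$rr_ms, config$min_window_beats),
                frequency_domain_features(cl$rr_ms, cl$beat_times,
                                          win$window_start_s[i],
                                          config$window_len_s,
                                          config$interp_hz,
                                          config$min_window_beats),
                nonlinear_features(cl$rr_ms, config$sampen_r_factor,
                                   config$min_window_beats))
      } else {
        fv <- na_map(feats)
      }
      rows[[i]] <- c(n_beats = length(cl$rr_ms), fv)
    }
    if (!any(keep)) { n_invalid <- n_invalid + nrow(win); next }
    m <- do.call(rbind, rows[keep])
    cc <- clock_features(win$clock_h[keep])
    df <- data.frame(patient_id = rec$patient_id,
                     window_start_s = win$window_start_s[keep],
                     clock_h = win$clock_h[keep],
                     n_beats = m[, "n_beats"],
                     glucose_mgdl = win$glucose_mgdl[keep],
                     c24_sin = cc[, "c24_sin"], c24_cos = cc[, "c24_cos"],
                     check.names = FALSE)
    df[feats] <- m[, feats, drop = FALSE]
    df$contains_brady_event <- win$contains_brady_event[keep]
    rownames(df) <- NULL
    n_invalid <- n_invalid + sum(!keep)
    out[[p]] <- df
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(feature_table_schema()))),
      feature_table_schema())
  }
  rownames(res) <- NULL
  attr(res, "n_windows_total") <- n_total
  attr(res, "n_invalid") <- n_invalid
  res
}
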