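# Independent straight-from-definition implementations used as oracles.
# These deliberately use naive loops / direct sums, not the package's code
# paths.

# exhaustive bradycardia run scan: tests every possible run of consecutive
# slow intervals
oracle_detect <- function(rr, threshold_bpm = 45, min_run = 5) {
  slow <- 60000 / rr$rr_ms < threshold_bpm
  n <- length(slow)
  out <- list()
  i <- 1
  while (i <= n) {
    if (slow[i]) {
      j <- i
      while (j < n && slow[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) {
        out[[length(out) + 1]] <- data.frame(
          start_s = rr$beat_times[i], end_s = rr$beat_times[j + 1],
          n_beats = j - i + 1L,
          min_hr_bpm = min(60000 / rr$rr_ms[i:j]))
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(out)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_beats = integer(0), min_hr_bpm = numeric(0)))
  }
  do.call(rbind, out)
}

oracle_time_domain <- function(rr) {
  n <- length(rr)
  d <- rr[-1] - rr[-n]
  hr <- 60000 / rr
  sdnn <- sqrt(sum((rr - mean(rr))^2) / (n - 1))
  pnn50 <- 100 * sum(abs(d) > 50) / length(d)
  pnn20 <- 100 * sum(abs(d) > 20) / length(d)
  rmssd <- sqrt(sum(d^2) / length(d))
  mu <- sum(hr) / n
  m2 <- sum((hr - mu)^2) / n
  m3 <- sum((hr - mu)^3) / n
  m4 <- sum((hr - mu)^4) / n
  sk <- if (m2 > 0) m3 / m2^1.5 else 0
  ku <- if (m2 > 0) m4 / m2^2 - 3 else 0
  cent <- hr - mu
  zc <- 0
  for (i in 2:n) if (cent[i] * cent[i - 1] < 0) zc <- zc + 1
  c("RR-sdnn" = sdnn, "RR-pnn50" = pnn50, "RR-pnn20" = pnn20,
    "RR-rmssd" = rmssd, "HR-mean" = mu, "HR-median" = median(hr),
    "HR-std" = sqrt(sum((hr - mu)^2) / (n - 1)), "HR-max" = max(hr),
    "HR-min" = min(hr), "HR-p2p" = max(hr) - min(hr),
    "HR-kurtosis" = ku, "HR-skewness" = sk,
    "HR-mad" = median(abs(hr[-1] - hr[-n])), "HR-zcr" = zc / (n - 1))
}

# direct-sum DFT periodogram on the same cubic-spline resampled tachogram
oracle_freq_domain <- function(rr, beat_times, window_start_s,
                               window_len_s = 300, interp_hz = 4) {
  n_out <- round(window_len_s * interp_hz)
  xout <- window_start_s + (seq_len(n_out) - 1) / interp_hz
  xout <- pmin(pmax(xout, min(beat_times)), max(beat_times))
  x <- stats::spline(beat_times, rr, xout = xout, method = "fmm",
                     ties = mean)$y
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_out) - 1) / (n_out - 1))
  xw <- x * w
  ks <- seq_len(floor(n_out / 2))
  nidx <- 0:(n_out - 1)
  psd <- vapply(ks, function(k) {
    X <- sum(xw * exp(-2i * pi * k * nidx / n_out))
    2 * Mod(X)^2 / (interp_hz * sum(w^2))
  }, numeric(1))
  f <- ks * interp_hz / n_out
  trap <- function(lo, hi) {
    i <- which(f >= lo & f <= hi)
    s <- 0
    for (j in seq_along(i)[-1])
      s <- s + (f[i[j]] - f[i[j - 1]]) * (psd[i[j]] + psd[i[j - 1]]) / 2
    s
  }
  peak <- function(lo, hi) {
    i <- which(f >= lo & f <= hi)
    f[i][which.max(psd[i])]
  }
  vlf <- trap(0.0033, 0.04); lf <- trap(0.04, 0.15); hf <- trap(0.15, 0.40)
  c("RR-vlf-power" = vlf, "RR-lf-power" = lf, "RR-hf-power" = hf,
    "RR-total-power" = trap(0.0033, 0.40),
    "RR-lf-norm" = 100 * lf / (lf + hf), "RR-hf-norm" = 100 * hf / (lf + hf),
    "RR-lf-peak" = peak(0.04, 0.15), "RR-hf-peak" = peak(0.15, 0.40),
    "RR-lfhf-ratio" = 100 * lf / hf)
}

# O(n^2) template-counting sample entropy (m, Chebyshev tolerance r)
oracle_sampen <- function(x, m = 2, r) {
  n <- length(x)
  nm <- n - m
  A <- 0; B <- 0
  for (i in 1:(nm - 1)) {
    for (j in (i + 1):nm) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_nonlinear <- function(rr, r_factor = 0.2) {
  n <- length(rr)
  d <- rr[-1] - rr[-n]
  v0 <- function(x) sum((x - mean(x))^2) / length(x)
  sd1 <- sqrt(v0(d) / 2)
  sd2 <- sqrt(max(0, 2 * v0(rr) - v0(d) / 2))
  pat <- vapply(seq_len(n - 2), function(i) {
    paste(order(rr[i:(i + 2)]), collapse = "")
  }, character(1))
  p <- table(pat) / length(pat)
  pe <- -sum(p * log(p)) / log(6)
  c("RR-sd1" = sd1, "RR-sd2" = sd2, "RR-s-area" = pi * sd1 * sd2,
    "RR-sd-ratio" = if (sd2 > 0) sd1 / sd2 else NA_real_,
    "RR-sample-ent" = oracle_sampen(rr, 2, r_factor * sd(rr)),
    "RR-perm-ent" = pe)
}

# two-sided Fisher exact p by full hypergeometric enumeration (different
# code path from the package: explicit choose() products)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- vapply(support, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  d_obs <- dens[match(a, support)]
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

# random but physiologically shaped RR window for oracle comparisons
random_rr_window <- function(seed, n = 300, base = 900, sd = 40) {
  set.seed(seed)
  rr <- base + cumsum(rnorm(n, 0, 5)) + rnorm(n, 0, sd)
  rr <- pmin(2900, pmax(350, rr))
  bt <- cumsum(c(0, rr[-n])) / 1000
  list(rr_ms = rr, beat_times = bt)
}

# random RR series with planted slow stretches for detector tests
random_rr_series <- function(seed, n_beats = 10000) {
  set.seed(seed)
  rr <- runif(n_beats, 700, 1200)
  # plant slow stretches of random length 1..9 so both sub- and supra-
  # threshold runs occur
  k <- 0
  while (k < n_beats - 20) {
    k <- k + sample(50:400, 1)
    len <- sample(1:9, 1)
    if (k + len > n_beats) break
    rr[k:(k + len - 1)] <- runif(len, 1350, 1900)
  }
  rr_series(sprintf("rand%d", seed), cumsum(c(0, rr)) / 1000)
}

quiet_cfg <- function(...) analysis_config(...)

# tiny deterministic feature table for statistics tests
toy_feature_table <- function(n = 200, seed = 1) {
  set.seed(seed)
  ft <- data.frame(patient_id = "T1",
                   window_start_s = (seq_len(n) - 1) * 300,
                   clock_h = ((seq_len(n) - 1) * 300 / 3600) %% 24,
                   n_beats = 300,
                   glucose_mgdl = runif(n, 80, 240),
                   check.names = FALSE)
  cc <- clock_features(ft$clock_h)
  ft$c24_sin <- cc[, 1]; ft$c24_cos <- cc[, 2]
  for (f in hrv_feature_names()) ft[[f]] <- rnorm(n)
  ft$contains_brady_event <- FALSE
  ft
}
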