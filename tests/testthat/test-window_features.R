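cfg <- analysis_config()

test_that("a one-day record tiles into 288 half-open windows", {
  p <- sim_patient_params(rr_noise_sd_ms = 10)
  g <- simulate_glucose(p, 1, 1, "P1")
  rr <- simulate_rr(p, g, 2, "P1")
  rec <- patient_record(rr, g)
  win <- segment_windows(rec, NULL, cfg)
  expect_gte(nrow(win), 288)
  expect_lte(nrow(win), 289)  # a partial tail window may exist
  expect_equal(win$window_start_s[1:288], (0:287) * 300)

  # a beat at exactly t = 300 s starts an interval belonging to window 2
  rr2 <- rr_series("P1", c(0, 150, 300, 450, 600))
  g2 <- glucose_series("P1", c(0, 300, 600), c(100, 110, 120))
  win2 <- segment_windows(patient_record(rr2, g2), NULL, cfg)
  expect_equal(win2$interval_idx[[1]], 1:2)
  expect_equal(win2$interval_idx[[2]], 3:4)
})

test_that("an episode spanning a window boundary flags both windows", {
  rr <- rr_series("P1", cumsum(c(0, rep(0.8, 1000))))
  g <- glucose_series("P1", c(0, 300, 600), c(100, 110, 120))
  ep <- data.frame(start_s = 295, end_s = 305, n_beats = 7L, min_hr_bpm = 40)
  win <- segment_windows(patient_record(rr, g), ep, cfg)
  expect_true(win$contains_brady_event[1])
  expect_true(win$contains_brady_event[2])
  expect_false(any(win$contains_brady_event[-(1:2)]))
})

test_that("window cleaning drops artifacts and applies validity rules", {
  rr <- rep(1000, 300)
  rr[100] <- 5000
  bt <- cumsum(c(0, rr[-300])) / 1000
  cl <- clean_rr_window(rr, bt, cfg)
  expect_true(cl$valid)
  expect_equal(length(cl$rr_ms), 299)
  expect_true(all(cl$rr_ms <= 3000))

  expect_false(clean_rr_window(numeric(0), numeric(0), cfg)$valid)
  # 40% coverage -> invalid
  rr40 <- rep(1000, 120)
  expect_false(clean_rr_window(rr40, cumsum(c(0, rr40[-120])) / 1000,
                               cfg)$valid)
})

test_that("time-domain features match hand values on constructed windows", {
  td <- time_domain_features(rep(1000, 12))
  expect_equal(td[["RR-sdnn"]], 0)
  expect_equal(td[["RR-rmssd"]], 0)
  expect_equal(td[["RR-pnn50"]], 0)
  expect_equal(td[["HR-mean"]], 60)
  expect_equal(td[["HR-p2p"]], 0)

  td2 <- time_domain_features(c(1000, 1060, 1000, 1060), min_n = 4)
  expect_equal(td2[["RR-pnn50"]], 100)
  expect_equal(td2[["RR-rmssd"]], 60)
  # sample SD: 4 deviations of +/-30 around 1030, divided by n-1 = 3
  expect_equal(td2[["RR-sdnn"]], sqrt(1200), tolerance = 1e-12)

  expect_true(all(is.na(time_domain_features(rep(1000, 5)))))
})

test_that("all 29 features match straight-from-definition oracles", {
  for (seed in 1:30) {
    w <- random_rr_window(seed)
    got_td <- time_domain_features(w$rr_ms)
    expect_equal(got_td, oracle_time_domain(w$rr_ms), tolerance = 1e-9)
    got_fd <- frequency_domain_features(w$rr_ms, w$beat_times, 0)
    expect_equal(got_fd, oracle_freq_domain(w$rr_ms, w$beat_times, 0),
                 tolerance = 1e-9)
    got_nl <- nonlinear_features(w$rr_ms)
    expect_equal(got_nl, oracle_nonlinear(w$rr_ms), tolerance = 1e-9)
  }
})

test_that("spectral features recover a pure sinusoidal modulation", {
  t <- seq(0, 299, by = 0.9)
  rr <- 1000 + 50 * sin(2 * pi * 0.1 * t)
  fd <- frequency_domain_features(rr, t, 0)
  expect_lt(abs(fd[["RR-lf-peak"]] - 0.1), 1 / 300 + 1e-9)
  expect_gt(fd[["RR-lf-norm"]], 95)
  expect_equal(fd[["RR-lf-norm"]] + fd[["RR-hf-norm"]], 100)
  expect_gte(fd[["RR-total-power"]], fd[["RR-lf-power"]])

  const <- frequency_domain_features(rep(1000, 300),
                                     cumsum(rep(1, 300)) - 1, 0)
  expect_lt(const[["RR-total-power"]], 1e-15)
})

test_that("Poincare geometry satisfies its analytic identities", {
  # zero-mean successive differences: SD1 must equal RMSSD/sqrt(2) exactly
  rr <- c(1000, 1060, 1000, 1060, 1000)
  nl <- nonlinear_features(rr, min_n = 5)
  expect_equal(nl[["RR-sd1"]], 60 / sqrt(2), tolerance = 1e-12)
  td <- time_domain_features(rr, min_n = 5)
  expect_equal(nl[["RR-sd1"]], td[["RR-rmssd"]] / sqrt(2), tolerance = 1e-12)
  expect_equal(nl[["RR-s-area"]], pi * nl[["RR-sd1"]] * nl[["RR-sd2"]])

  inc <- seq(1000, 1100, by = 10)
  expect_equal(nonlinear_features(inc)[["RR-perm-ent"]], 0)
})

test_that("sample entropy equals the O(n^2) template-counting oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- 1000 + rnorm(50, 0, 30)
    r <- 0.2 * sd(x)
    expect_equal(bradyglucose:::sampen_cpp(x, 2L, r), oracle_sampen(x, 2, r),
                 tolerance = 1e-12)
  }
})

test_that("clock features encode the 24-hour phase", {
  expect_equal(clock_features(0), c(c24_sin = 0, c24_cos = 1))
  expect_equal(clock_features(6), c(c24_sin = 1, c24_cos = 0))
  expect_equal(clock_features(18), c(c24_sin = -1, c24_cos = 0))
  cc <- clock_features(runif(20, 0, 24))
  expect_equal(unname(cc[, 1]^2 + cc[, 2]^2), rep(1, 20))
})

test_that("feature table conserves windows and flags the episode window", {
  p <- sim_patient_params(brady_base_rate = 0, rr_noise_sd_ms = 15)
  g <- simulate_glucose(p, 1, 3, "P1")
  rr <- simulate_rr(p, g, 4, "P1")
  # plant one episode fully inside minute 47
  t0 <- 47 * 60
  keep <- rr$beat_times < t0 - 0.3 | rr$beat_times > t0 + 8 * 1.5 + 0.3
  beats <- sort(c(rr$beat_times[keep], t0 + (0:8) * 1.5))
  rec <- patient_record(rr_series("P1", beats), g)
  ep <- detect_bradycardia(rec$rr, cfg)
  expect_equal(nrow(ep), 1)
  ft <- build_feature_table(rec, list(P1 = ep), cfg)
  expect_equal(nrow(ft) + attr(ft, "n_invalid"), attr(ft, "n_windows_total"))
  flagged <- ft$window_start_s[ft$contains_brady_event]
  expect_equal(flagged, 45 * 60)
  # glucose is the matching grid slot sample
  expect_equal(ft$glucose_mgdl,
               g$glucose_mgdl[match(ft$window_start_s, g$timestamps)])
})

test_that("CGM imputation fills only short gaps", {
  v <- c(100, NA, NA, 130, NA, NA, NA, NA, 180, 190)
  g <- glucose_series("P1", (0:9) * 300, v)
  gi <- impute_glucose(g, max_gap_slots = 3)
  expect_equal(gi$glucose_mgdl[2:3], c(110, 120))
  expect_true(all(is.na(gi$glucose_mgdl[5:8])))
})

test_that("feature extraction is deterministic and patient-order invariant", {
  cohort <- simulate_cohort(2, cfg, seed = 21, days = 1)
  recs <- lapply(cohort, `[[`, "record")
  f12 <- build_feature_table(recs, config = cfg)
  f21 <- build_feature_table(rev(recs), config = cfg)
  a <- f12[order(f12$patient_id, f12$window_start_s), ]
  b <- f21[order(f21$patient_id, f21$window_start_s), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
})
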