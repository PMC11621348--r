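cfg <- analysis_config()

test_that("glucose simulator reproduces the closed-form circadian profile", {
  p <- sim_patient_params(glucose_mesor = 150, glucose_amplitude = 0,
                          glucose_noise_sd = 0)
  g <- simulate_glucose(p, 2, 1)
  expect_true(all(g$glucose_mgdl == 150))
  expect_equal(length(g$glucose_mgdl), 2 * 288)

  p2 <- sim_patient_params(glucose_mesor = 150, glucose_amplitude = 40,
                           glucose_acrophase_h = 15, glucose_noise_sd = 0)
  g2 <- simulate_glucose(p2, 3, 1)
  hour <- floor((g2$timestamps / 3600) %% 24)
  prof <- tapply(g2$glucose_mgdl, hour, mean)
  expect_equal(as.integer(names(prof)[which.max(prof)]), 15)

  expect_error(simulate_glucose(sim_patient_params(glucose_mesor = 1000,
                                                   glucose_amplitude = 0,
                                                   glucose_noise_sd = 0),
                                1, 1), "all-clipped")
})

test_that("simulators are deterministic in the seed", {
  p <- sim_patient_params()
  expect_identical(simulate_glucose(p, 1, 42)$glucose_mgdl,
                   simulate_glucose(p, 1, 42)$glucose_mgdl)
  g <- simulate_glucose(p, 1, 42)
  expect_identical(simulate_rr(p, g, 7)$beat_times,
                   simulate_rr(p, g, 7)$beat_times)
  expect_false(identical(simulate_rr(p, g, 7)$beat_times,
                         simulate_rr(p, g, 8)$beat_times))
})

test_that("noise-free RR stream at 60 bpm is a 1000-ms metronome", {
  p <- sim_patient_params(hr_mesor = 60, hr_amplitude = 0, rr_lf_mod_ms = 0,
                          rr_hf_mod_ms = 0, rr_noise_sd_ms = 0)
  g <- simulate_glucose(p, 1, 1)
  rr <- simulate_rr(p, g, 2)
  expect_true(all(abs(rr$rr_ms - 1000) <= 1))
})

test_that("pure 0.1-Hz RR modulation is recovered as the LF band peak", {
  p <- sim_patient_params(hr_mesor = 70, hr_amplitude = 0, rr_lf_mod_ms = 50,
                          rr_hf_mod_ms = 0, rr_noise_sd_ms = 0)
  g <- simulate_glucose(p, 1, 1)
  rr <- simulate_rr(p, g, 3)
  i <- which(rr$beat_times[-length(rr$beat_times)] >= 600 &
               rr$beat_times[-length(rr$beat_times)] < 900)
  fd <- frequency_domain_features(rr$rr_ms[i], rr$beat_times[i], 600)
  expect_lt(abs(fd[["RR-lf-peak"]] - 0.1), 0.025)
  expect_gt(fd[["RR-lf-norm"]], 95)
})

test_that("injection respects rate zero and stays detector-consistent", {
  p <- sim_patient_params(brady_base_rate = 0)
  g <- simulate_glucose(p, 1, 1)
  rr <- simulate_rr(p, g, 2)
  out <- inject_bradycardia(rr, g, p, compute_tertile_bounds(g), 3, cfg)
  expect_identical(out$rr$beat_times, rr$beat_times)
  expect_equal(nrow(out$truth), 0)

  p2 <- sim_patient_params(brady_base_rate = 2, brady_nocturnal_mult = 1,
                           pre_episode_hr_drift_bpm = 0)
  out2 <- inject_bradycardia(rr, g, p2, compute_tertile_bounds(g), 4, cfg)
  expect_gt(nrow(out2$truth), 10)
  # every injected run must be recovered by the detector
  ep <- detect_bradycardia(out2$rr, cfg)
  for (i in seq_len(nrow(out2$truth))) {
    hit <- ep$start_s < out2$truth$end_s[i] & ep$end_s > out2$truth$start_s[i]
    expect_true(any(hit), info = paste("run", i))
    expect_gte(max(ep$n_beats[hit]), out2$truth$n_beats[i])
  }
  # truth intervals are non-overlapping and ordered
  expect_true(all(diff(out2$truth$start_s) > 0))
  expect_true(all(out2$truth$start_s[-1] >= out2$truth$end_s[-nrow(out2$truth)]))
})

test_that("low-tertile odds multiply the injection intensity as configured", {
  counts <- c(low = 0, high = 0)
  hours <- c(low = 0, high = 0)
  for (i in 1:6) {
    p <- sim_patient_params(brady_base_rate = 1.2, brady_odds_low = 3,
                            brady_odds_high = 1, brady_nocturnal_mult = 1,
                            pre_episode_hr_drift_bpm = 0)
    g <- simulate_glucose(p, 3, 100 + i)
    rr <- simulate_rr(p, g, 200 + i)
    bounds <- compute_tertile_bounds(g)
    out <- inject_bradycardia(rr, g, p, bounds, 300 + i, cfg)
    tert <- assign_tertile(g$glucose_mgdl, bounds)
    hours["low"] <- hours["low"] + sum(tert == "low", na.rm = TRUE) / 12
    hours["high"] <- hours["high"] + sum(tert == "high", na.rm = TRUE) / 12
    counts["low"] <- counts["low"] + sum(out$truth$tertile == "low")
    counts["high"] <- counts["high"] + sum(out$truth$tertile == "high")
  }
  rate_ratio <- (counts["low"] / hours["low"]) / (counts["high"] / hours["high"])
  expect_gt(rate_ratio, 2)
  expect_lt(rate_ratio, 4.5)
})

test_that("infeasibly high injection rates error instead of overlapping", {
  p <- sim_patient_params(brady_base_rate = 500)
  g <- simulate_glucose(p, 1, 1)
  rr <- simulate_rr(p, g, 2)
  expect_error(inject_bradycardia(rr, g, p, compute_tertile_bounds(g), 3, cfg),
               "too high")
})

test_that("cohorts are reproducible and heterogeneous between patients", {
  c1 <- simulate_cohort(3, cfg, seed = 9, days = 1)
  c2 <- simulate_cohort(3, cfg, seed = 9, days = 1)
  expect_identical(lapply(c1, function(p) p$record$rr$beat_times),
                   lapply(c2, function(p) p$record$rr$beat_times))
  expect_identical(lapply(c1, function(p) p$truth),
                   lapply(c2, function(p) p$truth))
  # adding a patient does not perturb existing ones
  c4 <- simulate_cohort(4, cfg, seed = 9, days = 1)
  expect_identical(c4[[2]]$record$rr$beat_times, c1[[2]]$record$rr$beat_times)

  means <- vapply(simulate_cohort(20, cfg, seed = 5, days = 1),
                  function(p) mean(p$record$glucose$glucose_mgdl, na.rm = TRUE),
                  numeric(1))
  expect_gt(diff(range(means)), 30)
})
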