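cfg <- analysis_config()

mk_table <- function(starts, id = "P1") {
  ft <- data.frame(patient_id = id, window_start_s = starts,
                   clock_h = (starts / 3600) %% 24, n_beats = 300,
                   glucose_mgdl = 120, check.names = FALSE)
  cc <- clock_features(ft$clock_h)
  ft$c24_sin <- cc[, 1]; ft$c24_cos <- cc[, 2]
  for (f in hrv_feature_names()) ft[[f]] <- 0
  ft$contains_brady_event <- FALSE
  ft
}

test_that("zone labeling implements the risk/normal/excluded rules", {
  ft <- mk_table((0:19) * 300)
  # one episode group at t = 47.5 min
  g <- data.frame(start_s = 47.5 * 60, end_s = 47.5 * 60 + 12,
                  episode_count = 1L)
  lab <- label_windows(ft, list(P1 = g), cfg)
  zone <- setNames(lab$zone, lab$window_start_s / 60)
  expect_equal(unname(zone["45"]), "excluded")  # contains the group
  expect_equal(unname(zone["40"]), "risk")      # ends 150 s before onset
  expect_equal(unname(zone["50"]), "excluded")  # within the buffer after it
  expect_equal(unname(zone["35"]), "normal")
  expect_equal(unname(zone["55"]), "normal")

  # no episodes -> everything normal
  lab0 <- label_windows(ft, list(P1 = g[0, ]), cfg)
  expect_true(all(lab0$zone == "normal"))
})

test_that("labeling partitions every window on random synthetic patients", {
  for (seed in 1:5) {
    p <- sim_patient_params(brady_base_rate = 1, brady_nocturnal_mult = 1,
                            pre_episode_hr_drift_bpm = 0)
    g <- simulate_glucose(p, 1, seed, "Px")
    rr <- simulate_rr(p, g, seed + 50, "Px")
    inj <- inject_bradycardia(rr, g, p, compute_tertile_bounds(g),
                              seed + 100, cfg)
    rec <- patient_record(inj$rr, g)
    ep <- detect_bradycardia(rec$rr, cfg)
    ft <- build_feature_table(rec, list(Px = ep), cfg, compute = "labels")
    grp <- group_episodes(ep, cfg)
    lab <- label_windows(ft, list(Px = grp), cfg)
    expect_true(all(lab$zone %in% c("risk", "normal", "excluded")))
    # every episode-containing window is excluded
    expect_true(all(lab$zone[lab$contains_brady_event] == "excluded"))
    # each group start is preceded by one risk window (when it is clean)
    risk_starts <- lab$window_start_s[lab$zone == "risk"]
    for (k in seq_len(nrow(grp))) {
      w_end <- risk_starts + cfg$window_len_s
      lead <- grp$start_s[k] - w_end
      in_lead <- lead >= 0 & lead < cfg$risk_lead_s
      expect_lte(sum(in_lead), 1)
    }
    # normal windows keep their distance from every group
    normal <- lab[lab$zone == "normal", ]
    for (k in seq_len(nrow(grp))) {
      gap <- pmax(grp$start_s[k] - (normal$window_start_s + cfg$window_len_s),
                  normal$window_start_s - grp$end_s[k])
      expect_true(all(gap > cfg$normal_buffer_s))
    }
    # idempotence
    expect_identical(label_windows(lab, list(Px = grp), cfg)$zone, lab$zone)
  }
})

test_that("z-scoring normalizes per patient and is shift-invariant", {
  ft <- rbind(toy_feature_table(50, 1), {
    t2 <- toy_feature_table(50, 2); t2$patient_id <- "T2"; t2
  })
  z <- zscore_per_patient(ft)
  for (p in c("T1", "T2")) {
    v <- z[["RR-sdnn"]][z$patient_id == p]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  # clock features pass through untouched
  expect_identical(z$c24_sin, ft$c24_sin)
  # shifting one patient's feature leaves its normalized column unchanged
  ft2 <- ft
  ft2[["RR-sdnn"]][ft2$patient_id == "T1"] <-
    ft[["RR-sdnn"]][ft$patient_id == "T1"] + 100
  z2 <- zscore_per_patient(ft2)
  expect_equal(z2[["RR-sdnn"]], z[["RR-sdnn"]], tolerance = 1e-9)
  # idempotence
  z3 <- zscore_per_patient(z)
  expect_equal(z3[["RR-sdnn"]], z[["RR-sdnn"]], tolerance = 1e-9)
  # zero-variance features become 0; single-window patients error
  ft$glucose_mgdl <- 120
  expect_true(all(zscore_per_patient(ft)$glucose_mgdl == 0))
  expect_error(zscore_per_patient(ft[1, ]), "single window")
})

test_that("a perfectly separable shift yields near-perfect CV performance", {
  set.seed(30)
  ft <- toy_feature_table(700)
  ft$zone <- c(rep("risk", 100), rep("normal", 600))
  ft[["HR-min"]] <- rnorm(700) - 8 * (ft$zone == "risk")
  small <- analysis_config(cv_iterations = 5, rf_num_trees = 100)
  rep1 <- balanced_cv_evaluate(ft, small, seed = 3)
  expect_gte(rep1$summary$mean[rep1$summary$metric == "auc"], 0.99)
  # determinism
  rep2 <- balanced_cv_evaluate(ft, small, seed = 3)
  expect_identical(rep1$iterations, rep2$iterations)
  expect_identical(rep1$importances, rep2$importances)
  # importances normalized per iteration
  expect_equal(unname(rowSums(rep1$importances)), rep(1, 5), tolerance = 1e-9)
  # the discriminative feature dominates the ranking
  imp <- feature_importance_summary(rep1)
  expect_equal(imp$feature[1], "HR-min")

  expect_error(balanced_cv_evaluate(ft[ft$zone == "normal", ], small, 1),
               "risk windows")
})

test_that("permuted labels give chance-level AUC", {
  set.seed(31)
  ft <- toy_feature_table(800)
  ft$zone <- sample(c(rep("risk", 120), rep("normal", 680)))
  small <- analysis_config(cv_iterations = 4, rf_num_trees = 60)
  aucs <- vapply(1:4, function(s) {
    r <- balanced_cv_evaluate(ft, small, seed = s)
    r$summary$mean[r$summary$metric == "auc"]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("precision-recall curve is exact in the separable and random cases", {
  pooled <- data.frame(score = c(runif(50, 0.8, 1), runif(200, 0, 0.5)),
                       is_risk = c(rep(TRUE, 50), rep(FALSE, 200)))
  pr <- precision_recall_curve(pooled)
  expect_equal(pr$area, 1)
  expect_true(all(diff(pr$curve$recall) >= 0))

  set.seed(8)
  areas <- vapply(1:30, function(i) {
    pooled <- data.frame(score = runif(400),
                         is_risk = c(rep(TRUE, 100), rep(FALSE, 300)))
    precision_recall_curve(pooled)$area
  }, numeric(1))
  expect_lt(abs(mean(areas) - 0.25), 0.03)  # prevalence of the risk class

  expect_error(precision_recall_curve(
    data.frame(score = runif(5), is_risk = rep(TRUE, 5))), "single class")
})
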