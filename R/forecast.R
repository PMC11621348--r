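#' Label risk, normal and excluded windows
#'
#' Forecasting labels relative to merged episode groups: windows containing
#' an episode are `excluded` (predicting them has no forecasting value);
#' a non-excluded window ending within `risk_lead_s` before a group start is
#' `risk`; non-excluded windows whose gap to every group exceeds
#' `normal_buffer_s` on both sides are `normal`; the remaining near-event
#' windows are also `excluded` so neither class leaks event context.
#'
#' @param table Feature table rows of one or more patients.
#' @param groups Named list (by patient id) of group `data.frame`s from
#'   [group_episodes()] (a single `data.frame` is accepted for a one-patient
#'   table).
#' @param config An [analysis_config()].
#' @return The table with a `zone` column (`"risk"`, `"normal"`,
#'   `"excluded"`).
#' @export
label_windows <- function(table, groups, config = analysis_config()) {
  if (is.data.frame(groups)) {
    pts <- unique(table$patient_id)
    stopifnot(length(pts) == 1)
    groups <- stats::setNames(list(groups), pts)
  }
  L <- config$window_len_s
  table$zone <- "normal"
  for (p in unique(table$patient_id)) {
    i <- which(table$patient_id == p)
    g <- groups[[p]]
    if (is.null(g) || nrow(g) == 0) next
    ws <- table$window_start_s[i]
    we <- ws + L
    zone <- rep("normal", length(i))
    for (k in seq_len(nrow(g))) {
      gs <- g$start_s[k]; ge <- g$end_s[k]
      overlap <- gs < we & ge > ws
      zone[overlap] <- "excluded"
      lead <- gs - we
      zone[!overlap & zone != "excluded" & lead >= 0 &
             lead < config$risk_lead_s & zone != "risk"] <- "risk"
      gap <- pmax(gs - we, ws - ge)
      near <- !overlap & gap <= config$normal_buffer_s
      zone[near & zone == "normal"] <- "near"
    }
    zone[zone == "near"] <- "excluded"
    # a window can be risk for one group yet near another; risk wins only if
    # it is not itself contaminated by an overlapping episode
    table$zone[i] <- zone
  }
  table
}

forecast_predictors <- function() {
  c(hrv_feature_names(), "glucose_mgdl", "c24_sin", "c24_cos")
}

#' Per-patient z-scoring of features
#'
#' Subtracts each patient's mean and divides by the patient's SD for every
#' HRV feature and the glucose column; zero-variance columns become 0. Clock
#' features (already bounded) and labels pass through untouched.
#'
#' @param table Labeled feature table.
#' @param columns Columns to scale.
#' @return The table with scaled columns.
#' @export
zscore_per_patient <- function(table,
                               columns = c(hrv_feature_names(),
                                           "glucose_mgdl")) {
  for (p in unique(table$patient_id)) {
    i <- which(table$patient_id == p)
    if (length(i) < 2)
      stop("patient ", p, " has a single window; cannot z-score",
           call. = FALSE)
    for (cn in columns) {
      v <- table[[cn]][i]
      mu <- mean(v, na.rm = TRUE)
      s <- stats::sd(v, na.rm = TRUE)
      table[[cn]][i] <- if (is.na(s) || s == 0) ifelse(is.na(v), NA, 0)
                        else (v - mu) / s
    }
  }
  table
}

rank_auc <- function(scores, labels) {
  # labels logical: TRUE = positive class
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- scores >= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(accuracy = mean(pred == labels), auc = rank_auc(scores, labels),
    precision = precision, recall = recall, f1 = f1)
}

#' Balanced bootstrap Random-Forest cross-validation
#'
#' Handles the heavy class imbalance between risk and normal windows: each
#' of `cv_iterations` iterations draws, without replacement, a normal-window
#' sample of the same size as the (fixed) risk class, then evaluates a
#' Random-Forest classifier by stratified `cv_folds`-fold cross-validation
#' on the balanced set. Fold-mean accuracy, ROC-AUC, precision, recall and
#' F1 are recorded per iteration and aggregated as mean +/- SD; impurity
#' (Gini) feature importances are collected per iteration (normalized to sum
#' to 1); out-of-fold scores are pooled for the precision-recall curve.
#'
#' @param table Labeled (and normally z-scored) feature table with a `zone`
#'   column.
#' @param config An [analysis_config()].
#' @param seed Integer seed; the report is a pure function of
#'   `(table, config, seed)`.
#' @param predictors Predictor columns (default: 29 HRV features, glucose,
#'   clock features).
#' @return An object of class `cv_report`: `iterations` (per-iteration
#'   metrics), `summary` (mean and SD per metric), `importances`
#'   (iterations x features matrix), `pooled_scores` (out-of-fold scores and
#'   labels) and `settings`.
#' @export
balanced_cv_evaluate <- function(table, config = analysis_config(),
                                 seed = config$rng_seed,
                                 predictors = forecast_predictors()) {
  stopifnot("zone" %in% names(table))
  use <- table$zone %in% c("risk", "normal")
  dat <- table[use, c(predictors, "zone")]
  complete <- stats::complete.cases(dat[predictors])
  n_dropped <- sum(!complete)
  dat <- dat[complete, ]
  risk <- dat[dat$zone == "risk", ]
  normal <- dat[dat$zone == "normal", ]
  n_risk <- nrow(risk)
  if (n_risk < config$cv_folds)
    stop("fewer risk windows (", n_risk, ") than folds (", config$cv_folds,
         ")", call. = FALSE)
  if (nrow(normal) < n_risk)
    stop("fewer normal than risk windows; cannot undersample", call. = FALSE)

  metrics <- c("accuracy", "auc", "precision", "recall", "f1")
  iter_rows <- matrix(NA_real_, config$cv_iterations, length(metrics),
                      dimnames = list(NULL, metrics))
  importances <- matrix(NA_real_, config$cv_iterations, length(predictors),
                        dimnames = list(NULL, predictors))
  pooled <- vector("list", config$cv_iterations)

  for (it in seq_len(config$cv_iterations)) {
    res <- with_seed(derive_seed(seed, "cv", it), {
      ns <- normal[sample.int(nrow(normal), n_risk), ]
      X <- rbind(risk[predictors], ns[predictors])
      names(X) <- make.names(names(X))
      y <- factor(rep(c("risk", "normal"), each = n_risk),
                  levels = c("normal", "risk"))
      fold <- integer(nrow(X))
      for (cls in levels(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(config$cv_folds), length(idx)))
      }
      fold_m <- matrix(NA_real_, config$cv_folds, length(metrics))
      imp <- numeric(length(predictors))
      sc <- numeric(0); lb <- logical(0)
      for (k in seq_len(config$cv_folds)) {
        tr <- fold != k
        fit <- randomForest::randomForest(
          x = X[tr, , drop = FALSE], y = y[tr],
          ntree = config$rf_num_trees)
        prob <- stats::predict(fit, X[!tr, , drop = FALSE],
                               type = "prob")[, "risk"]
        lab <- y[!tr] == "risk"
        fold_m[k, ] <- binary_metrics(prob, lab)
        imp <- imp + fit$importance[, "MeanDecreaseGini"]
        sc <- c(sc, prob); lb <- c(lb, lab)
      }
      list(m = colMeans(fold_m, na.rm = TRUE),
           imp = if (sum(imp) > 0) imp / sum(imp) else imp,
           scores = sc, labels = lb)
    })
    iter_rows[it, ] <- res$m
    importances[it, ] <- res$imp
    pooled[[it]] <- data.frame(iteration = it, score = res$scores,
                               is_risk = res$labels)
  }
  summary <- data.frame(metric = metrics,
                        mean = colMeans(iter_rows, na.rm = TRUE),
                        sd = apply(iter_rows, 2, stats::sd, na.rm = TRUE))
  rownames(summary) <- NULL
  structure(list(iterations = as.data.frame(iter_rows), summary = summary,
                 importances = importances,
                 pooled_scores = do.call(rbind, pooled),
                 settings = list(n_risk = n_risk, n_normal = nrow(normal),
                                 n_dropped_na = n_dropped,
                                 cv_iterations = config$cv_iterations,
                                 cv_folds = config$cv_folds,
                                 rf_num_trees = config$rf_num_trees,
                                 seed = seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$settings$cv_iterations, "iterations of balanced",
      x$settings$cv_folds, "-fold CV;", x$settings$n_risk,
      "risk windows vs", x$settings$n_normal, "normal\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Precision-recall curve of the pooled out-of-fold scores
#'
#' Sweeps descending score thresholds over the pooled out-of-fold
#' predictions and integrates the area stepwise (average-precision style:
#' precision at each threshold weighted by the recall increment).
#'
#' @param report A `cv_report`, or a `data.frame` with columns `score` and
#'   `is_risk`.
#' @return List with `curve` (a `data.frame` of threshold, precision,
#'   recall) and `area`.
#' @export
precision_recall_curve <- function(report) {
  scores <- if (inherits(report, "cv_report")) report$pooled_scores else report
  if (length(unique(scores$is_risk)) < 2)
    stop("pooled scores contain a single class", call. = FALSE)
  o <- order(scores$score, decreasing = TRUE)
  y <- scores$is_risk[o]
  s <- scores$score[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  n_pos <- sum(y)
  # evaluate at the last index of each distinct score
  last <- which(diff(s) != 0)
  idx <- c(last, length(s))
  precision <- tp[idx] / (tp[idx] + fp[idx])
  recall <- tp[idx] / n_pos
  area <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = s[idx], precision = precision,
                          recall = recall),
       area = area)
}

#' Rank features by Random-Forest importance
#'
#' Median and interquartile range of each feature's normalized impurity
#' importance across the CV iterations, ranked by median.
#'
#' @param report A `cv_report`.
#' @return `data.frame` with `feature`, `median`, `q25`, `q75`, sorted
#'   decreasingly by median.
#' @export
feature_importance_summary <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  imp <- report$importances
  out <- data.frame(feature = colnames(imp),
                    median = apply(imp, 2, stats::median, na.rm = TRUE),
                    q25 = apply(imp, 2, stats::quantile, 0.25, na.rm = TRUE),
                    q75 = apply(imp, 2, stats::quantile, 0.75, na.rm = TRUE))
  out <- out[order(-out$median), ]
  rownames(out) <- NULL
  out
}
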