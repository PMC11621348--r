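#' Mann-Whitney comparison of bradycardia frequencies across tertiles
#'
#' Two-sided U tests for the three pairwise comparisons of per-patient
#' bradycardia event frequencies (low vs medium, low vs high, medium vs
#' high). The exact distribution is used up to a combined sample size of
#' `config$exact_u_max_n` (and no ties); beyond that, the normal
#' approximation with tie correction.
#'
#' @param freqs `data.frame` with columns `patient_id`, `low`, `medium`,
#'   `high`: per-patient event counts (or rates) in each tertile. See
#'   [tertile_event_frequencies()].
#' @param config An [analysis_config()].
#' @return `data.frame` with `comparison`, `U`, `p_value`.
#' @export
mannwhitney_tertile_comparison <- function(freqs, config = analysis_config()) {
  pairs <- list(c("low", "medium"), c("low", "high"), c("medium", "high"))
  out <- lapply(pairs, function(pr) {
    x <- freqs[[pr[1]]]; y <- freqs[[pr[2]]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y))
      stop("empty group in comparison ", pr[1], " vs ", pr[2], call. = FALSE)
    exact <- (length(x) + length(y)) <= config$exact_u_max_n &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact))
    data.frame(comparison = paste0(pr[1], "_vs_", pr[2]),
               U = unname(wt$statistic), p_value = wt$p.value)
  })
  do.call(rbind, out)
}

#' Per-patient bradycardia event frequencies by tertile
#'
#' Counts each patient's bradycardia-containing windows per relative glucose
#' tertile, the unit compared across tertiles by
#' [mannwhitney_tertile_comparison()].
#'
#' @param table Annotated feature table (with `tertile`).
#' @return `data.frame` with `patient_id`, `low`, `medium`, `high`.
#' @export
tertile_event_frequencies <- function(table) {
  stopifnot("tertile" %in% names(table))
  b <- table[table$contains_brady_event & !is.na(table$tertile), ]
  pts <- unique(table$patient_id)
  tab <- table(factor(b$patient_id, levels = pts),
               factor(b$tertile, levels = c("low", "medium", "high")))
  data.frame(patient_id = pts, low = as.integer(tab[, "low"]),
             medium = as.integer(tab[, "medium"]),
             high = as.integer(tab[, "high"]))
}

fisher_two_sided_p <- function(a, b, c, d) {
  # two-sided Fisher exact p by summing hypergeometric point probabilities
  # no larger than the observed one (relative tolerance 1e-7)
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  d_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

#' Direction-signed Fisher exact statistic
#'
#' Two-sided Fisher exact p value of a 2x2 contingency table (rows:
#' bradycardia / non-bradycardia windows; columns: in-tertile / not),
#' transformed to `-log10(p)` and signed by the deviation of the observed
#' top-left count from its fixed-margin expectation `row1 * col1 / total`.
#' Positive values mean enrichment of bradycardia in the tertile, negative
#' depletion; a table with p = 1 (or a zero margin) scores 0.
#'
#' @param table 2x2 matrix of non-negative counts, or the four counts
#'   `a, b, c, d` (row-wise).
#' @param a,b,c,d Alternative scalar interface.
#' @return List with `statistic` (signed `-log10 p`), `p_value`,
#'   `direction` (-1, 0, +1).
#' @export
fisher_signed <- function(table = NULL, a = NULL, b = NULL, c = NULL, d = NULL) {
  if (!is.null(table)) {
    stopifnot(length(table) == 4)
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) == 0)
    stop("contingency table needs non-negative counts and a positive total",
         call. = FALSE)
  n <- a + b + c + d
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    warning("zero margin in contingency table; statistic set to 0")
    return(list(statistic = 0, p_value = 1, direction = 0L))
  }
  p <- fisher_two_sided_p(a, b, c, d)
  expected_a <- (a + b) * (a + c) / n
  dir <- sign(a - expected_a)
  stat <- if (p >= 1) 0 else -log10(p) * dir
  list(statistic = stat, p_value = min(p, 1), direction = as.integer(dir))
}

timeband_of <- function(clock_h, band_h = 3) floor((clock_h %% 24) / band_h)

timeband_label <- function(band, band_h = 3) {
  sprintf("%02d:00-%02d:00", band * band_h, (band + 1) * band_h)
}

#' Bootstrap Fisher enrichment of bradycardia by time band and tertile
#'
#' For each 3-hour clock band and each extreme tertile (low, high): the
#' band's windows are resampled with replacement at original size
#' `n_boot_fisher` times; each replicate forms the 2x2 table (bradycardia vs
#' non-bradycardia windows x in-tertile vs not) and contributes one
#' [fisher_signed()] statistic. Positive medians indicate bradycardia
#' enrichment in that tertile and band.
#'
#' @param table Annotated feature table (needs `tertile`,
#'   `contains_brady_event`, `clock_h`).
#' @param config An [analysis_config()].
#' @param seed Integer seed; the full set of replicates is reproducible.
#' @return `data.frame` with one row per stratum: `band`, `band_label`,
#'   `tertile`, `n_windows`, `n_brady`, `reliable`, `median`, `q025`, `q975`,
#'   and a list column `samples` of the signed statistics.
#' @export
bootstrap_fisher_by_timeband <- function(table, config = analysis_config(),
                                         seed = config$rng_seed) {
  stopifnot("tertile" %in% names(table))
  use <- !is.na(table$tertile)
  tab <- table[use, c("clock_h", "tertile", "contains_brady_event")]
  tab$band <- timeband_of(tab$clock_h, config$timeband_h)
  bands <- 0:(24 / config$timeband_h - 1)
  rows <- list()
  for (band in bands) {
    w <- tab[tab$band == band, ]
    for (side in c("low", "high")) {
      s <- derive_seed(seed, "fisher", band, side)
      n <- nrow(w)
      samples <- if (n >= 2) with_seed(s, {
        vapply(seq_len(config$n_boot_fisher), function(it) {
          i <- sample.int(n, n, replace = TRUE)
          brady <- w$contains_brady_event[i]
          int <- w$tertile[i] == side
          suppressWarnings(fisher_signed(a = sum(brady & int),
                                         b = sum(brady & !int),
                                         c = sum(!brady & int),
                                         d = sum(!brady & !int))$statistic)
        }, numeric(1))
      }) else rep(NA_real_, config$n_boot_fisher)
      q <- stats::quantile(samples, c(0.5, 0.025, 0.975), na.rm = TRUE,
                           names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        band = band, band_label = timeband_label(band, config$timeband_h),
        tertile = side, n_windows = n,
        n_brady = sum(w$contains_brady_event),
        reliable = n >= config$timeband_min_windows,
        median = q[1], q025 = q[2], q975 = q[3])
      rows[[length(rows)]]$samples <- list(samples)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap Wilcoxon rank-sum significance of HRV features
#'
#' Windows with and without bradycardia are compared feature by feature.
#' Because the classes are heavily imbalanced, each of `n_boot_wilcoxon`
#' iterations draws `wilcoxon_sample_n` windows per class *without*
#' replacement, runs a two-sided rank-sum test per feature, and records
#' `-log10(p)` signed by the difference of class means (bradycardia minus
#' non-bradycardia). If a class is smaller than the sample size, the draw
#' shrinks to the smaller class with a warning.
#'
#' @param table Feature table with computed HRV features.
#' @param config An [analysis_config()].
#' @param seed Integer seed.
#' @param features Feature columns to test (default all 29).
#' @return `data.frame` with one row per feature: `feature`, `median`,
#'   `q025`, `q975` and list column `samples`.
#' @export
wilcoxon_hrv_bootstrap <- function(table, config = analysis_config(),
                                   seed = config$rng_seed,
                                   features = hrv_feature_names()) {
  brady <- table[table$contains_brady_event, , drop = FALSE]
  normal <- table[!table$contains_brady_event, , drop = FALSE]
  n_draw <- min(config$wilcoxon_sample_n, nrow(brady), nrow(normal))
  if (n_draw < 2)
    stop("need at least 2 windows in each class", call. = FALSE)
  if (n_draw < config$wilcoxon_sample_n)
    warning("class smaller than wilcoxon_sample_n; drawing ", n_draw,
            " windows per class")
  samples <- with_seed(derive_seed(seed, "wilcoxon"), {
    replicate(config$n_boot_wilcoxon, {
      bi <- brady[sample.int(nrow(brady), n_draw), features, drop = FALSE]
      ni <- normal[sample.int(nrow(normal), n_draw), features, drop = FALSE]
      vapply(features, function(f) {
        x <- bi[[f]]; y <- ni[[f]]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2 || length(y) < 2) return(NA_real_)
        p <- suppressWarnings(
          stats::wilcox.test(x, y, exact = FALSE)$p.value)
        if (is.na(p)) return(NA_real_)
        s <- sign(mean(x) - mean(y))
        if (p >= 1) 0 else -log10(p) * s
      }, numeric(1))
    })
  })
  samples <- matrix(samples, nrow = length(features))
  out <- data.frame(
    feature = features,
    median = apply(samples, 1, stats::median, na.rm = TRUE),
    q025 = apply(samples, 1, stats::quantile, 0.025, na.rm = TRUE),
    q975 = apply(samples, 1, stats::quantile, 0.975, na.rm = TRUE))
  out$samples <- lapply(seq_len(nrow(samples)), function(i) samples[i, ])
  rownames(out) <- NULL
  out
}

#' Hourly heart rate vs glucose correlation
#'
#' Averages each patient's window-level mean heart rate (`HR-mean`) and
#' glucose within each clock hour, averages those profiles across patients
#' (24 pairs), and reports the Pearson correlation of the two daily
#' profiles with its two-sided p value and per-hour 95% confidence
#' intervals across patients.
#'
#' @param table Feature table with `HR-mean`, `glucose_mgdl`, `clock_h`.
#' @return List with `r`, `p_value`, `n_hours`, and `profile` (a
#'   `data.frame` with hourly means and CI bounds).
#' @export
hourly_hr_glucose_correlation <- function(table) {
  hr_col <- table[["HR-mean"]]
  hour <- floor(table$clock_h) %% 24
  per <- stats::aggregate(
    cbind(hr = hr_col, glucose = table$glucose_mgdl),
    by = list(patient_id = table$patient_id, hour = hour),
    FUN = mean, na.rm = TRUE)
  ci <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2) return(c(mean(v), NA, NA))
    se <- stats::sd(v) / sqrt(n)
    mean(v) + c(0, -1, 1) * c(0, rep(stats::qt(0.975, n - 1) * se, 2))
  }
  hours <- sort(unique(per$hour))
  prof <- do.call(rbind, lapply(hours, function(h) {
    x <- per[per$hour == h, ]
    hr <- ci(x$hr); gl <- ci(x$glucose)
    data.frame(hour = h, hr_mean = hr[1], hr_lo = hr[2], hr_hi = hr[3],
               glucose_mean = gl[1], glucose_lo = gl[2], glucose_hi = gl[3])
  }))
  ok <- !is.na(prof$hr_mean) & !is.na(prof$glucose_mean)
  if (sum(ok) < 3)
    stop("need at least 3 hourly bins with data", call. = FALSE)
  ct <- stats::cor.test(prof$hr_mean[ok], prof$glucose_mean[ok],
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_hours = sum(ok),
       profile = prof)
}

#' Shares of bradycardia events by glucose category
#'
#' Percentages of bradycardia-containing windows per relative tertile
#' (overall and within 3-hour clock bands), the tertile occupancy of all
#' windows per band, and the shares by absolute glucose category
#' (< 70, 70-180, > 180 mg/dL).
#'
#' @param table Annotated feature table.
#' @param band_h Clock band width in hours.
#' @return List with `overall_pct` (per tertile), `absolute_pct` (per
#'   absolute category), `band_window_pct` and `band_brady_pct`
#'   (band x tertile matrices, rows summing to 100 where data exist).
#' @export
tertile_event_shares <- function(table, band_h = 3) {
  stopifnot("tertile" %in% names(table))
  lev <- c("low", "medium", "high")
  pct <- function(f) {
    t <- table(factor(f, levels = lev))
    if (sum(t) == 0) return(stats::setNames(rep(NA_real_, 3), lev))
    stats::setNames(100 * as.numeric(t) / sum(t), lev)
  }
  brady <- table$contains_brady_event & !is.na(table$tertile)
  overall <- pct(table$tertile[brady])
  g <- table$glucose_mgdl[table$contains_brady_event & !is.na(table$glucose_mgdl)]
  abs_cat <- cut(g, c(-Inf, 70, 180, Inf), labels = c("<70", "70-180", ">180"),
                 right = TRUE)
  absolute <- stats::setNames(100 * as.numeric(table(abs_cat)) / max(1, length(g)),
                              levels(abs_cat))
  band <- timeband_of(table$clock_h, band_h)
  bands <- 0:(24 / band_h - 1)
  mk <- function(mask) {
    m <- t(vapply(bands, function(b) pct(table$tertile[mask & band == b]),
                  numeric(3)))
    rownames(m) <- timeband_label(bands, band_h)
    m
  }
  list(overall_pct = overall, absolute_pct = absolute,
       band_window_pct = mk(!is.na(table$tertile)),
       band_brady_pct = mk(brady))
}
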