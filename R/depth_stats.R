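#' @importFrom stats ks.test lm coef sd var cor
NULL

#' Summary of a depth distribution
#'
#' Median depth with a bootstrap standard error (standard deviation of the
#' medians of `n_boot` resamples), plus range.
#'
#' @param depths Numeric vector of depths (divisions), non-empty.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @param label Optional group label carried into the result.
#' @return A `depth_summary` data frame row: `label`, `n`, `median`,
#'   `se_median`, `min`, `max`.
#' @export
depth_summary <- function(depths, n_boot = 2000L, seed = NULL, label = NA_character_) {
  if (length(depths) == 0L) stop("empty depth vector", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  boot_med <- vapply(seq_len(n_boot), function(i)
    median(sample(depths, replace = TRUE)), 0)
  out <- data.frame(label = label, n = length(depths),
                    median = median(depths),
                    se_median = stats::sd(boot_med),
                    min = min(depths), max = max(depths),
                    stringsAsFactors = FALSE)
  class(out) <- c("depth_summary", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two depth distributions; used for the age-contrast tests
#' (young vs old cohorts).
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `D` (statistic) and `p` (two-sided p-value).
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Depths of crypt cells relative to their computed MRCSC
#'
#' The relative depth of a crypt cell is the number of divisions
#' separating it from the crypt's most recent common stem cell, i.e. the
#' path length from the computed MRCSC node to the leaf.
#'
#' @param tree A rooted `phylo`.
#' @param crypt_leaves Leaf labels of the cells sampled from one crypt.
#' @return Named numeric vector of relative depths (all >= 0).
#' @export
relative_depths <- function(tree, crypt_leaves) {
  if (length(crypt_leaves) == 0L) stop("empty crypt leaf set", call. = FALSE)
  mrcsc <- computed_mrcsc(tree, crypt_leaves)
  dep <- leaf_depths(tree, exclude_root_sample = FALSE)
  dep[crypt_leaves] - mrcsc$depth
}

#' Linear fit of median depth against mouse age
#'
#' Ordinary least squares of cohort median depths on age; under ongoing
#' monoclonal conversion with one stem division per day, the slope is
#' expected near one division per day.
#'
#' @param ages Ages in days (>= 2 points).
#' @param medians Median depths (divisions), same length.
#' @return List with `slope` (divisions/day), `intercept`, `r2`.
#' @export
depth_age_fit <- function(ages, medians) {
  if (length(ages) < 2L || length(ages) != length(medians))
    stop("need >= 2 (age, median) points", call. = FALSE)
  fit <- stats::lm(medians ~ ages)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # collinear fixtures warn
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2)
}

#' Calibrate the mutation rate against the adult stem division clock
#'
#' Colon stem cells divide about once per day in adulthood, so the
#' difference in the number of divisions between an old and a young mouse
#' should equal the difference between their ages at sacrifice. Depths of
#' the two cohorts are estimated under a trial mutation rate, and the rate
#' is updated by fixed-point iteration until the median depth difference,
#' divided by the age gap, matches the assumed division rate to within
#' `tol` (relative).
#'
#' @param cohort_young,cohort_old `ms_signatures` matrices (one row per
#'   whole-crypt sample) of the young and old cohorts.
#' @param age_gap_days Age difference in days (> 0).
#' @param divisions_per_day Assumed adult stem division rate (default 1).
#' @param mu_init Starting mutation rate for the iteration.
#' @param single_to_double_odds Step-size odds of the model.
#' @param t_max Division grid upper end for depth estimation.
#' @param tol Relative tolerance on the depth-gap / target ratio.
#' @param max_iter Iteration cap.
#' @return A `calibration_result` list: `mu_hat`, `iterations`,
#'   `median_young`, `median_old` (at the calibrated rate), `target_gap`.
#' @export
calibrate_mutation_rate <- function(cohort_young, cohort_old, age_gap_days,
                                    divisions_per_day = 1,
                                    mu_init = 0.01,
                                    single_to_double_odds = 7,
                                    t_max = 3000L,
                                    tol = 0.01, max_iter = 20L) {
  if (age_gap_days <= 0) stop("age gap must be positive", call. = FALSE)
  target <- age_gap_days * divisions_per_day
  mu <- mu_init
  root_depths <- function(sig, model, tab) {
    zero <- rep(0L, ncol(sig))
    vapply(seq_len(nrow(sig)), function(i)
      pair_ml_divisions(sig[i, ], zero, model, t_max = t_max,
                        min_shared = 1L, loglik_table = tab), 0L)
  }
  k_max <- max(abs(c(cohort_young, cohort_old)), na.rm = TRUE)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    model <- mutation_model(mu, single_to_double_odds)
    tab <- step_loglik_table(model, t_max, k_max)
    dy <- root_depths(cohort_young, model, tab)
    do <- root_depths(cohort_old, model, tab)
    gap <- median(do) - median(dy)
    if (gap <= 0)
      stop("non-positive depth difference between cohorts; cannot calibrate",
           call. = FALSE)
    ratio <- gap / target
    if (abs(ratio - 1) <= tol || iterations >= max_iter) break
    mu <- mu * ratio  # more apparent divisions than the clock allows => rate is higher
  }
  structure(list(mu_hat = mu, iterations = iterations,
                 median_young = median(dy), median_old = median(do),
                 target_gap = target,
                 divisions_per_day = divisions_per_day),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibrated mutation rate: %.5f per locus per division (%d iteration(s); cohort medians %.0f / %.0f divisions, target gap %.0f)\n",
    x$mu_hat, x$iterations, x$median_young, x$median_old, x$target_gap))
  invisible(x)
}

#' Mutation size spectrum of a set of signatures
#'
#' Histogram of the per-channel repeat deviations pooled over samples;
#' the spectrum widens with the number of divisions the cells have
#' undergone, so older animals show broader spectra.
#'
#' @param signatures An `ms_signatures` matrix.
#' @return Data frame with columns `deviation` and `count`; the counts sum
#'   to the number of measured (sample, channel) entries.
#' @export
mutation_size_spectrum <- function(signatures) {
  v <- signatures[!is.na(signatures)]
  tab <- table(factor(v, levels = seq(min(v, 0), max(v, 0))))
  data.frame(deviation = as.integer(names(tab)), count = as.integer(tab))
}
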