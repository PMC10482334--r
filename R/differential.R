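#' Time-course summary: per-day means and area under the curve
#'
#' Summarizes one feature's trajectory in one condition: replicate values are
#' averaged per day (missing replicates skipped) and the per-day means are
#' integrated over the day grid by the trapezoid rule. The AUC (abundance x
#' day units) is the time-course statistic used for between-condition fold
#' changes.
#'
#' @param days Numeric vector of distinct culture days (any order; sorted
#'   internally), length at least 2.
#' @param values Either a numeric vector of per-day values (one per day) or a
#'   matrix of replicates x days. `NA` replicate values are skipped in the
#'   per-day mean; a day where every replicate is missing is an error.
#' @return A `time_course` list: `days` (sorted), `means`, `auc`.
#' @export
compute_auc <- function(days, values) {
  days <- as.numeric(days)
  if (length(days) < 2) stop("need at least 2 days")
  if (anyDuplicated(days)) stop("days must be distinct")
  if (is.matrix(values) || is.data.frame(values)) {
    values <- as.matrix(values)
    if (ncol(values) != length(days))
      stop("values must have one column per day")
    all_na <- apply(values, 2, function(v) all(is.na(v)))
    if (any(all_na))
      stop("all replicate values missing at day ",
           paste(days[all_na], collapse = ", "))
    means <- colMeans(values, na.rm = TRUE)
  } else {
    if (length(values) != length(days))
      stop("values must have one entry per day")
    if (anyNA(values))
      stop("all replicate values missing at day ",
           paste(days[is.na(values)], collapse = ", "))
    means <- as.numeric(values)
  }
  if (any(means < 0)) stop("abundances must be non-negative")
  ord <- order(days)
  days <- days[ord]; means <- means[ord]
  auc <- sum(diff(days) * (means[-1] + means[-length(means)]) / 2)
  structure(list(days = days, means = means, auc = auc),
            class = "time_course")
}

#' Signed fold change between two AUCs
#'
#' Ratio `r = auc_test / auc_control` reported in the signed "± fold"
#' convention: `r` when `r >= 1`, `-1/r` otherwise, so the value always lies
#' in (-Inf, -1] U [1, Inf) and thresholds read "± k-fold". When the control
#' AUC is at or below the detection floor while the test AUC is above it the
#' result is the `+Inf` sentinel ("infinite increase"; symmetrically `-Inf`);
#' when both are at or below the floor the fold change is undefined (`NA`)
#' and can never be called regulated.
#'
#' @param auc_test,auc_control Non-negative AUCs (vectorized).
#' @param floor Detection floor on the AUC scale. For AUCs of raw abundances
#'   use `abundance_floor * diff(range(days))` so that a trajectory pinned at
#'   the abundance floor stays below it.
#' @return Signed fold change(s); `Inf`/`-Inf` sentinels, `NA` undefined.
#' @export
fold_change <- function(auc_test, auc_control, floor = 5000) {
  if (any(auc_test < 0, na.rm = TRUE) || any(auc_control < 0, na.rm = TRUE))
    stop("AUCs must be non-negative")
  n <- max(length(auc_test), length(auc_control))
  auc_test <- rep_len(auc_test, n); auc_control <- rep_len(auc_control, n)
  out <- numeric(n)
  below_t <- auc_test <= floor
  below_c <- auc_control <= floor
  out[below_t & below_c] <- NA_real_
  out[below_c & !below_t] <- Inf
  out[below_t & !below_c] <- -Inf
  ok <- !below_t & !below_c
  tt <- auc_test[ok]; cc <- auc_control[ok]
  # -(control/test) rather than -1/r: exact antisymmetry under condition swap
  out[ok] <- ifelse(tt >= cc, tt / cc, -(cc / tt))
  out
}

#' Maximum per-day signed fold change
#'
#' The alternative fold statistic for protein ratios: per-day signed fold
#' changes are computed as in [fold_change()] on the per-day means, and the
#' one with the largest absolute value wins (sign kept; infinite sentinels
#' dominate finite values; ties broken by the earliest day). Days where both
#' conditions sit at or below the floor are undefined and ignored; if no day
#' is defined the result is the `NA` sentinel.
#'
#' @param means_test,means_control Per-day mean abundances on a shared day
#'   grid.
#' @param days The day grid (same length as the means).
#' @param floor Per-day detection floor (abundance units).
#' @return A list: `signed_fc` and `day` (the day attaining the maximum;
#'   `NA` when undefined).
#' @export
max_fold_change <- function(means_test, means_control, days,
                            floor = 5000) {
  stopifnot(length(means_test) == length(days),
            length(means_control) == length(days))
  fc <- fold_change(means_test, means_control, floor = floor)
  if (all(is.na(fc))) return(list(signed_fc = NA_real_, day = NA_real_))
  i <- which.max(abs(fc))  # NA ignored; first (earliest day) wins ties
  list(signed_fc = fc[i], day = days[i])
}

#' Finalize regulation calls
#'
#' A feature is differentially regulated when its signed fold change passes
#' the threshold (boundary inclusive; infinite sentinels pass, undefined
#' never does) AND it was flagged significant by the OPLS-DA predictive-
#' loading rule. Direction follows the sign of the fold change for regulated
#' features and is `"none"` otherwise. Conventional thresholds: metabolites
#' ±1.5, proteins ±1.1.
#'
#' @param calls Data frame with at least `feature_id` and `signed_fc`.
#' @param threshold Fold threshold, at least 1.
#' @param significant_ids Feature ids flagged by [significant_loadings()].
#' @return `calls` with columns `passes_threshold`, `opls_significant`,
#'   `regulated`, `direction` added/overwritten.
#' @export
call_regulation <- function(calls, threshold, significant_ids) {
  stopifnot(is.data.frame(calls),
            all(c("feature_id", "signed_fc") %in% names(calls)))
  if (!is.numeric(threshold) || threshold < 1)
    stop("threshold must be a number >= 1")
  fc <- calls$signed_fc
  calls$passes_threshold <- !is.na(fc) & (is.infinite(fc) | abs(fc) >= threshold)
  calls$opls_significant <- calls$feature_id %in% significant_ids
  calls$regulated <- calls$passes_threshold & calls$opls_significant
  calls$direction <- ifelse(calls$regulated,
                            ifelse(fc > 0, "up", "down"), "none")
  calls
}

# Per-feature, per-condition replicate matrix (replicates x days) for one
# condition's samples, over the given day grid.
condition_day_matrix <- function(table, condition, days) {
  sm <- table$sample_meta
  sapply(days, function(d) {
    cols <- sm$sample_id[sm$condition == condition & sm$day == d]
    table$abundance[, cols, drop = FALSE]
  }, simplify = FALSE)
}

#' Differential analysis of a feature table
#'
#' Computes, for every feature, the per-condition time-course AUC over the
#' shared day grid, the signed AUC fold change (test vs control), the maximum
#' per-day fold change, and the final regulation call combining the fold
#' threshold with the OPLS-DA significance set. Missing abundances should be
#' imputed first ([impute_missing()]); the AUC-scale detection floor is
#' `abundance_floor * diff(range(days))`. If the two conditions were sampled
#' on different day grids the intersection is used, with a warning.
#'
#' @param table A [feature_table()] (imputed: no `NA`).
#' @param significant_ids Feature ids from [significant_loadings()].
#' @param mode `"metabolite"` (threshold 1.5, AUC statistic) or `"protein"`
#'   (threshold 1.1). The default fold statistic is the AUC ratio in both
#'   modes; set `stat = "max"` for the maximum per-day fold change.
#' @param stat Which statistic drives the threshold: `"auc"` or `"max"`.
#' @param threshold Override the mode's default threshold.
#' @param abundance_floor Per-day detection floor (default 5000).
#' @param test_label,control_label Condition labels in `sample_meta`.
#' @return Data frame of differential calls: `feature_id`, `auc_test`,
#'   `auc_control`, `signed_fc`, `max_fc`, `max_fc_day`, `passes_threshold`,
#'   `opls_significant`, `regulated`, `direction`.
#' @export
differential_analysis <- function(table, significant_ids,
                                  mode = c("metabolite", "protein"),
                                  stat = c("auc", "max"),
                                  threshold = NULL, abundance_floor = 5000,
                                  test_label = "test",
                                  control_label = "control") {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  if (is.null(threshold))
    threshold <- if (mode == "metabolite") 1.5 else 1.1
  if (anyNA(table$abundance))
    stop("table contains missing abundances; run impute_missing() first")

  sm <- table$sample_meta
  days_t <- sort(unique(sm$day[sm$condition == test_label]))
  days_c <- sort(unique(sm$day[sm$condition == control_label]))
  if (!length(days_t) || !length(days_c))
    stop("conditions '", test_label, "' / '", control_label,
         "' not found in sample_meta")
  days <- intersect(days_t, days_c)
  if (!setequal(days_t, days_c))
    warning("day grids differ between conditions; using their intersection")
  days <- sort(days)
  if (length(days) < 2) stop("need at least 2 shared days")

  mats_t <- condition_day_matrix(table, test_label, days)
  mats_c <- condition_day_matrix(table, control_label, days)
  nf <- nrow(table$abundance)
  means_t <- sapply(mats_t, rowMeans)  # features x days
  means_c <- sapply(mats_c, rowMeans)
  if (nf == 1) { means_t <- matrix(means_t, 1); means_c <- matrix(means_c, 1) }

  span <- diff(range(days))
  trap <- function(m) {
    wd <- diff(days)
    as.numeric((m[, -1, drop = FALSE] + m[, -length(days), drop = FALSE]) %*%
                 (wd / 2))
  }
  auc_t <- trap(means_t)
  auc_c <- trap(means_c)
  floor_auc <- abundance_floor * span

  mx <- lapply(seq_len(nf), function(i)
    max_fold_change(means_t[i, ], means_c[i, ], days, floor = abundance_floor))

  calls <- data.frame(
    feature_id = rownames(table$abundance),
    auc_test = auc_t, auc_control = auc_c,
    signed_fc = fold_change(auc_t, auc_c, floor = floor_auc),
    max_fc = vapply(mx, `[[`, numeric(1), "signed_fc"),
    max_fc_day = vapply(mx, `[[`, numeric(1), "day"),
    stringsAsFactors = FALSE
  )
  if (stat == "max") {
    calls_stat <- calls
    calls_stat$signed_fc <- calls$max_fc
    calls_stat <- call_regulation(calls_stat, threshold, significant_ids)
    calls_stat$signed_fc <- calls$signed_fc
    calls <- calls_stat
  } else {
    calls <- call_regulation(calls, threshold, significant_ids)
  }
  calls
}
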