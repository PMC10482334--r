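#' Feature-retention filter
#'
#' Keeps features eluting inside a retention-time window and whose maximum
#' abundance across samples exceeds a floor. Defaults follow the standard
#' untargeted LC-MS curation rule for this pipeline: retain features eluted
#' between 0.8 and 9 minutes (bounds inclusive) with abundances strictly
#' greater than 5,000. Feature order is preserved; the filter is idempotent.
#'
#' @param table A [feature_table()]. Retention-time filtering requires a
#'   `feature_meta` with an `rt` column (minutes).
#' @param rt_window Length-2 numeric `(min, max)` in minutes, bounds inclusive,
#'   or `NULL` to skip the retention-time rule.
#' @param abundance_floor Features whose maximum abundance across samples is
#'   not strictly greater than this are removed. `-Inf` disables the rule.
#' @return The filtered `feature_table`.
#' @export
filter_features <- function(table, rt_window = c(0.8, 9.0),
                            abundance_floor = 5000) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$abundance)
  keep <- rep(TRUE, n)

  if (!is.null(rt_window)) {
    stopifnot(length(rt_window) == 2, rt_window[1] <= rt_window[2])
    if (is.null(table$feature_meta) || !"rt" %in% names(table$feature_meta))
      stop("retention-time filtering requested but feature_meta has no 'rt' ",
           "column; pass rt_window = NULL to skip the RT rule")
    rt <- table$feature_meta$rt
    keep <- keep & !is.na(rt) & rt >= rt_window[1] & rt <= rt_window[2]
  }

  max_ab <- apply(table$abundance, 1, function(v) {
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
  })
  keep <- keep & max_ab > abundance_floor

  subset_features(table, keep)
}

#' Impute missing abundances
#'
#' Replaces `NA` abundances (signals below the detection floor) with a fixed
#' value, conventionally half the detection floor.
#'
#' @param table A [feature_table()].
#' @param value Replacement value; default half the 5,000 retention floor.
#' @return The imputed `feature_table`.
#' @export
impute_missing <- function(table, value = 2500) {
  stopifnot(inherits(table, "feature_table"), value >= 0)
  ab <- table$abundance
  ab[is.na(ab)] <- value
  feature_table(ab, table$sample_meta, table$feature_meta)
}

#' Pareto scaling
#'
#' Transforms each variable to `(x - mean) / sqrt(s)` where `s` is the sample
#' standard deviation — intermediate between mean centering and unit-variance
#' scaling, the metabolomics convention that tempers the dominance of
#' high-abundance features without amplifying noise-level ones. Zero-variance
#' variables are centered only (all zeros). After scaling each variable has
#' mean 0 and variance equal to its pre-scaling standard deviation.
#'
#' @param x Numeric matrix with no missing values (impute first).
#' @param by Which margin holds the variables: `"columns"` (default;
#'   observations in rows, the model orientation) or `"rows"`.
#' @return Scaled matrix of identical shape, with attributes `scaled:center`
#'   and `scaled:scale` (the divisor `sqrt(s)`, 1 for constant variables) for
#'   applying the same transform to new observations.
#' @export
pareto_scale <- function(x, by = c("columns", "rows")) {
  by <- match.arg(by)
  x <- as.matrix(x)
  if (by == "rows") {
    out <- pareto_scale(t(x), by = "columns")
    res <- t(out)
    attr(res, "scaled:center") <- attr(out, "scaled:center")
    attr(res, "scaled:scale") <- attr(out, "scaled:scale")
    return(res)
  }
  if (anyNA(x)) stop("pareto_scale requires complete data; impute first")
  if (nrow(x) < 2) stop("pareto scaling needs at least 2 observations")
  ctr <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  scl <- sqrt(s)
  scl[s == 0] <- 1
  out <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  attr(out, "scaled:center") <- ctr
  attr(out, "scaled:scale") <- scl
  out
}

#' Mean centering
#'
#' Subtracts the per-variable mean; the scaling used for ratio-type data
#' (e.g. TMT protein ratios) where the variance structure is already
#' comparable across variables.
#'
#' @inheritParams pareto_scale
#' @return Centered matrix with a `scaled:center` attribute.
#' @export
mean_center <- function(x, by = c("columns", "rows")) {
  by <- match.arg(by)
  x <- as.matrix(x)
  if (length(x) == 0) stop("cannot center an empty matrix")
  if (by == "rows") {
    out <- mean_center(t(x), by = "columns")
    res <- t(out)
    attr(res, "scaled:center") <- attr(out, "scaled:center")
    return(res)
  }
  if (anyNA(x)) stop("mean_center requires complete data; impute first")
  ctr <- colMeans(x)
  out <- sweep(x, 2, ctr, "-")
  attr(out, "scaled:center") <- ctr
  out
}

# Apply a previously fitted scaling to new observations (columns = variables).
apply_scaling <- function(xnew, fitted) {
  ctr <- attr(fitted, "scaled:center")
  scl <- attr(fitted, "scaled:scale")
  out <- sweep(xnew, 2, ctr, "-")
  if (!is.null(scl)) out <- sweep(out, 2, scl, "/")
  out
}

# Scale an observations x variables matrix by mode; "none" passes through.
scale_matrix <- function(x, mode = c("pareto", "center", "none")) {
  mode <- match.arg(mode)
  switch(mode,
         pareto = pareto_scale(x),
         center = mean_center(x),
         none = x)
}
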