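#' Signed mass error in parts per million
#'
#' `1e6 * (observed - reference) / reference`.
#'
#' @param observed_mass,reference_mass Masses in Da (vectorized);
#'   `reference_mass` must be strictly positive.
#' @return Signed ppm error(s).
#' @export
ppm_error <- function(observed_mass, reference_mass) {
  if (any(reference_mass <= 0))
    stop("reference mass must be strictly positive")
  1e6 * (observed_mass - reference_mass) / reference_mass
}

#' Build a reference-standard table
#'
#' @param name Unique record names.
#' @param monoisotopic_mass Positive masses (Da).
#' @param retention_time Retention times (minutes); required for
#'   `in_house_standard` records, `NA` allowed otherwise.
#' @param source One of `in_house_standard`, `spectral_library`,
#'   `tentative_structure`, `sum_formula`.
#' @param msms_spectrum_id Optional spectrum identifiers.
#' @return A `data.frame` usable as the `references` argument of
#'   [assign_tier()].
#' @export
reference_standards <- function(name, monoisotopic_mass, retention_time = NA,
                                source, msms_spectrum_id = NA) {
  src_levels <- c("in_house_standard", "spectral_library",
                  "tentative_structure", "sum_formula")
  df <- data.frame(name = as.character(name),
                   monoisotopic_mass = as.numeric(monoisotopic_mass),
                   retention_time = as.numeric(retention_time),
                   source = as.character(source),
                   msms_spectrum_id = as.character(msms_spectrum_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("reference names must be unique")
  if (any(df$monoisotopic_mass <= 0)) stop("masses must be positive")
  bad <- setdiff(unique(df$source), src_levels)
  if (length(bad)) stop("unknown source(s): ", paste(bad, collapse = ", "))
  if (any(df$source == "in_house_standard" & is.na(df$retention_time)))
    stop("in_house_standard records must carry a retention_time")
  df
}

# Tier order used for monotonicity reasoning: 1 best ... 5 worst.
TIER_LEVELS <- c("1", "1*", "2", "3", "4", "5")

# Pick the best of several candidate references: smallest |ppm| error, ties
# by smallest |delta RT|, remaining ties lexicographic by name.
best_candidate <- function(cand) {
  rt_err <- ifelse(is.na(cand$rt_err), Inf, abs(cand$rt_err))
  cand[order(abs(cand$ppm), rt_err, cand$name)[1], , drop = FALSE]
}

#' Assign an identification-confidence tier
#'
#' Applies the tier cascade, first rule that fires:
#' \describe{
#'   \item{tier 1}{in-house standard matched on retention time (± `rt_tol`),
#'     precursor mass (± `ppm_tol`) and MS/MS fragmentation pattern.}
#'   \item{tier 1*}{same standard match, but the feature lacks MS/MS data.}
#'   \item{tier 2}{precursor mass (± `ppm_tol`) and MS/MS pattern match a
#'     spectral-library record (no retention-time requirement: libraries are
#'     not instrument-specific).}
#'   \item{tier 3}{precursor mass matches a tentative structure and the MS/MS
#'     data were annotated manually.}
#'   \item{tier 4}{precursor mass matches (± `ppm_tol`) and the isotopic
#'     pattern fits a sum formula (mSigma strictly below `msigma_max`);
#'     skipped, not an error, when mSigma is missing.}
#'   \item{tier 5}{anything else — known only by a unique retention time and
#'     precursor mass.}
#' }
#' Mass and RT tolerances are boundary-inclusive; the mSigma bound is strict.
#' Among multiple candidate references the smallest |ppm| wins, ties broken
#' by |delta RT| then name.
#'
#' @param evidence A one-row data frame or list with fields `feature_id`,
#'   `precursor_mass`, `retention_time`, `has_msms`, `msms_match_standard`,
#'   `msms_match_library`, `msms_manual_structure`, `msigma` (may be `NA`),
#'   `formula_match`.
#' @param references Reference table as from [reference_standards()].
#' @param rt_tol Retention-time tolerance, minutes (default 0.3).
#' @param ppm_tol Mass tolerance, ppm (default 3.0).
#' @param msigma_max Isotope-fit bound, strict (default 100).
#' @return A one-row data frame (`annotation_record`): `feature_id`, `tier`,
#'   `matched_reference`, `ppm_error`, `rt_error`.
#' @export
assign_tier <- function(evidence, references, rt_tol = 0.3, ppm_tol = 3.0,
                        msigma_max = 100) {
  stopifnot(rt_tol > 0, ppm_tol > 0, msigma_max > 0)
  ev <- as.list(evidence)
  for (fl in c("msms_match_standard", "msms_match_library",
               "msms_manual_structure"))
    if (isTRUE(ev[[fl]]) && !isTRUE(ev$has_msms))
      stop(fl, " = TRUE requires has_msms = TRUE")

  rec <- function(tier, match = NULL) {
    data.frame(
      feature_id = as.character(ev$feature_id), tier = tier,
      matched_reference = if (is.null(match)) NA_character_ else match$name,
      ppm_error = if (is.null(match)) NA_real_ else match$ppm,
      rt_error = if (is.null(match)) NA_real_ else match$rt_err,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(references) || nrow(references) == 0) return(rec("5"))

  cand <- references
  cand$ppm <- ppm_error(ev$precursor_mass, cand$monoisotopic_mass)
  cand$rt_err <- ev$retention_time - cand$retention_time
  in_mass <- abs(cand$ppm) <= ppm_tol

  std <- cand[in_mass & cand$source == "in_house_standard" &
                !is.na(cand$rt_err) & abs(cand$rt_err) <= rt_tol, ,
              drop = FALSE]
  if (nrow(std)) {
    if (isTRUE(ev$msms_match_standard)) return(rec("1", best_candidate(std)))
    if (!isTRUE(ev$has_msms)) return(rec("1*", best_candidate(std)))
  }
  lib <- cand[in_mass & cand$source == "spectral_library", , drop = FALSE]
  if (nrow(lib) && isTRUE(ev$msms_match_library))
    return(rec("2", best_candidate(lib)))
  tent <- cand[in_mass & cand$source == "tentative_structure", , drop = FALSE]
  if (nrow(tent) && isTRUE(ev$msms_manual_structure))
    return(rec("3", best_candidate(tent)))
  any_mass <- cand[in_mass, , drop = FALSE]
  if (nrow(any_mass) && !is.na(ev$msigma) && ev$msigma < msigma_max &&
      isTRUE(ev$formula_match))
    return(rec("4", best_candidate(any_mass)))
  rec("5")
}

#' Assign tiers to a whole evidence table
#'
#' @param evidence Data frame with one row per feature (fields as in
#'   [assign_tier()]).
#' @inheritParams assign_tier
#' @return Data frame of annotation records, one row per evidence row.
#' @export
assign_tiers <- function(evidence, references, rt_tol = 0.3, ppm_tol = 3.0,
                         msigma_max = 100) {
  stopifnot(is.data.frame(evidence), nrow(evidence) > 0)
  out <- lapply(seq_len(nrow(evidence)), function(i)
    assign_tier(evidence[i, , drop = FALSE], references,
                rt_tol = rt_tol, ppm_tol = ppm_tol, msigma_max = msigma_max))
  do.call(rbind, out)
}

#' Tier-by-abundance-bin summary
#'
#' Cross-tabulates annotation tiers against abundance bins — the standard
#' view of how identification confidence degrades with signal intensity.
#'
#' @param records Annotation records ([assign_tiers()]).
#' @param abundances Named numeric vector of per-feature maximum abundance
#'   (names = feature ids); features with no abundance are counted in an
#'   `unbinned` column with a warning.
#' @param bins Strictly increasing bin edges; default
#'   `c(5000, 10000, 50000, 100000, Inf)`. Values at or below the first edge
#'   fall in the first bin.
#' @return A table, rows = tiers (1, 1*, 2-5), columns = bins; entries sum to
#'   the number of records.
#' @export
summarize_tiers <- function(records, abundances,
                            bins = c(5000, 10000, 50000, 100000, Inf)) {
  stopifnot(is.data.frame(records), "tier" %in% names(records))
  if (is.unsorted(bins, strictly = TRUE)) stop("bins must be strictly increasing")
  tier <- factor(records$tier, levels = TIER_LEVELS)
  ab <- abundances[records$feature_id]
  labs <- paste0("(", utils::head(bins, -1), ",", utils::tail(bins, -1), "]")
  bin <- rep(NA_character_, nrow(records))
  known <- !is.na(ab)
  if (any(!known))
    warning(sum(!known), " record(s) without abundance counted as 'unbinned'")
  if (any(known)) {
    idx <- findInterval(ab[known], bins, left.open = TRUE,
                        rightmost.closed = FALSE)
    idx[idx < 1] <- 1          # at/below the first edge: first bin
    idx[idx >= length(bins)] <- length(bins) - 1
    bin[known] <- labs[idx]
  }
  lev <- c(labs, if (any(!known)) "unbinned")
  bin[!known] <- "unbinned"
  table(tier = tier, bin = factor(bin, levels = lev))
}
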