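#' Study design for the synthetic-data generator
#'
#' Describes the world the generator emulates: a fed-batch culture sampled on
#' a fixed day grid under two conditions with a few biological replicates,
#' thousands of log-normal LC-MS features whose variance is dominated by a
#' shared smooth culture-time trajectory, a small planted condition effect on
#' a subset of discriminative features, and a handful of features present in
#' only one condition.
#'
#' @param conditions Ordered pair of labels, `(test, control)`.
#' @param days Strictly increasing non-negative culture days, at least 3.
#' @param replicates_per_condition Biological replicates per condition
#'   (default 3).
#' @param n_features Number of features (default 2000).
#' @param n_discriminative Features with a planted condition effect
#'   (default 50).
#' @param effect_log2fc Planted effect on the log2 scale (default 1, i.e. a
#'   true 2x ratio); sign is drawn per feature.
#' @param time_variance_fraction Target share of each feature's log-abundance
#'   variance driven by the shared time trajectory, in (0,1) (default 0.6,
#'   emulating time-dominated fed-batch data where roughly 50-65% of the
#'   variance follows culture time).
#' @param noise_cv Replicate coefficient of variation of the multiplicative
#'   log-normal noise (default 0.2).
#' @param n_exclusive Features present only in the test condition
#'   (default 20).
#' @param seed Integer seed; one root seed drives the whole generator.
#' @return A `study_design` list (validated).
#' @export
study_design <- function(conditions = c("test", "control"),
                         days = c(3, 5, 7, 10, 12, 14, 17),
                         replicates_per_condition = 3,
                         n_features = 2000, n_discriminative = 50,
                         effect_log2fc = 1, time_variance_fraction = 0.6,
                         noise_cv = 0.2, n_exclusive = 20, seed = 1) {
  design <- list(conditions = as.character(conditions), days = as.numeric(days),
                 replicates_per_condition = as.integer(replicates_per_condition),
                 n_features = as.integer(n_features),
                 n_discriminative = as.integer(n_discriminative),
                 effect_log2fc = as.numeric(effect_log2fc),
                 time_variance_fraction = as.numeric(time_variance_fraction),
                 noise_cv = as.numeric(noise_cv),
                 n_exclusive = as.integer(n_exclusive),
                 seed = as.integer(seed))
  with(design, {
    if (length(conditions) != 2 || anyDuplicated(conditions))
      stop("conditions must be two distinct labels")
    if (length(days) < 3) stop("need at least 3 days")
    if (is.unsorted(days, strictly = TRUE))
      stop("days must be strictly increasing")
    if (any(days < 0)) stop("days must be non-negative")
    if (replicates_per_condition < 1) stop("replicates_per_condition must be >= 1")
    if (n_features < 1) stop("n_features must be positive")
    if (n_discriminative < 0 || n_exclusive < 0 ||
        n_discriminative + n_exclusive > n_features)
      stop("n_discriminative + n_exclusive must be <= n_features")
    if (effect_log2fc < 0) stop("effect_log2fc must be non-negative")
    if (time_variance_fraction <= 0 || time_variance_fraction >= 1)
      stop("time_variance_fraction must be in (0,1)")
    if (noise_cv <= 0) stop("noise_cv must be positive")
  })
  structure(design, class = "study_design")
}

#' Generate a synthetic feature table with ground truth
#'
#' Each feature's log-abundance is
#' `baseline + amplitude * h(day) + condition_offset + noise`, where `h` is
#' one shared smooth (cubic) trajectory over the day grid, standardized to
#' unit variance; the per-feature amplitude (random sign) is set so that the
#' time trajectory accounts for `time_variance_fraction` of that feature's
#' log-variance — making culture time a single dominant orthogonal direction,
#' as in fed-batch multi-omics data. Discriminative features get a condition
#' offset of `±effect_log2fc * ln 2` in the test condition; replicate noise
#' is i.i.d. log-normal with coefficient of variation `noise_cv`. Exclusive
#' features are absent (below the 5,000 detection floor, recorded as `NA`)
#' in the control condition. Identical seeds give bit-identical output.
#'
#' @param design A [study_design()].
#' @return A list:
#'   \describe{
#'     \item{table}{[feature_table()] with per-feature retention times in
#'       `feature_meta` (planted features are kept inside the 0.8-9 min
#'       retention window so filtering cannot silently drop ground truth).}
#'     \item{truth}{`ground_truth` list: `discriminative_ids`,
#'       `exclusive_ids`, `planted_log2fc` (signed, named, 0 for nulls),
#'       `time_profile` (per-feature label), `trajectory` (data frame
#'       `day`, `value` of the shared standardized trajectory),
#'       `amplitude` (named per-feature time amplitude on the log scale),
#'       `sigma_log` (replicate noise sd on the natural-log scale).}
#'   }
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "study_design"))
  d <- design
  set.seed(d$seed)

  n_days <- length(d$days)
  reps <- d$replicates_per_condition
  n_samp <- 2L * reps * n_days
  sm <- expand.grid(replicate = seq_len(reps), day = d$days,
                    condition = d$conditions, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  sm <- sm[, c("condition", "day", "replicate")]
  sm$sample_id <- sprintf("%s_d%g_r%d", sm$condition, sm$day, sm$replicate)
  stopifnot(nrow(sm) == n_samp, !anyDuplicated(sm$sample_id))

  # shared cubic trajectory, standardized over the day grid
  u <- if (diff(range(d$days)) > 0)
    2 * (d$days - min(d$days)) / diff(range(d$days)) - 1 else rep(0, n_days)
  h <- rep(0, n_days)
  while (stats::sd(h) < 1e-8) {
    cf <- stats::rnorm(4)
    h <- cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3
  }
  # population sd over the day grid: unit variance across samples, since
  # every day carries the same number of samples
  h <- (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  names(h) <- as.character(d$days)
  h_samp <- h[as.character(sm$day)]

  fid <- sprintf("F%05d", seq_len(d$n_features))
  disc <- sample(fid, d$n_discriminative)
  excl <- sample(setdiff(fid, disc), d$n_exclusive)
  special <- fid %in% c(disc, excl)

  # baselines: log-normal abundances; planted features kept well above the
  # 5,000 detection floor so retention filtering cannot remove ground truth
  mu <- stats::rnorm(d$n_features, log(1e5), 1)
  mu[special] <- pmax(mu[special], log(5e4))

  delta <- stats::setNames(rep(0, d$n_features), fid)
  delta[disc] <- sample(c(-1, 1), length(disc), replace = TRUE) *
    d$effect_log2fc * log(2)

  sigma <- sqrt(log(1 + d$noise_cv^2))
  cond_var <- (delta / 2)^2  # offset on half the samples: variance delta^2/4
  tvf <- d$time_variance_fraction
  amp <- sample(c(-1, 1), d$n_features, replace = TRUE) *
    sqrt(tvf / (1 - tvf) * (sigma^2 + cond_var))
  names(amp) <- fid

  is_test <- as.numeric(sm$condition == d$conditions[1])
  log_ab <- outer(mu, rep(1, n_samp)) +
    outer(amp, rep(1, n_samp)) * matrix(h_samp, d$n_features, n_samp,
                                        byrow = TRUE) +
    outer(delta, is_test) +
    matrix(stats::rnorm(d$n_features * n_samp, 0, sigma),
           d$n_features, n_samp)
  ab <- exp(log_ab)
  dimnames(ab) <- list(fid, sm$sample_id)
  ab[excl, sm$condition == d$conditions[2]] <- NA_real_  # absent in control

  rt <- stats::runif(d$n_features, 0.5, 9.5)
  rt[special] <- stats::runif(sum(special), 1.0, 8.5)
  fm <- data.frame(feature_id = fid, rt = rt, stringsAsFactors = FALSE)

  table <- feature_table(ab, sm, fm)
  truth <- structure(
    list(discriminative_ids = disc, exclusive_ids = excl,
         planted_log2fc = delta / log(2),
         time_profile = stats::setNames(
           ifelse(amp >= 0, "shared_cubic_up", "shared_cubic_down"), fid),
         trajectory = data.frame(day = d$days, value = unname(h)),
         amplitude = amp, sigma_log = sigma, design = d),
    class = "ground_truth"
  )
  list(table = table, truth = truth)
}

#' Realized share of variance driven by the time trajectory
#'
#' Regresses every feature of the pooled, scaled data on the generator's
#' shared trajectory evaluated at each sample's day, and returns the pooled
#' explained sum of squares over the total. This is the quantity the fitted
#' OPLS-DA orthogonal component should approximate on time-dominated data.
#'
#' @param table A [feature_table()] from [generate_dataset()].
#' @param truth The matching `ground_truth`.
#' @param scale Scaling applied before the regression (default `"pareto"`,
#'   the model's input scale).
#' @param impute_value Replacement for missing abundances (default 2500).
#' @return The realized variance fraction in `[0, 1]`.
#' @export
realized_time_variance <- function(table, truth, scale = "pareto",
                                   impute_value = 2500) {
  stopifnot(inherits(table, "feature_table"), inherits(truth, "ground_truth"))
  X <- scale_matrix(t(impute_missing(table, impute_value)$abundance), scale)
  h <- truth$trajectory$value[match(table$sample_meta$day,
                                    truth$trajectory$day)]
  hc <- h - mean(h)
  beta <- drop(crossprod(X, hc)) / sum(hc^2)
  ss_fit <- sum(beta^2) * sum(hc^2)
  Xc <- sweep(X, 2, colMeans(X), "-")
  ss_fit / sum(Xc^2)
}

#' Generate annotation evidence with known intended tiers
#'
#' Builds a reference library (masses spaced far apart so a feature can match
#' at most one record) and, for every feature of the table, evidence
#' engineered to realize a randomly drawn intended tier: mass within ±2.5 ppm
#' and, for standards, retention time within ±0.25 min of the matched record,
#' with the MS/MS, isotope-fit and formula flags the tier requires and no
#' accidental qualification for a better tier. The intended tier is recorded
#' as ground truth (`intended_tier` column) and ignored by [assign_tier()].
#'
#' @param table A [feature_table()].
#' @param library_size Number of reference records (default 200); must allow
#'   every requested source. Zero is an error when tier-1/1* ground truth is
#'   requested.
#' @param seed Integer seed.
#' @param tier_probs Named sampling weights over intended tiers
#'   `c("1","1*","2","3","4","5")`.
#' @return A list: `evidence` (data frame, one row per feature, including the
#'   ground-truth `intended_tier`) and `references` (see
#'   [reference_standards()]).
#' @export
generate_annotation_evidence <- function(table, library_size = 200, seed = 1,
                                         tier_probs = c("1" = 0.25, "1*" = 0.05,
                                                        "2" = 0.15, "3" = 0.10,
                                                        "4" = 0.20, "5" = 0.25)) {
  stopifnot(inherits(table, "feature_table"), nrow(table$abundance) > 0)
  stopifnot(setequal(names(tier_probs), TIER_LEVELS), all(tier_probs >= 0))
  set.seed(seed)
  fid <- rownames(table$abundance)
  n <- length(fid)
  intended <- sample(TIER_LEVELS, n, replace = TRUE, prob = tier_probs)

  if (library_size == 0 && any(intended %in% c("1", "1*")))
    stop("library_size = 0 but tier-1 ground truth requested")

  src_levels <- c("in_house_standard", "spectral_library",
                  "tentative_structure", "sum_formula")
  refs <- NULL
  if (library_size > 0) {
    if (library_size < length(src_levels))
      stop("library_size must be at least ", length(src_levels),
           " to cover every reference source")
    # jittered mass grid: records separated by far more than the ppm window
    mass <- seq(100, 1000, length.out = library_size) +
      stats::runif(library_size, -0.02, 0.02)
    src <- rep_len(src_levels, library_size)
    refs <- reference_standards(
      name = sprintf("REF_%04d", seq_len(library_size)),
      monoisotopic_mass = mass,
      retention_time = stats::runif(library_size, 0.8, 9.0),
      source = src,
      msms_spectrum_id = ifelse(src %in% c("in_house_standard",
                                           "spectral_library"),
                                sprintf("SPEC_%04d", seq_len(library_size)),
                                NA_character_))
  }

  pick_ref <- function(source) {
    pool <- which(refs$source == source)
    if (!length(pool)) stop("no reference of source '", source, "' available")
    refs[sample(pool, 1), , drop = FALSE]
  }
  near_mass <- function(m) m * (1 + stats::runif(1, -2.5, 2.5) * 1e-6)
  far_mass <- function() {
    repeat {
      m <- stats::runif(1, 100, 1000)
      if (is.null(refs) ||
          min(abs(ppm_error(m, refs$monoisotopic_mass))) > 5) return(m)
    }
  }

  ev <- data.frame(
    feature_id = fid, precursor_mass = NA_real_, retention_time = NA_real_,
    has_msms = FALSE, msms_match_standard = FALSE, msms_match_library = FALSE,
    msms_manual_structure = FALSE, msigma = NA_real_, formula_match = FALSE,
    intended_tier = intended, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    ti <- intended[i]
    if (ti %in% c("1", "1*")) {
      r <- pick_ref("in_house_standard")
      ev$precursor_mass[i] <- near_mass(r$monoisotopic_mass)
      ev$retention_time[i] <- r$retention_time + stats::runif(1, -0.25, 0.25)
      if (ti == "1") {
        ev$has_msms[i] <- TRUE; ev$msms_match_standard[i] <- TRUE
      }
    } else if (ti == "2") {
      r <- pick_ref("spectral_library")
      ev$precursor_mass[i] <- near_mass(r$monoisotopic_mass)
      ev$retention_time[i] <- stats::runif(1, 0.8, 9.0)
      ev$has_msms[i] <- TRUE; ev$msms_match_library[i] <- TRUE
    } else if (ti == "3") {
      r <- pick_ref("tentative_structure")
      ev$precursor_mass[i] <- near_mass(r$monoisotopic_mass)
      ev$retention_time[i] <- stats::runif(1, 0.8, 9.0)
      ev$has_msms[i] <- TRUE; ev$msms_manual_structure[i] <- TRUE
    } else if (ti == "4") {
      r <- pick_ref("sum_formula")
      ev$precursor_mass[i] <- near_mass(r$monoisotopic_mass)
      ev$retention_time[i] <- stats::runif(1, 0.8, 9.0)
      ev$msigma[i] <- stats::runif(1, 0, 99)
      ev$formula_match[i] <- TRUE
      ev$has_msms[i] <- TRUE  # spectra acquired, but no match anywhere
    } else {  # tier 5: no mass match to any record
      ev$precursor_mass[i] <- far_mass()
      ev$retention_time[i] <- stats::runif(1, 0.8, 9.0)
      ev$msigma[i] <- stats::runif(1, 120, 300)
    }
  }
  list(evidence = ev, references = refs)
}
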