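#' Pipeline configuration
#'
#' Gathers every tunable of the simulate -> preprocess -> OPLS-DA ->
#' differential -> annotate pipeline in one validated record. Either a
#' simulation design or input file paths must be supplied.
#'
#' @param design Optional [study_design()] — when given, data are simulated.
#' @param abundance_file,samples_file,features_file Input TSVs (used when no
#'   `design` is given; see [read_feature_table()]).
#' @param omics `"metabolite"` (pareto scaling of raw abundances, fold
#'   threshold 1.5) or `"protein"` (centering of ratio-type data, threshold
#'   1.1). Either default can be overridden.
#' @param scaling `"pareto"` or `"center"`; default follows `omics`.
#' @param fc_threshold Fold threshold; default follows `omics`.
#' @param fc_stat `"auc"` (integral fold change) or `"max"` (maximum per-day
#'   fold change).
#' @param rt_window,abundance_floor Feature-retention rules
#'   ([filter_features()]); set `rt_window = NULL` to skip the RT rule.
#' @param impute_value Replacement for missing abundances (default
#'   `abundance_floor / 2`).
#' @param n_ortho `"auto"` or a fixed count of orthogonal components.
#' @param folds Cross-validation folds (default 7).
#' @param n_perm Label permutations for model validation (default 200; 0
#'   skips the permutation test).
#' @param annotate Logical: simulate annotation evidence and assign tiers
#'   (simulation runs only).
#' @param seed Integer seed for every stochastic step.
#' @param out_dir Output directory.
#' @param test_label,control_label Condition labels; default taken from the
#'   design when simulating.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(design = NULL, abundance_file = NULL,
                            samples_file = NULL, features_file = NULL,
                            omics = c("metabolite", "protein"),
                            scaling = NULL, fc_threshold = NULL,
                            fc_stat = c("auc", "max"),
                            rt_window = c(0.8, 9.0), abundance_floor = 5000,
                            impute_value = NULL, n_ortho = "auto", folds = 7,
                            n_perm = 200, annotate = FALSE, seed = 1,
                            out_dir = NULL,
                            test_label = NULL, control_label = NULL) {
  omics <- match.arg(omics)
  fc_stat <- match.arg(fc_stat)
  if (is.null(scaling))
    scaling <- if (omics == "metabolite") "pareto" else "center"
  scaling <- match.arg(scaling, c("pareto", "center"))
  if (is.null(fc_threshold))
    fc_threshold <- if (omics == "metabolite") 1.5 else 1.1
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  if (abundance_floor < 0) stop("abundance_floor must be non-negative")
  if (is.null(impute_value)) impute_value <- abundance_floor / 2
  if (is.null(design)) {
    if (is.null(abundance_file) || is.null(samples_file))
      stop("either a simulation design or abundance_file + samples_file ",
           "must be supplied")
  } else {
    stopifnot(inherits(design, "study_design"))
    if (is.null(test_label)) test_label <- design$conditions[1]
    if (is.null(control_label)) control_label <- design$conditions[2]
  }
  if (is.null(test_label)) test_label <- "test"
  if (is.null(control_label)) control_label <- "control"
  structure(
    list(design = design, abundance_file = abundance_file,
         samples_file = samples_file, features_file = features_file,
         omics = omics, scaling = scaling, fc_threshold = fc_threshold,
         fc_stat = fc_stat, rt_window = rt_window,
         abundance_floor = abundance_floor, impute_value = impute_value,
         n_ortho = n_ortho, folds = folds, n_perm = n_perm,
         annotate = isTRUE(annotate), seed = as.integer(seed),
         out_dir = out_dir, test_label = test_label,
         control_label = control_label),
    class = "pipeline_config"
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Simulate (or load) a feature table, filter and impute it, scale it, fit
#' the OPLS-DA, validate by permutation, call differential regulation by the
#' fold threshold x loading-significance rule, optionally assign annotation
#' tiers, and write every result table plus a machine-readable run manifest.
#' Identical config + seed gives identical outputs; on failure any partial
#' outputs written by the run are removed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a run report list: `table` (filtered), `model`,
#'   `diagnostics`, `calls`, `significant_ids`, `annotations` (or NULL),
#'   `truth` (simulation only), `files` (paths written), `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  say <- function(...) if (!quiet) message(sprintf(...))
  written <- character(0)
  out <- function(name, df) {
    p <- write_tsv(df, file.path(cfg$out_dir, name))
    written <<- c(written, p)
    p
  }

  run <- function() {
    truth <- NULL
    if (!is.null(cfg$design)) {
      sim <- generate_dataset(cfg$design)
      table <- sim$table; truth <- sim$truth
      say("simulate: %d features x %d samples", nrow(table$abundance),
          ncol(table$abundance))
    } else {
      table <- read_feature_table(cfg$abundance_file, cfg$samples_file,
                                  cfg$features_file)
      say("load: %d features x %d samples", nrow(table$abundance),
          ncol(table$abundance))
    }

    rt_window <- cfg$rt_window
    if (!is.null(rt_window) &&
        (is.null(table$feature_meta) || !"rt" %in% names(table$feature_meta))) {
      say("filter: no retention times available, skipping the RT rule")
      rt_window <- NULL
    }
    n0 <- nrow(table$abundance)
    table <- filter_features(table, rt_window = rt_window,
                             abundance_floor = cfg$abundance_floor)
    say("filter: %d of %d features retained", nrow(table$abundance), n0)
    table <- impute_missing(table, cfg$impute_value)

    X <- scale_matrix(t(table$abundance), cfg$scaling)
    labels <- table$sample_meta$condition
    fit <- fit_opls_da(X, labels, n_ortho = cfg$n_ortho, folds = cfg$folds,
                       positive_class = cfg$test_label)
    say("opls: %d orthogonal component(s), R2Y %.3f, Q2 %.3f",
        fit$model$n_ortho, fit$diagnostics$r2y, fit$diagnostics$q2)
    if (cfg$n_perm > 0) {
      fit$diagnostics$permutation <-
        permutation_test(X, labels, n_ortho = fit$model$n_ortho,
                         n_perm = cfg$n_perm, folds = cfg$folds,
                         seed = cfg$seed, positive_class = cfg$test_label)
      say("permutation: p = %.5f (%d permutations)",
          fit$diagnostics$permutation$p_value, cfg$n_perm)
    }
    sig <- significant_loadings(fit$model)
    say("significant loadings: %d feature(s)", length(sig))

    calls <- differential_analysis(
      table, sig, mode = cfg$omics, stat = cfg$fc_stat,
      threshold = cfg$fc_threshold, abundance_floor = cfg$abundance_floor,
      test_label = cfg$test_label, control_label = cfg$control_label)
    say("differential: %d regulated feature(s)", sum(calls$regulated))

    annots <- NULL
    if (cfg$annotate && !is.null(cfg$design)) {
      gen <- generate_annotation_evidence(table, seed = cfg$seed)
      annots <- assign_tiers(gen$evidence, gen$references)
      annots$intended_tier <- gen$evidence$intended_tier
      say("annotation: %d records tiered", nrow(annots))
    }

    files <- NULL
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      tf <- write_feature_table(table, cfg$out_dir, prefix = "filtered")
      written <<- c(written, tf)
      out("scores.tsv", data.frame(
        sample_id = table$sample_meta$sample_id,
        condition = labels, day = table$sample_meta$day,
        t_pred = fit$model$t_pred,
        t_ortho = if (fit$model$n_ortho) fit$model$T_ortho[, 1] else NA_real_))
      out("loadings.tsv", data.frame(
        feature_id = names(fit$model$p_pred),
        p_pred = fit$model$p_pred,
        significant = names(fit$model$p_pred) %in% sig))
      out("significant_features.tsv", data.frame(feature_id = sig))
      dg <- fit$diagnostics
      out("diagnostics.tsv", data.frame(
        r2x_pred = dg$r2x_pred,
        r2x_ortho = sum(dg$r2x_ortho),
        r2x_residual = dg$r2x_residual,
        r2y = dg$r2y, q2 = dg$q2, n_ortho = dg$n_ortho,
        cv_folds = dg$cv_folds, n_perm = cfg$n_perm,
        permutation_p = if (is.null(dg$permutation)) NA_real_
                        else dg$permutation$p_value))
      out("differential_calls.tsv", calls)
      if (!is.null(annots)) out("annotations.tsv", annots)
      if (!is.null(truth)) {
        out("ground_truth.tsv", data.frame(
          feature_id = names(truth$planted_log2fc),
          planted_log2fc = truth$planted_log2fc,
          discriminative = names(truth$planted_log2fc) %in%
            truth$discriminative_ids,
          exclusive = names(truth$planted_log2fc) %in% truth$exclusive_ids,
          time_profile = truth$time_profile))
      }
      manifest <- list(
        package = "longomix",
        version = as.character(utils::packageVersion("longomix")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = cfg$seed,
        config = cfg[setdiff(names(cfg), c("design", "out_dir"))],
        design = if (!is.null(cfg$design)) unclass(cfg$design),
        n_features_in = n0,
        n_features_retained = nrow(table$abundance),
        n_regulated = sum(calls$regulated)
      )
      mp <- file.path(cfg$out_dir, "manifest.json")
      jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                           null = "null")
      written <<- c(written, mp)
      files <- written
    }

    invisible(list(table = table, model = fit$model,
                   diagnostics = fit$diagnostics, calls = calls,
                   significant_ids = sig, annotations = annots,
                   truth = truth, files = files))
  }

  tryCatch(run(), error = function(e) {
    unlink(written)  # no partial outputs on failure
    stop(e)
  })
}
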