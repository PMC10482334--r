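#' Feature-by-sample abundance table
#'
#' The universal data container passed between pipeline stages: a numeric
#' abundance matrix (rows = metabolite features or proteins, columns =
#' samples), a per-sample design table and an optional per-feature metadata
#' table. Missing abundances (`NA`) denote signals below the detection floor.
#'
#' @param abundance Numeric matrix, features x samples. Row names are feature
#'   identifiers, column names are sample identifiers; both must be unique.
#'   Values must be non-negative or `NA`.
#' @param sample_meta Data frame with one row per sample column, containing at
#'   least `sample_id`, `condition`, `day` and `replicate`. Rows are matched to
#'   the matrix columns by `sample_id`.
#' @param feature_meta Optional data frame with one row per feature, containing
#'   at least `feature_id` and typically `rt` (retention time, minutes).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(abundance, sample_meta, feature_meta = NULL) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)) || anyDuplicated(rownames(abundance)))
    stop("abundance matrix needs unique row names (feature ids)")
  if (is.null(colnames(abundance)) || anyDuplicated(colnames(abundance)))
    stop("abundance matrix needs unique column names (sample ids)")
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative")

  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "day", "replicate")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    stop("sample_meta is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicated sample_id in sample_meta")
  if (!setequal(sample_meta$sample_id, colnames(abundance)))
    stop("sample_meta$sample_id must match the abundance column names")
  sample_meta <- sample_meta[match(colnames(abundance), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (!is.numeric(sample_meta$day)) stop("sample_meta$day must be numeric")

  if (!is.null(feature_meta)) {
    feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
    if (!"feature_id" %in% names(feature_meta))
      stop("feature_meta needs a feature_id column")
    if (!setequal(feature_meta$feature_id, rownames(abundance)))
      stop("feature_meta$feature_id must match the abundance row names")
    feature_meta <- feature_meta[match(rownames(abundance),
                                       feature_meta$feature_id), , drop = FALSE]
    rownames(feature_meta) <- NULL
  }

  structure(
    list(abundance = abundance, sample_meta = sample_meta,
         feature_meta = feature_meta),
    class = "feature_table"
  )
}

#' @export
dim.feature_table <- function(x) dim(x$abundance)

#' @export
print.feature_table <- function(x, ...) {
  d <- dim(x$abundance)
  cat(sprintf("<feature_table> %d features x %d samples\n", d[1], d[2]))
  cat("  conditions:", paste(unique(x$sample_meta$condition), collapse = ", "),
      "\n")
  cat("  days:      ", paste(sort(unique(x$sample_meta$day)), collapse = ", "),
      "\n")
  cat(sprintf("  missing:    %d values\n", sum(is.na(x$abundance))))
  invisible(x)
}

#' Subset a feature table by feature id
#'
#' @param table A [feature_table()].
#' @param ids Character vector of feature ids, or a logical/integer index along
#'   the feature axis. Feature order of the table is preserved for logical and
#'   integer indices; character ids select in the order given.
#' @return A `feature_table` with the selected features.
#' @export
subset_features <- function(table, ids) {
  stopifnot(inherits(table, "feature_table"))
  ab <- table$abundance[ids, , drop = FALSE]
  fm <- table$feature_meta
  if (!is.null(fm)) fm <- fm[match(rownames(ab), fm$feature_id), , drop = FALSE]
  feature_table(ab, table$sample_meta, fm)
}

#' Subset a feature table by sample
#'
#' @param table A [feature_table()].
#' @param idx Sample ids, or a logical/integer index along the sample axis.
#' @return A `feature_table` with the selected samples.
#' @export
subset_samples <- function(table, idx) {
  stopifnot(inherits(table, "feature_table"))
  ab <- table$abundance[, idx, drop = FALSE]
  sm <- table$sample_meta[match(colnames(ab), table$sample_meta$sample_id), ,
                          drop = FALSE]
  feature_table(ab, sm, table$feature_meta)
}

#' Write a feature table to TSV files
#'
#' Writes the abundance matrix (first column `feature_id`), the sample
#' metadata, and, when present, the feature metadata as tab-separated text.
#'
#' @param table A [feature_table()].
#' @param dir Output directory, created if needed.
#' @param prefix File-name prefix; files are `<prefix>_abundance.tsv`,
#'   `<prefix>_samples.tsv` and `<prefix>_features.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_feature_table <- function(table, dir, prefix = "table") {
  stopifnot(inherits(table, "feature_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- data.frame(feature_id = rownames(table$abundance),
                   table$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  paths <- c(
    abundance = file.path(dir, paste0(prefix, "_abundance.tsv")),
    samples   = file.path(dir, paste0(prefix, "_samples.tsv"))
  )
  utils::write.table(ab, paths[["abundance"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$sample_meta, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(table$feature_meta)) {
    paths[["features"]] <- file.path(dir, paste0(prefix, "_features.tsv"))
    utils::write.table(table$feature_meta, paths[["features"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a feature table from TSV files
#'
#' @param abundance_file TSV with a `feature_id` first column and one column
#'   per sample.
#' @param samples_file TSV with `sample_id`, `condition`, `day`, `replicate`.
#' @param features_file Optional TSV with per-feature metadata
#'   (`feature_id`, `rt`, ...).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(abundance_file, samples_file,
                               features_file = NULL) {
  ab <- utils::read.delim(abundance_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab[[1]]
  sm <- utils::read.delim(samples_file, stringsAsFactors = FALSE)
  fm <- if (!is.null(features_file))
    utils::read.delim(features_file, stringsAsFactors = FALSE)
  feature_table(m, sm, fm)
}
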