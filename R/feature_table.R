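#' Feature-by-sample table
#'
#' The shared container for microbiome and expression data: a numeric matrix
#' with features as rows and samples as columns, tagged with the scale the
#' values live on (`kind`). Counts must be non-negative integers; relative
#' abundances must sum to 1 per sample; CLR values must sum to 0 per sample.
#'
#' @param values numeric matrix, features x samples, with unique non-empty
#'   rownames (feature ids) and colnames (sample ids).
#' @param kind one of `"counts"`, `"relative_abundance"`, `"clr"`,
#'   `"log_cpm"`, `"residual"`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, kind = c("counts", "relative_abundance",
                                           "clr", "log_cpm", "residual")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("`values` contains missing entries")
  if (kind == "counts") {
    if (any(values < 0)) stop("counts must be non-negative")
    if (any(abs(values - round(values)) > 1e-8)) stop("counts must be integers")
  }
  if (kind == "relative_abundance" &&
      any(abs(colSums(values) - 1) > 1e-9))
    stop("relative-abundance columns must sum to 1")
  if (kind == "clr" && any(abs(colSums(values)) > 1e-9))
    stop("clr columns must sum to 0")
  structure(list(values = values, kind = kind), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table[%s]> %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

feature_ids <- function(t) rownames(t$values)
sample_ids <- function(t) colnames(t$values)

#' Read a feature table from TSV
#'
#' Expects features as rows, a header row of sample ids, and feature ids in
#' the first column.
#'
#' @param path path to a tab-separated file.
#' @param kind value scale, as in [feature_table()].
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, kind = "counts") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  feature_table(m, kind = kind)
}

#' Write a feature table to TSV
#'
#' @param t a `feature_table`.
#' @param path output path; the first column (named `feature_id`) holds the
#'   feature ids and remaining columns are samples.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path) {
  df <- data.frame(feature_id = feature_ids(t), t$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Per-sample metadata keyed on `sample_id`: patient id, intestinal location,
#' fixed covariates, DNA concentration and control status.
#'
#' @param path path to a tab-separated file with a `sample_id` column.
#' @return a data.frame with one row per sample.
#' @export
read_sample_frame <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_frame(df)
  df
}

validate_sample_frame <- function(df) {
  if (!"sample_id" %in% names(df)) stop("metadata must have a `sample_id` column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  invisible(df)
}

#' Align a feature table and metadata on shared samples
#'
#' @param t a `feature_table`.
#' @param samples a metadata data.frame with `sample_id`.
#' @return list with the table restricted (in metadata order) and metadata
#'   restricted to samples present in the table.
#' @export
align_samples <- function(t, samples) {
  validate_sample_frame(samples)
  shared <- intersect(samples$sample_id, sample_ids(t))
  if (length(shared) == 0) stop("no overlapping samples between table and metadata")
  t$values <- t$values[, shared, drop = FALSE]
  list(table = t, samples = samples[match(shared, samples$sample_id), , drop = FALSE])
}
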