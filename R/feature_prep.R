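#' Prevalence filter for taxa
#'
#' Keeps taxa whose per-sample relative abundance reaches `min_rel_abund` in
#' at least `ceiling(min_sample_frac * n_samples)` samples. "At least x% of
#' samples" is read with ceiling semantics on the integer sample count.
#'
#' @param t a `feature_table` of counts.
#' @param min_rel_abund minimum within-sample relative abundance (default
#'   1e-4, i.e. 0.01%).
#' @param min_sample_frac minimum fraction of samples (default 0.10).
#' @return the filtered `feature_table`, feature order preserved.
#' @export
filter_taxa_prevalence <- function(t, min_rel_abund = 1e-4,
                                   min_sample_frac = 0.10) {
  stopifnot(inherits(t, "feature_table"), t$kind == "counts")
  ra <- sweep(t$values, 2, colSums(t$values), "/")
  need <- ceiling(min_sample_frac * ncol(t$values))
  keep <- rowSums(ra >= min_rel_abund) >= need
  if (!any(keep)) stop("no features pass the prevalence filter")
  feature_table(t$values[keep, , drop = FALSE], "counts")
}

#' Prevalence filter for genes
#'
#' Keeps genes with at least `min_count` counts in at least
#' `ceiling(min_sample_frac * n_samples)` samples.
#'
#' @param t a `feature_table` of counts.
#' @param min_count minimum count per qualifying sample (default 10).
#' @param min_sample_frac minimum fraction of samples (default 0.33).
#' @return the filtered `feature_table`.
#' @export
filter_genes <- function(t, min_count = 10, min_sample_frac = 0.33) {
  stopifnot(inherits(t, "feature_table"), t$kind == "counts")
  need <- ceiling(min_sample_frac * ncol(t$values))
  keep <- rowSums(t$values >= min_count) >= need
  if (!any(keep)) stop("no features pass the count filter")
  feature_table(t$values[keep, , drop = FALSE], "counts")
}

#' Variance filter
#'
#' Removes features whose per-feature variance falls strictly below the
#' `quantile`-th empirical quantile of variances; ties at the quantile are
#' retained, so a constant table passes through unchanged.
#'
#' @param t a `feature_table` (any kind).
#' @param quantile fraction of lowest-variance features to drop (default 0.25).
#' @return the filtered `feature_table`.
#' @export
variance_filter <- function(t, quantile = 0.25) {
  stopifnot(inherits(t, "feature_table"), ncol(t$values) >= 2,
            quantile >= 0, quantile < 1)
  v <- apply(t$values, 1, stats::var)
  cut <- stats::quantile(v, quantile, names = FALSE)
  keep <- v >= cut
  if (!any(keep)) stop("no features pass the variance filter")
  out <- t
  out$values <- t$values[keep, , drop = FALSE]
  out
}

#' Total-sum scaling
#'
#' @param t a `feature_table` of counts.
#' @return a `feature_table` of relative abundances (columns sum to 1).
#' @export
tss <- function(t) {
  stopifnot(inherits(t, "feature_table"),
            t$kind %in% c("counts", "relative_abundance"))
  cs <- colSums(t$values)
  if (any(cs <= 0))
    stop("zero-sum sample(s): ",
         paste(colnames(t$values)[cs <= 0], collapse = ", "))
  feature_table(sweep(t$values, 2, cs, "/"), "relative_abundance")
}

#' Centered log-ratio transform
#'
#' Converts each column to relative abundance, adds `pseudocount` on the
#' relative-abundance scale, and returns `log(x) - mean(log(x))` per column.
#'
#' @param t a `feature_table` of counts or relative abundances.
#' @param pseudocount positive offset on the relative-abundance scale
#'   (default 1e-6, the value used for Aitchison distances here).
#' @return a `feature_table[clr]`; columns sum to 0.
#' @export
clr <- function(t, pseudocount = 1e-6) {
  stopifnot(inherits(t, "feature_table"))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("`pseudocount` must be positive")
  ra <- if (t$kind == "relative_abundance") t else tss(t)
  lx <- log(ra$values + pseudocount)
  feature_table(sweep(lx, 2, colMeans(lx), "-"), "clr")
}

#' Log counts per million
#'
#' A simple variance-stabilizing normalization for expression counts:
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`.
#'
#' @param t a `feature_table` of counts.
#' @param prior prior count (default 0.5).
#' @return a `feature_table[log_cpm]`.
#' @export
log_cpm <- function(t, prior = 0.5) {
  stopifnot(inherits(t, "feature_table"), t$kind == "counts", prior > 0)
  cs <- colSums(t$values)
  if (any(cs <= 0))
    stop("zero-sum sample(s): ",
         paste(colnames(t$values)[cs <= 0], collapse = ", "))
  m <- log2(sweep(t$values + prior, 2, cs + 2 * prior, "/") * 1e6)
  out <- t
  out$values <- m
  out$kind <- "log_cpm"
  out
}

#' Frequency-method contaminant scoring
#'
#' For each feature, over the samples where it is present, compares (in
#' log10-log10 space of relative frequency vs DNA concentration) the fit of a
#' contaminant model (slope fixed at -1, free intercept) against a
#' non-contaminant model (slope 0, free intercept). The score is the p-value
#' of the residual-sum-of-squares ratio under an F(m-1, m-1) reference; small
#' scores indicate contamination. Features present in fewer than 5 samples
#' with known concentration are reported as not evaluable and never flagged.
#'
#' @param t a `feature_table` of counts.
#' @param dna_conc named (by sample id) or table-ordered vector of positive
#'   DNA concentrations.
#' @param threshold classification threshold on the score (default 0.1).
#' @return data.frame with one row per feature: `feature_id`, `score`,
#'   `slope` (free-slope OLS estimate), `n_samples_used`, `evaluable`,
#'   `contaminant`.
#' @export
frequency_contaminant_score <- function(t, dna_conc, threshold = 0.1) {
  stopifnot(inherits(t, "feature_table"), t$kind == "counts")
  if (!is.null(names(dna_conc))) {
    missing <- setdiff(colnames(t$values), names(dna_conc))
    if (length(missing) > 0)
      stop("missing DNA concentration for: ", paste(missing, collapse = ", "))
    dna_conc <- dna_conc[colnames(t$values)]
  }
  if (length(dna_conc) != ncol(t$values))
    stop("`dna_conc` must have one value per sample")
  if (any(!is.finite(dna_conc)) || any(dna_conc <= 0))
    stop("DNA concentrations must be positive")
  freq <- sweep(t$values, 2, colSums(t$values), "/")
  lc_all <- log10(dna_conc)
  res <- lapply(seq_len(nrow(freq)), function(i) {
    use <- freq[i, ] > 0
    m <- sum(use)
    if (m < 5)
      return(data.frame(feature_id = rownames(freq)[i], score = NA_real_,
                        slope = NA_real_, n_samples_used = m,
                        evaluable = FALSE, contaminant = FALSE))
    lf <- log10(freq[i, use])
    lc <- lc_all[use]
    ss_contam <- sum((lf + lc - mean(lf + lc))^2)    # slope -1, intercept fit
    ss_noncon <- sum((lf - mean(lf))^2)              # slope 0, intercept fit
    score <- if (ss_noncon == 0 && ss_contam == 0) 1
             else stats::pf(ss_contam / ss_noncon, m - 1, m - 1)
    slope <- if (stats::var(lc) > 0) stats::cov(lf, lc) / stats::var(lc) else NA_real_
    data.frame(feature_id = rownames(freq)[i], score = score, slope = slope,
               n_samples_used = m, evaluable = TRUE,
               contaminant = is.finite(score) && score < threshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
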