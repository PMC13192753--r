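#' Covariate design for mixed-model residualization
#'
#' @param samples metadata data.frame (one row per sample, in the column order
#'   of the response matrices).
#' @param covariates character vector of fixed-covariate column names (may be
#'   empty: intercept-only design).
#' @param patient_col name of the patient-id column used as the random
#'   intercept grouping (default `"patient_id"`).
#' @return a `covariate_design` list with the fixed model matrix (with
#'   intercept) and the patient grouping factor.
#' @export
covariate_design <- function(samples, covariates = character(),
                             patient_col = "patient_id") {
  stopifnot(is.data.frame(samples))
  missing <- setdiff(c(covariates, patient_col), names(samples))
  if (length(missing) > 0)
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  fml <- if (length(covariates) == 0) ~1 else
    stats::reformulate(covariates)
  X <- stats::model.matrix(fml, data = samples)
  if (nrow(X) != nrow(samples))
    stop("missing values in covariates: ",
         paste(covariates[colSums(is.na(samples[covariates])) > 0], collapse = ", "))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient fixed design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  if (anyNA(samples[[patient_col]]))
    stop("missing patient ids")
  structure(list(fixed = X, patient = factor(samples[[patient_col]]),
                 covariates = covariates),
            class = "covariate_design")
}

#' Residualize features on covariates with a patient random intercept
#'
#' Fits, per feature, a linear mixed model with the design's fixed effects and
#' a random intercept per patient (REML), and returns marginal residuals
#' (observed minus the fixed-effect fit), so patient-level variation is
#' retained unless `conditional = TRUE`. Falls back to ordinary least squares,
#' with a warning, when the random-intercept variance is estimated at zero or
#' the mixed fit fails (including the degenerate one-sample-per-patient case).
#'
#' @param y a `feature_table` or numeric matrix, features x samples.
#' @param design a [covariate_design()] whose rows match `y`'s columns.
#' @param conditional if `TRUE`, also subtract the predicted random effects.
#' @return a `feature_table[residual]` of the same shape as `y`.
#' @export
lmm_residualize <- function(y, design, conditional = FALSE) {
  m <- if (inherits(y, "feature_table")) y$values else y
  stopifnot(is.matrix(m), inherits(design, "covariate_design"))
  if (ncol(m) != nrow(design$fixed))
    stop("design rows must match response columns")
  if (ncol(m) <= ncol(design$fixed))
    stop("need more samples than fixed covariates")
  X <- design$fixed
  g <- design$patient
  res <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  n_fallback <- 0L
  singleton <- !any(duplicated(g))
  for (i in seq_len(nrow(m))) {
    yi <- m[i, ]
    fit <- if (singleton) NULL else tryCatch(
      suppressMessages(lme4::lmer(
        yi ~ 0 + X + (1 | g), REML = TRUE,
        control = lme4::lmerControl(calc.derivs = FALSE,
                                    check.conv.singular = "ignore"))),
      error = function(e) NULL)
    use_lmm <- !is.null(fit) &&
      lme4::VarCorr(fit)$g[1, 1] > 0
    if (use_lmm) {
      beta <- lme4::fixef(fit)
      r <- yi - drop(X %*% beta)
      if (conditional) {
        b <- lme4::ranef(fit)$g
        r <- r - b[as.character(g), 1]
      }
    } else {
      n_fallback <- n_fallback + 1L
      r <- stats::lm.fit(X, yi)$residuals
    }
    res[i, ] <- r
  }
  if (n_fallback > 0)
    warning(sprintf("OLS fallback for %d of %d features (zero or failed random-effect variance)",
                    n_fallback, nrow(m)))
  feature_table(sweep(res, 2, 0, "+"), "residual")
}

#' CLR differential abundance across locations (mixed model)
#'
#' Per taxon, fits `clr ~ location + covariates + (1 | patient)` by REML and
#' reports, for every non-reference location level, the coefficient, its
#' standard error, a Wald t p-value with Satterthwaite degrees of freedom, and
#' a Benjamini-Hochberg q-value computed across taxa within each contrast.
#'
#' @param clr_taxa a `feature_table[clr]` (taxa x samples).
#' @param location per-sample location labels (character or factor).
#' @param design a [covariate_design()] aligned to the samples; its fixed part
#'   must not already contain the location.
#' @param reference_level location level used as baseline (default: first).
#' @return data.frame with columns `feature`, `contrast`, `coef`, `stderr`,
#'   `N`, `N.not.0`, `pval`, `qval`.
#' @export
lmm_differential_abundance <- function(clr_taxa, location, design,
                                       reference_level = NULL) {
  m <- if (inherits(clr_taxa, "feature_table")) clr_taxa$values else clr_taxa
  loc <- factor(location)
  if (nlevels(loc) < 2) stop("location must have at least 2 levels")
  if (!is.null(reference_level)) loc <- stats::relevel(loc, reference_level)
  stopifnot(inherits(design, "covariate_design"), ncol(m) == length(loc))
  # fixed design: intercept + location contrasts + covariates (sans intercept)
  L <- stats::model.matrix(~loc)
  X <- cbind(L, design$fixed[, setdiff(colnames(design$fixed), "(Intercept)"),
                             drop = FALSE])
  loc_cols <- colnames(L)[-1]
  g <- design$patient
  singleton <- !any(duplicated(g))
  rows <- list()
  for (i in seq_len(nrow(m))) {
    yi <- m[i, ]
    cf <- NULL
    if (!singleton) {
      fit <- tryCatch(
        suppressMessages(lmerTest::lmer(
          yi ~ 0 + X + (1 | g), REML = TRUE,
          control = lme4::lmerControl(calc.derivs = FALSE,
                                      check.conv.singular = "ignore"))),
        error = function(e) NULL)
      if (!is.null(fit) && lme4::VarCorr(fit)$g[1, 1] > 0) {
        s <- summary(fit)$coefficients
        rownames(s) <- sub("^X", "", rownames(s))
        cf <- s[loc_cols, c("Estimate", "Std. Error", "Pr(>|t|)"), drop = FALSE]
      }
    }
    if (is.null(cf)) {
      ols <- stats::lm(yi ~ 0 + X)
      s <- summary(ols)$coefficients
      rownames(s) <- sub("^X", "", rownames(s))
      cf <- s[loc_cols, c("Estimate", "Std. Error", "Pr(>|t|)"), drop = FALSE]
    }
    rows[[i]] <- data.frame(feature = rownames(m)[i],
                            contrast = sub("^loc", "", loc_cols),
                            coef = cf[, 1], stderr = cf[, 2],
                            N = length(yi), N.not.0 = sum(yi != 0),
                            pval = cf[, 3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$qval <- stats::ave(out$pval, out$contrast,
                         FUN = function(p) bh_adjust(p))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR q-values: `q_i = min_{j: p_j >= p_i} min(1, m * p_j / rank_j)`.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Write a differential-abundance table to TSV
#'
#' Columns mirror the conventional supplementary-table schema
#' (coef, stderr, N, N.not.0, pval, qval).
#'
#' @param result output of [lmm_differential_abundance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_result <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
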