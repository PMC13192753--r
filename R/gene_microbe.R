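#' Per-microbe elastic-net gene selection
#'
#' Regresses one microbe's CLR residual on the gene residual matrix with the
#' elastic-net penalty
#' `(1/(2n)) ||y - b0 - X b||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)`,
#' tuning the mixing parameter and the penalty strength jointly by k-fold
#' cross-validation repeated several times (loss: RMSE, averaged over
#' repeats x folds). The final coefficients come from a full-data refit at the
#' selected pair, reported on the original predictor scale. Covariates are
#' expected to have been regressed out of both `y` and `X` upstream and are
#' not part of the model.
#'
#' @param y numeric response vector (one microbe, CLR residual per sample).
#' @param X samples x genes numeric matrix; standardized internally.
#' @param alpha_grid mixing parameters in (0, 1] (default 0.1..1 by 0.1).
#' @param n_lambda lambda path length (default 100); the path is log-spaced
#'   over 4 decades down from `max |X'y| / (n * alpha)`.
#' @param folds,repeats cross-validation folds (default 5) and repeats
#'   (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return an `elastic_net_fit`: list with `intercept`, `coefficients` (named,
#'   original scale), `alpha`, `lambda`, `cv_rmse` (grid data.frame),
#'   `n_nonzero`.
#' @export
fit_elastic_net <- function(y, X, alpha_grid = seq(0.1, 1, by = 0.1),
                            n_lambda = 100, folds = 5, repeats = 5,
                            seed = 1L) {
  stopifnot(is.numeric(y), is.matrix(X), length(y) == nrow(X))
  n <- length(y)
  if (folds > n) stop("more folds than samples")
  if (n < folds) stop("need at least `folds` samples")
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (any(alpha_grid <= 0 | alpha_grid > 1)) stop("alpha must lie in (0, 1]")
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  sx <- standardize_columns(X, warn = FALSE)
  Xs <- sx$M
  yc <- y - mean(y)

  set.seed(seed)
  fold_id <- replicate(repeats,
                       sample(rep_len(seq_len(folds), n)), simplify = FALSE)

  grid <- list()
  for (a in alpha_grid) {
    lambda_max <- max(abs(crossprod(Xs, yc))) / (n * a)
    lambda <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                      length.out = n_lambda))
    se <- matrix(0, n_lambda, 0)
    for (r in seq_len(repeats)) for (f in seq_len(folds)) {
      test <- fold_id[[r]] == f
      fit <- glmnet::glmnet(Xs[!test, , drop = FALSE], yc[!test],
                            alpha = a, lambda = lambda,
                            standardize = FALSE, family = "gaussian")
      pred <- stats::predict(fit, Xs[test, , drop = FALSE], s = lambda,
                             exact = FALSE)
      se <- cbind(se, colMeans((pred - yc[test])^2))
    }
    grid[[length(grid) + 1]] <- data.frame(alpha = a, lambda = lambda,
                                           rmse = sqrt(rowMeans(se)))
  }
  grid <- do.call(rbind, grid)
  # ties toward stronger (sparser) regularization, then larger alpha
  ord <- order(grid$rmse, -grid$lambda, -grid$alpha)
  best <- grid[ord[1], ]

  full <- glmnet::glmnet(Xs, yc, alpha = best$alpha,
                         lambda = best$lambda, standardize = FALSE,
                         family = "gaussian")
  beta_std <- drop(as.matrix(full$beta))
  beta <- beta_std / sx$sd
  names(beta) <- names(sx$sd)
  intercept <- mean(y) - sum(beta * sx$mean)
  structure(list(intercept = intercept, coefficients = beta,
                 alpha = best$alpha, lambda = best$lambda,
                 cv_rmse = grid, n_nonzero = sum(beta != 0)),
            class = "elastic_net_fit")
}

#' @export
print.elastic_net_fit <- function(x, ...) {
  cat(sprintf("<elastic_net_fit> alpha = %.2f, lambda = %.4g, %d nonzero of %d genes\n",
              x$alpha, x$lambda, x$n_nonzero, length(x$coefficients)))
  invisible(x)
}

#' Collect gene-microbe pairs from elastic-net fits
#'
#' One row per (microbe, gene with nonzero coefficient), sorted by microbe
#' then absolute coefficient (descending). If the residual matrices are
#' supplied, each pair is annotated with its post-hoc Pearson correlation and
#' two-sided p-value via [pair_correlation()].
#'
#' @param fits named list of `elastic_net_fit` objects (names = microbe ids).
#' @param X optional samples x genes matrix for post-hoc correlations.
#' @param Z optional samples x microbes matrix (same samples as `X`).
#' @param region optional region label recorded on every row.
#' @return data.frame with columns `gene`, `microbe`, `coefficient`, `rho`,
#'   `pval`, `region`.
#' @export
extract_pairs <- function(fits, X = NULL, Z = NULL, region = NA_character_) {
  if (length(fits) == 0) stop("`fits` must be non-empty")
  if (is.null(names(fits))) names(fits) <- paste0("microbe", seq_along(fits))
  rows <- lapply(names(fits), function(mb) {
    b <- fits[[mb]]$coefficients
    nz <- b[b != 0]
    if (length(nz) == 0) return(NULL)
    nz <- nz[order(-abs(nz))]
    df <- data.frame(gene = names(nz), microbe = mb, coefficient = unname(nz),
                     rho = NA_real_, pval = NA_real_, region = region,
                     stringsAsFactors = FALSE)
    if (!is.null(X) && !is.null(Z)) {
      for (r in seq_len(nrow(df))) {
        pc <- pair_correlation(X[, df$gene[r]], Z[, mb])
        df$rho[r] <- pc$rho
        df$pval[r] <- pc$p
      }
    }
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), microbe = character(),
                      coefficient = numeric(), rho = numeric(),
                      pval = numeric(), region = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of a gene-microbe pair
#'
#' @param gene,microbe paired numeric vectors (>= 3 observations).
#' @return list with `rho` and the two-sided t-test `p` (df = n - 2).
#' @export
pair_correlation <- function(gene, microbe) {
  if (length(gene) != length(microbe) || length(gene) < 3)
    stop("need >= 3 paired observations")
  if (stats::sd(gene) == 0 || stats::sd(microbe) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(gene, microbe, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Write a gene-microbe pair table to TSV
#'
#' @param pairs output of [extract_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
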