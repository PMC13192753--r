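#' Soft-thresholding operator
#'
#' `sign(x) * max(|x| - delta, 0)`, the proximal operator of the lasso penalty
#' and the elementwise shrinkage step of the penalized matrix decomposition.
#'
#' @param x numeric vector.
#' @param delta non-negative threshold.
#' @return shrunken vector.
#' @export
soft_threshold <- function(x, delta) {
  if (delta < 0) stop("delta must be non-negative")
  sign(x) * pmax(abs(x) - delta, 0)
}

# smallest delta such that the L2-normalized soft-thresholded vector has
# L1 norm <= c. The L1/L2 ratio of soft_threshold(x, delta) is piecewise
# smooth between the sorted |x| knots; with k entries surviving and partial
# sums S1, S2 of the k largest |x|, the crossing solves the quadratic
# (S1 - k d)^2 = c^2 (S2 - 2 d S1 + k d^2), whose smaller root is
# d = S1/k - (c/k) sqrt((k S2 - S1^2) / (k - c^2)). Falls back to bisection
# if no segment accepts its root numerically.
l1_constrained_unit <- function(x, c_bound) {
  ax <- abs(x)
  n2 <- sqrt(sum(ax^2))
  if (!is.finite(n2) || n2 == 0) return(x * 0)
  if (sum(ax) / n2 <= c_bound) return(x / n2)
  a <- sort.int(ax, decreasing = TRUE, method = "quick")
  k <- seq_along(a)
  S1 <- cumsum(a)
  S2 <- cumsum(a^2)
  c2 <- c_bound^2
  disc <- (k * S2 - S1^2) / (k - c2)
  disc[disc < 0] <- 0
  delta <- S1 / k - (c_bound / k) * sqrt(disc)
  seg <- k > c2 & is.finite(delta) & delta >= 0 &
    delta < a & delta >= c(a[-1], 0)
  d <- if (any(seg)) delta[which.max(seg)] else l1_delta_bisect(x, c_bound)
  u <- ax - d
  u <- sign(x) * u * (u > 0)
  u / sqrt(sum(u^2))
}

l1_delta_bisect <- function(x, c_bound, iter = 60) {
  lo <- 0
  hi <- max(abs(x))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    u <- soft_threshold(x, mid)
    n2 <- sqrt(sum(u^2))
    if (n2 > 0 && sum(abs(u)) / n2 > c_bound) lo <- mid else hi <- mid
  }
  hi
}

#' Rank-one penalized matrix decomposition
#'
#' Alternating soft-thresholded power iterations on a cross-product matrix:
#' `v` is initialized to the leading right singular vector; each update sets
#' `u` to the L2-normalized soft-thresholding of `K v`, with the threshold
#' chosen by bisection as the smallest value satisfying
#' `||u||_1 <= c1_frac * sqrt(nrow(K))` (symmetrically for `v`). This is the
#' computational core of sparse CCA: applied to the standardized
#' gene-by-taxon cross-product it yields one sparse canonical component.
#'
#' @param K_cross numeric matrix (e.g. genes x taxa cross-product).
#' @param c1_frac,c2_frac L1 bounds as fractions of `sqrt(dimension)`,
#'   in (0, 1]; 1 disables sparsity and recovers the leading singular vectors.
#' @param tol convergence tolerance on the change in `v`.
#' @param max_iter maximum alternations; if exceeded the result is returned
#'   with `converged = FALSE` and a warning.
#' @return list with unit-norm sparse `u`, `v`, the factor value
#'   `d = t(u) K v`, `converged`, `iterations`.
#' @export
pmd_rank_one <- function(K_cross, c1_frac, c2_frac, tol = 1e-6, max_iter = 200) {
  stopifnot(is.matrix(K_cross))
  if (c1_frac <= 0 || c1_frac > 1 || c2_frac <= 0 || c2_frac > 1)
    stop("penalty fractions must lie in (0, 1]")
  # an L2-unit vector always has L1 >= 1, so the bound is clamped to 1
  c1 <- max(1, c1_frac * sqrt(nrow(K_cross)))
  c2 <- max(1, c2_frac * sqrt(ncol(K_cross)))
  v <- svd(K_cross, nu = 0, nv = 1)$v[, 1]
  u <- rep(0, nrow(K_cross))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    u <- l1_constrained_unit(drop(K_cross %*% v), c1)
    v_new <- l1_constrained_unit(drop(crossprod(K_cross, u)), c2)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    v <- v_new
  }
  if (!converged)
    warning("pmd_rank_one: max_iter reached without convergence")
  list(u = u, v = v, d = drop(crossprod(u, K_cross %*% v)),
       converged = converged, iterations = it)
}

# column-standardize, dropping zero-variance columns with a warning
standardize_columns <- function(M, warn = TRUE) {
  mu <- colMeans(M)
  sd <- sqrt(pmax(colMeans(M^2) - mu^2, 0) * nrow(M) / (nrow(M) - 1))
  drop_ix <- which(sd <= 1e-10 * pmax(abs(mu), 1) | !is.finite(sd))
  if (length(drop_ix) > 0) {
    if (warn)
      warning("dropping zero-variance column(s): ",
              paste(colnames(M)[drop_ix], collapse = ", "))
    M <- M[, -drop_ix, drop = FALSE]
    mu <- mu[-drop_ix]
    sd <- sd[-drop_ix]
  }
  list(M = sweep(sweep(M, 2, mu, "-"), 2, sd, "/"), mean = mu, sd = sd)
}

#' Fit a sparse CCA model by successive penalized rank-one decompositions
#'
#' Both matrices are column-standardized; components are extracted from the
#' cross-product `t(X) Z` by [pmd_rank_one()], deflating
#' `K <- K - d u v'` after each component. Gene loadings `u_k` and taxon
#' loadings `v_k` have unit L2 norm and L1 norm bounded by
#' `c_frac * sqrt(dimension)`.
#'
#' @param X samples x genes matrix (typically covariate residuals).
#' @param Z samples x taxa matrix (typically CLR residuals).
#' @param c1_frac,c2_frac penalty fractions in (0, 1] for genes and taxa.
#' @param K number of components (default 10).
#' @return a `sparse_cca_model`: list with loading matrices `u`
#'   (genes x K), `v` (taxa x K), singular values `d`, penalties, and the
#'   standardization constants.
#' @export
fit_sparse_cca <- function(X, Z, c1_frac, c2_frac, K = 10) {
  stopifnot(is.matrix(X), is.matrix(Z), nrow(X) == nrow(Z))
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  sx <- standardize_columns(X)
  sz <- standardize_columns(Z)
  if (K > min(ncol(sx$M), ncol(sz$M)))
    stop("K exceeds the smaller feature dimension")
  Kc <- crossprod(sx$M, sz$M)
  u <- matrix(0, ncol(sx$M), K, dimnames = list(colnames(sx$M), NULL))
  v <- matrix(0, ncol(sz$M), K, dimnames = list(colnames(sz$M), NULL))
  d <- numeric(K)
  for (k in seq_len(K)) {
    f <- pmd_rank_one(Kc, c1_frac, c2_frac)
    u[, k] <- f$u
    v[, k] <- f$v
    d[k] <- f$d
    Kc <- Kc - f$d * tcrossprod(f$u, f$v)
  }
  structure(list(u = u, v = v, d = d, c1_frac = c1_frac, c2_frac = c2_frac,
                 K = K, x_center = sx$mean, x_scale = sx$sd,
                 z_center = sz$mean, z_scale = sz$sd),
            class = "sparse_cca_model")
}

#' @export
print.sparse_cca_model <- function(x, ...) {
  cat(sprintf("<sparse_cca_model> K = %d, penalties (%.2f, %.2f)\n",
              x$K, x$c1_frac, x$c2_frac))
  cat(sprintf("  nonzero loadings per component: genes %s | taxa %s\n",
              paste(colSums(x$u != 0), collapse = ","),
              paste(colSums(x$v != 0), collapse = ",")))
  invisible(x)
}

# name columns and drop zero-variance ones once, so full-data and
# leave-one-out fits index features consistently by name
drop_zero_variance <- function(X, Z) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  sdx <- apply(X, 2, stats::sd)
  sdz <- apply(Z, 2, stats::sd)
  if (any(sdx == 0) || any(sdz == 0))
    warning("dropping zero-variance column(s) before cross-validation")
  list(X = X[, sdx > 0, drop = FALSE], Z = Z[, sdz > 0, drop = FALSE])
}

# held-out canonical variate pairs for component 1..K via LOOCV,
# sign-aligned to the full-data loadings
loocv_variates <- function(X, Z, c1_frac, c2_frac, K, full) {
  n <- nrow(X)
  xv <- matrix(NA_real_, n, K)
  zv <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    sx <- standardize_columns(X[-i, , drop = FALSE], warn = FALSE)
    sz <- standardize_columns(Z[-i, , drop = FALSE], warn = FALSE)
    keep_x <- match(names(sx$mean), colnames(X))
    keep_z <- match(names(sz$mean), colnames(Z))
    Kc <- crossprod(sx$M, sz$M)
    xi <- (X[i, keep_x] - sx$mean) / sx$sd
    zi <- (Z[i, keep_z] - sz$mean) / sz$sd
    for (k in seq_len(K)) {
      f <- pmd_rank_one(Kc, c1_frac, c2_frac)
      su <- sign(sum(f$u * full$u[keep_x, k]))
      sv <- sign(sum(f$v * full$v[keep_z, k]))
      if (su == 0) su <- 1
      if (sv == 0) sv <- 1
      xv[i, k] <- sum(xi * f$u) * su
      zv[i, k] <- sum(zi * f$v) * sv
      Kc <- Kc - f$d * tcrossprod(f$u, f$v)
    }
  }
  list(x = xv, z = zv)
}

#' Tune sparse CCA penalties by leave-one-out cross-validation
#'
#' For every penalty pair on the grid, refits component 1 on each
#' leave-one-out training set, forms the held-out canonical variate pair
#' (sign-aligned to the full-data loadings), and scores the pair by the
#' Pearson correlation of the n held-out pairs. The pair with the greatest
#' correlation wins; ties break toward the sparsest pair (smallest
#' `c1_frac + c2_frac`), then toward smaller `c1_frac`.
#'
#' @inheritParams fit_sparse_cca
#' @param grid data.frame with columns `c1_frac`, `c2_frac`, or a numeric
#'   vector of fractions expanded to its Cartesian square. Default
#'   `seq(0.1, 1, by = 0.1)` squared.
#' @return list with `c1_frac`, `c2_frac`, `score`, and the full `grid`
#'   data.frame with per-point scores.
#' @export
tune_penalties_loocv <- function(X, Z, grid = seq(0.1, 1, by = 0.1)) {
  if (is.numeric(grid))
    grid <- expand.grid(c1_frac = grid, c2_frac = grid)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1,
            all(c("c1_frac", "c2_frac") %in% names(grid)))
  prep <- drop_zero_variance(X, Z)
  X <- prep$X
  Z <- prep$Z
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    full <- fit_sparse_cca(X, Z, grid$c1_frac[g], grid$c2_frac[g], K = 1)
    hv <- loocv_variates(X, Z, grid$c1_frac[g], grid$c2_frac[g], 1, full)
    scores[g] <- if (stats::sd(hv$x[, 1]) == 0 || stats::sd(hv$z[, 1]) == 0)
      NA_real_ else stats::cor(hv$x[, 1], hv$z[, 1])
  }
  if (all(is.na(scores)))
    stop("all grid scores undefined (constant held-out variates)")
  grid$score <- scores
  ord <- order(-scores, grid$c1_frac + grid$c2_frac, grid$c1_frac)
  best <- ord[1]
  list(c1_frac = grid$c1_frac[best], c2_frac = grid$c2_frac[best],
       score = scores[best], grid = grid)
}

#' LOOCV significance of sparse CCA components
#'
#' Refits all `K` components on each leave-one-out training set (penalties
#' fixed), collects the held-out canonical variate pairs per component
#' (matched by extraction order, sign-aligned to the full-data loadings),
#' computes the Pearson correlation and its two-sided t p-value (df = n - 2)
#' per component, adjusts across the K components by Benjamini-Hochberg, and
#' flags components with adjusted p below `alpha`.
#'
#' @inheritParams fit_sparse_cca
#' @param alpha significance cutoff on the adjusted p-value (default 0.1).
#' @return data.frame with one row per component: `component`, `rho`, `pval`,
#'   `qval`, `significant`, plus attributes `variates` (list of the held-out
#'   pair matrices) and `model` (the full-data fit).
#' @export
component_significance_loocv <- function(X, Z, c1_frac, c2_frac, K = 10,
                                         alpha = 0.1) {
  n <- nrow(X)
  # folds hold n-1 samples and the p-value needs df = n-2 >= 2
  if (n < 4) stop("need at least 4 samples for LOOCV significance")
  prep <- drop_zero_variance(X, Z)
  X <- prep$X
  Z <- prep$Z
  if (K > min(ncol(X), ncol(Z))) stop("K exceeds the smaller feature dimension")
  full <- fit_sparse_cca(X, Z, c1_frac, c2_frac, K = K)
  hv <- loocv_variates(X, Z, c1_frac, c2_frac, K, full)
  rho <- numeric(K)
  pval <- numeric(K)
  for (k in seq_len(K)) {
    if (stats::sd(hv$x[, k]) == 0 || stats::sd(hv$z[, k]) == 0) {
      rho[k] <- 0
      pval[k] <- 1
    } else {
      r <- stats::cor(hv$x[, k], hv$z[, k])
      tt <- r * sqrt((n - 2) / (1 - r^2))
      rho[k] <- r
      pval[k] <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  qval <- bh_adjust(pval)
  out <- data.frame(component = seq_len(K), rho = rho, pval = pval,
                    qval = qval, significant = qval < alpha)
  attr(out, "variates") <- hv
  attr(out, "model") <- full
  out
}

#' Write sparse CCA loadings to a long-format TSV
#'
#' One row per nonzero loading: component, feature id, loading, modality.
#'
#' @param model a `sparse_cca_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sparse_cca_loadings <- function(model, path) {
  long <- function(m, modality) {
    ix <- which(m != 0, arr.ind = TRUE)
    data.frame(component = ix[, 2], feature_id = rownames(m)[ix[, 1]],
               loading = m[ix], modality = modality, stringsAsFactors = FALSE)
  }
  df <- rbind(long(model$u, "gene"), long(model$v, "taxon"))
  df <- df[order(df$component, df$modality, -abs(df$loading)), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
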