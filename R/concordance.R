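#' Principal coordinates analysis
#'
#' Double-centers `-0.5 * d^2`, eigendecomposes, and returns coordinates on
#' all positive-eigenvalue axes (eigenvectors scaled by the square root of
#' their eigenvalues). Negative eigenvalues are dropped with a warning giving
#' their share of the total absolute eigenvalue mass.
#'
#' @param d a `dist` object or a symmetric matrix of sample dissimilarities.
#' @return an `ordination`: list with `coordinates` (samples x axes),
#'   `eigenvalues`, `proportion_explained`, `sample_ids`.
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(dm)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  B <- -0.5 * dm^2
  J <- diag(n) - 1 / n
  B <- J %*% B %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  neg_mass <- sum(abs(e$values[e$values < -tol]))
  if (neg_mass > 0)
    warning(sprintf("dropping negative eigenvalues (%.2f%% of eigenvalue mass)",
                    100 * neg_mass / sum(abs(e$values))))
  lam <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), length(lam))
  rownames(coords) <- ids
  colnames(coords) <- if (length(lam)) paste0("PCo", seq_along(lam)) else character()
  structure(list(coordinates = coords, eigenvalues = lam,
                 proportion_explained = if (length(lam)) lam / sum(lam) else numeric(),
                 sample_ids = ids),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples, %d axes\n",
              length(x$sample_ids), ncol(x$coordinates)))
  invisible(x)
}

# center and scale a coordinate matrix to unit total sum of squares
procrustes_normalize <- function(m) {
  m <- sweep(m, 2, colMeans(m), "-")
  ss <- sum(m^2)
  if (ss == 0) stop("degenerate configuration (zero spread)")
  m / sqrt(ss)
}

# align two ordinations on shared samples, pad axes with zero columns
procrustes_prepare <- function(a, b) {
  stopifnot(inherits(a, "ordination"), inherits(b, "ordination"))
  shared <- intersect(a$sample_ids, b$sample_ids)
  if (length(shared) < 3) stop("need at least 3 shared samples")
  A <- a$coordinates[shared, , drop = FALSE]
  B <- b$coordinates[shared, , drop = FALSE]
  w <- max(ncol(A), ncol(B))
  pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
  list(A = procrustes_normalize(pad(A)), B = procrustes_normalize(pad(B)),
       samples = shared)
}

#' Symmetric Procrustes superimposition
#'
#' Centers both configurations, scales each to unit total sum of squares, and
#' rotates one onto the other using the singular value decomposition of the
#' cross-product. The concordance statistic is `rho = sum of singular values`
#' and the residual is `m12_squared = 1 - rho^2`. Symmetric normalization
#' makes the statistic independent of argument order.
#'
#' @param a,b `ordination` objects sharing at least 3 samples; axis counts may
#'   differ (the narrower configuration is padded with zero columns).
#' @return a `procrustes_result`: list with `rho`, `m12_squared`, `rotation`,
#'   `n_samples`, and (after the permutation test) `p_value`, `n_permutations`.
#' @export
procrustes_fit <- function(a, b) {
  pr <- procrustes_prepare(a, b)
  sv <- svd(crossprod(pr$A, pr$B))
  rho <- sum(sv$d)
  structure(list(rho = rho, m12_squared = 1 - rho^2,
                 rotation = sv$v %*% t(sv$u),
                 n_samples = length(pr$samples),
                 p_value = NA_real_, n_permutations = 0L),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes> rho = %.4f, m12^2 = %.4f", x$rho, x$m12_squared))
  if (!is.na(x$p_value))
    cat(sprintf(", p = %.3g (%d permutations)", x$p_value, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Procrustes permutation test of concordance
#'
#' Permutes the row order of `b`'s configuration `n_perm` times, recomputes
#' the symmetric Procrustes `rho` for each permutation, and returns the
#' add-one permutation p-value
#' `p = (#\{permuted rho >= observed rho\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams procrustes_fit
#' @param n_perm number of row permutations (default 99999).
#' @param seed integer seed; the test is deterministic given it.
#' @return a `procrustes_result` with `p_value` and `n_permutations` filled in.
#' @export
procrustes_permutation_test <- function(a, b, n_perm = 99999, seed = 1L) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  pr <- procrustes_prepare(a, b)
  obs <- procrustes_fit(a, b)
  set.seed(seed)
  At <- t(pr$A)
  B <- pr$B
  n <- nrow(B)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    r <- sum(La.svd(At %*% B[sample.int(n), , drop = FALSE],
                    nu = 0, nv = 0)$d)
    if (r >= obs$rho - 1e-12) exceed <- exceed + 1L
  }
  obs$p_value <- (exceed + 1) / (n_perm + 1)
  obs$n_permutations <- n_perm
  obs
}

#' Write an ordination to TSV (coordinates plus an eigenvalue row block)
#'
#' @param ord an `ordination`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ord, path) {
  df <- data.frame(sample_id = ord$sample_ids, ord$coordinates,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  eig_path <- sub("(\\.[^.]+)?$", "_eigenvalues\\1", path)
  utils::write.table(data.frame(axis = colnames(ord$coordinates),
                                eigenvalue = ord$eigenvalues,
                                proportion = ord$proportion_explained),
                     eig_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
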