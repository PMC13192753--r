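test_that("soft thresholding shrinks elementwise", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(c(-3, 0.2, 4), 0), c(-3, 0.2, 4))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("rank-one PMD reduces to the leading singular vectors without sparsity", {
  set.seed(1)
  for (i in 1:20) {
    K <- matrix(rnorm(15 * 8), 15, 8)
    f <- pmd_rank_one(K, 1, 1)
    s <- svd(K)
    expect_equal(f$d, s$d[1], tolerance = 1e-5)
    expect_lt(min(max(abs(f$u - s$u[, 1])), max(abs(f$u + s$u[, 1]))), 1e-5)
    expect_lt(min(max(abs(f$v - s$v[, 1])), max(abs(f$v + s$v[, 1]))), 1e-5)
  }
  # exact rank-one input
  a <- rnorm(10); a <- a / sqrt(sum(a^2))
  b <- rnorm(6); b <- b / sqrt(sum(b^2))
  f <- pmd_rank_one(4.2 * tcrossprod(a, b), 1, 1)
  expect_equal(f$d, 4.2, tolerance = 1e-6)
})

test_that("strong penalties isolate a dominant entry", {
  # enumeration oracle on a 5 x 4 matrix: with penalties at the minimum
  # feasible L1 bound, the best single-support solution is the largest entry
  K <- matrix(0.1, 5, 4)
  K[3, 2] <- 5
  K[1, 4] <- 1.5
  f <- pmd_rank_one(K, 1 / sqrt(5) + 1e-9, 1 / sqrt(4) + 1e-9)
  best <- which(abs(K) == max(abs(K)), arr.ind = TRUE)
  expect_equal(abs(f$u), as.numeric(seq_len(5) == best[1]), tolerance = 1e-6)
  expect_equal(abs(f$v), as.numeric(seq_len(4) == best[2]), tolerance = 1e-6)
  expect_equal(f$d, 5, tolerance = 1e-6)
})

test_that("sign symmetry: negating the input flips loadings but not d", {
  set.seed(3)
  K <- matrix(rnorm(40), 8, 5)
  f1 <- pmd_rank_one(K, 0.6, 0.6)
  f2 <- pmd_rank_one(-K, 0.6, 0.6)
  expect_equal(f2$d, f1$d, tolerance = 1e-6)
  expect_lt(min(max(abs(f2$u - f1$u)), max(abs(f2$u + f1$u))), 1e-5)
})

test_that("loadings always satisfy their L1 and L2 constraints", {
  set.seed(9)
  for (i in 1:15) {
    K <- matrix(rnorm(30 * 12, sd = sample(c(0.5, 2), 1)), 30, 12)
    c1 <- runif(1, 0.15, 1)
    c2 <- runif(1, 0.15, 1)
    f <- suppressWarnings(pmd_rank_one(K, c1, c2))
    expect_equal(sum(f$u^2), 1, tolerance = 1e-6)
    expect_equal(sum(f$v^2), 1, tolerance = 1e-6)
    expect_lte(sum(abs(f$u)), max(1, c1 * sqrt(30)) + 1e-6)
    expect_lte(sum(abs(f$v)), max(1, c2 * sqrt(12)) + 1e-6)
  }
})

test_that("the K-component model at penalty 1 matches the truncated SVD", {
  set.seed(11)
  n <- 25
  X <- matrix(rnorm(n * 10), n, 10)
  Z <- matrix(rnorm(n * 7), n, 7)
  m <- fit_sparse_cca(X, Z, 1, 1, K = 4)
  s <- svd(crossprod(scale(X), scale(Z)))
  expect_equal(m$d, s$d[1:4], tolerance = 1e-5)
  for (k in 1:4) {
    expect_lt(min(max(abs(m$u[, k] - s$u[, k])),
                  max(abs(m$u[, k] + s$u[, k]))), 1e-4)
    expect_lt(min(max(abs(m$v[, k] - s$v[, k])),
                  max(abs(m$v[, k] + s$v[, k]))), 1e-4)
  }
})

test_that("planted disjoint gene modules are recovered exactly at low noise", {
  set.seed(13)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- matrix(rnorm(n * 100), n, 100)
  X[, 1:10] <- f1 + matrix(rnorm(n * 10, sd = 0.01), n)
  X[, 11:20] <- f2 + matrix(rnorm(n * 10, sd = 0.01), n)
  Z <- matrix(rnorm(n * 30), n, 30)
  Z[, 1:3] <- f1 + matrix(rnorm(n * 3, sd = 0.01), n)
  Z[, 4:6] <- f2 + matrix(rnorm(n * 3, sd = 0.01), n)
  m <- fit_sparse_cca(X, Z, 0.3, 0.3, K = 2)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  sup <- lapply(1:2, function(k) which(m$u[, k] != 0))
  expect_equal(max(jac(sup[[1]], 1:10), jac(sup[[1]], 11:20)), 1)
  expect_equal(max(jac(sup[[2]], 1:10), jac(sup[[2]], 11:20)), 1)
  # K = 1 equals the rank-one fit on the standardized cross-product
  m1 <- fit_sparse_cca(X, Z, 0.3, 0.3, K = 1)
  f <- pmd_rank_one(crossprod(scale(X), scale(Z)), 0.3, 0.3)
  expect_equal(unname(abs(drop(m1$u))), abs(f$u), tolerance = 1e-6)
  # identical sample permutation leaves loadings unchanged
  perm <- sample(n)
  mp <- fit_sparse_cca(X[perm, ], Z[perm, ], 0.3, 0.3, K = 2)
  expect_equal(mp$u, m$u, tolerance = 1e-6)
  expect_error(fit_sparse_cca(X[1:2, ], Z[1:2, ], 0.3, 0.3), "3 samples")
})

test_that("LOOCV penalty tuning finds the grid maximum", {
  set.seed(17)
  n <- 30
  f1 <- rnorm(n)
  X <- matrix(rnorm(n * 20), n, 20)
  X[, 1:5] <- f1 + matrix(rnorm(n * 5, sd = 0.05), n)
  Z <- matrix(rnorm(n * 10), n, 10)
  Z[, 1:2] <- f1 + matrix(rnorm(n * 2, sd = 0.05), n)
  tuned <- tune_penalties_loocv(X, Z, grid = c(0.2, 0.6, 1))
  # brute-force check: the returned score is the maximum over the grid
  expect_equal(tuned$score, max(tuned$grid$score, na.rm = TRUE))
  sel <- tuned$grid[tuned$grid$c1_frac == tuned$c1_frac &
                    tuned$grid$c2_frac == tuned$c2_frac, ]
  expect_equal(sel$score, tuned$score)
  expect_gt(tuned$score, 0.9)
  # single-point grid returns that point
  one <- tune_penalties_loocv(X, Z, grid = data.frame(c1_frac = 0.4,
                                                      c2_frac = 0.7))
  expect_equal(c(one$c1_frac, one$c2_frac), c(0.4, 0.7))
})

test_that("pure-noise tuning scores stay near zero", {
  set.seed(23)
  low <- 0L
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(40 * 10), 40, 10)
    Z <- matrix(rnorm(40 * 5), 40, 5)
    tuned <- tune_penalties_loocv(X, Z, grid = c(0.3, 1))
    if (abs(tuned$score) < 0.5) low <- low + 1L
  }
  expect_gte(low / n_rep, 0.9)
})

test_that("LOOCV significance flags a planted factor strongly", {
  set.seed(29)
  hits <- 0L
  n_rep <- 5
  for (r in seq_len(n_rep)) {
    n <- 40
    f1 <- rnorm(n)
    X <- matrix(rnorm(n * 25), n, 25)
    X[, 1:6] <- f1 + matrix(rnorm(n * 6, sd = 0.15), n)
    Z <- matrix(rnorm(n * 12), n, 12)
    Z[, 1:3] <- f1 + matrix(rnorm(n * 3, sd = 0.15), n)
    sig <- suppressWarnings(
      component_significance_loocv(X, Z, 0.4, 0.4, K = 5))
    if (sig$significant[1] && sig$rho[1] > 0.8) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
  expect_error(component_significance_loocv(matrix(rnorm(6), 3, 2),
                                            matrix(rnorm(6), 3, 2),
                                            0.5, 0.5, K = 1),
               "4 samples")
})

test_that("held-out variates match an independent per-fold SVD oracle at penalty 1", {
  # dual-route check of the LOOCV stream: component 1 at penalty fraction 1
  # equals the leading singular pair of each fold's standardized cross-product
  set.seed(31)
  n <- 25
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("z", 1:3)))
  sig <- component_significance_loocv(X, Z, 1, 1, K = 1)
  hv <- attr(sig, "variates")
  full <- svd(crossprod(scale(X), scale(Z)))
  oracle <- t(vapply(seq_len(n), function(i) {
    mx <- colMeans(X[-i, ]); sx <- apply(X[-i, ], 2, sd)
    mz <- colMeans(Z[-i, ]); sz <- apply(Z[-i, ], 2, sd)
    s <- svd(crossprod(scale(X[-i, ]), scale(Z[-i, ])))
    u <- s$u[, 1] * sign(sum(s$u[, 1] * full$u[, 1]))
    v <- s$v[, 1] * sign(sum(s$v[, 1] * full$v[, 1]))
    c(sum((X[i, ] - mx) / sx * u), sum((Z[i, ] - mz) / sz * v))
  }, c(0, 0)))
  expect_equal(hv$x[, 1], oracle[, 1], tolerance = 1e-5)
  expect_equal(hv$z[, 1], oracle[, 2], tolerance = 1e-5)
})
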