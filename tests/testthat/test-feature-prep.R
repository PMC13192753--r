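test_that("taxon prevalence filter uses at-least-ceiling semantics", {
  # feature at 0.02% everywhere is retained; absent feature removed;
  # a feature above threshold in exactly ceil(0.10 * 10) = 1 sample is retained
  depth <- 1e5
  m <- matrix(0, 4, 10)
  m[1, ] <- 20                         # 0.02% in all samples
  m[2, ] <- 0                          # absent
  m[3, 1] <- 50                        # 0.05% in exactly one sample
  m[4, ] <- depth - colSums(m)         # filler keeps depth constant
  t <- make_counts(m)
  out <- filter_taxa_prevalence(t, 1e-4, 0.10)
  expect_setequal(feature_ids(out), c("f1", "f3", "f4"))
  expect_identical(sample_ids(out), sample_ids(t))
  # order stability
  expect_identical(feature_ids(out), c("f1", "f3", "f4"))
  expect_error(filter_taxa_prevalence(make_counts(matrix(5, 2, 2)), 0.9, 0.1),
               "no features")
})

test_that("gene count filter applies ceil(frac * n) qualifying samples", {
  n <- 30
  m <- rbind(c(rep(10, 12), rep(0, 18)),  # >= 10 in 40% of samples -> kept
             rep(9, n),                   # 9 everywhere -> removed
             c(rep(10, 10), rep(0, 20)),  # exactly ceil(0.33*30) = 10 -> kept
             c(rep(10, 9), rep(0, 21)))   # 9 qualifying samples -> removed
  out <- filter_genes(make_counts(m), 10, 0.33)
  expect_identical(feature_ids(out), c("f1", "f3"))
})

test_that("variance filter drops strictly-below-quantile features and keeps ties", {
  # 100 features with variances ~ 1..100 (two-point rows, exact variance v)
  v <- 1:100
  m <- t(vapply(v, function(vi) c(-1, 1) * sqrt(vi / 2), c(0, 0)))
  t <- make_table(m, "residual")
  out <- variance_filter(t, 0.25)
  vars <- apply(t$values, 1, var)
  expect_equal(feature_ids(out),
               feature_ids(t)[vars >= quantile(vars, 0.25)])
  expect_identical(nrow(out$values), 75L)
  # quantile 0 is the identity; all-equal variances pass through untouched
  expect_identical(variance_filter(t, 0)$values, t$values)
  const <- make_table(matrix(5, 10, 4), "residual")
  expect_identical(variance_filter(const, 0.25)$values, const$values)
})

test_that("total-sum scaling normalizes columns and is idempotent", {
  t <- make_counts(matrix(c(2, 2, 4, 1, 1, 2), 3, 2))
  r <- tss(t)
  expect_equal(r$values[, 1], c(f1 = 0.25, f2 = 0.25, f3 = 0.5))
  expect_equal(unname(colSums(r$values)), c(1, 1))
  expect_equal(tss(r)$values, r$values)
  bad <- make_counts(cbind(c(1, 2), c(0, 0)))
  expect_error(tss(bad), "s2")
})

test_that("clr centers log relative abundances and is scale invariant", {
  t <- make_counts(matrix(c(1, 1, 1, 1), 4, 1))
  expect_equal(unname(clr(t)$values[, 1]), rep(0, 4))
  # limit example: column (0.5, 0.25, 0.25) with a vanishing pseudocount
  t2 <- make_counts(matrix(c(2, 1, 1), 3, 1))
  got <- clr(t2, pseudocount = 1e-12)$values[, 1]
  expect_equal(unname(got), c(0.462, -0.231, -0.231), tolerance = 1e-3)
  # scale invariance pre-pseudocount and clr(tss(x)) == clr(x)
  t3 <- make_counts(matrix(rpois(40, 50) + 1, 8, 5))
  t3_scaled <- t3; t3_scaled$values <- t3$values * 7
  expect_equal(clr(t3_scaled)$values, clr(t3)$values)
  expect_equal(clr(tss(t3))$values, clr(t3)$values)
  expect_true(all(abs(colSums(clr(t3)$values)) < 1e-9))
  expect_error(clr(t3, pseudocount = 0), "pseudocount")
})

test_that("log-CPM matches its formula and is monotone within a sample", {
  m <- matrix(c(1000, 1e6 - 1000), 2, 1)
  got <- log_cpm(make_counts(m), prior = 1e-9)$values[1, 1]
  expect_equal(got, log2(1000), tolerance = 1e-5)
  set.seed(1)
  t <- make_counts(matrix(rpois(60, 100), 12, 5))
  lc <- log_cpm(t)$values
  for (j in 1:5)
    expect_identical(order(lc[, j]), order(t$values[, j], seq_len(12)))
  # equal counts at equal depths give equal values
  eq <- make_counts(matrix(5, 3, 4))
  expect_true(all(abs(log_cpm(eq)$values - log_cpm(eq)$values[1, 1]) < 1e-12))
})

test_that("frequency contaminant score follows the stated F-ratio computation", {
  set.seed(42)
  n <- 20
  conc <- rlnorm(n, log(10), 1)
  depth <- rep(1e5, n)
  # feature 1: frequency exactly proportional to 1/concentration
  f_contam <- 1e3 / conc
  # feature 2: constant frequency
  f_const <- rep(150, n)
  filler <- depth - f_contam - f_const
  m <- rbind(round(f_contam), f_const, round(filler))
  t <- make_counts(m)
  rep <- frequency_contaminant_score(t, conc)
  # independent oracle: recompute the stated statistic directly
  oracle <- function(counts) {
    f <- counts / depth
    lf <- log10(f); lc <- log10(conc)
    ssc <- sum((lf + lc - mean(lf + lc))^2)
    ssn <- sum((lf - mean(lf))^2)
    pf(ssc / ssn, n - 1, n - 1)
  }
  expect_equal(rep$score[1], oracle(m[1, ]), tolerance = 1e-12)
  expect_equal(rep$score[2], oracle(m[2, ]), tolerance = 1e-12)
  expect_lt(rep$score[1], 0.05)
  expect_gt(rep$score[2], 0.5)
  expect_true(rep$contaminant[1])
  expect_false(rep$contaminant[2])
})

test_that("features present in fewer than 5 samples are not evaluable", {
  m <- matrix(0, 2, 10)
  m[1, 1:3] <- 100
  m[2, ] <- 1000
  rep <- frequency_contaminant_score(make_counts(m), rlnorm(10))
  expect_false(rep$evaluable[1])
  expect_false(rep$contaminant[1])
  expect_identical(rep$n_samples_used[1], 3L)
})

test_that("contaminant scoring recovers synthetic contaminants on generator defaults", {
  co <- generate_cohort(synth_config(n_samples_per_region = 60, n_regions = 1,
                                     n_patients = 60, n_genes = 20,
                                     n_taxa = 130, n_contaminants = 20,
                                     seed = 31))
  real <- !co$samples$is_control
  t <- co$microbiome
  t$values <- t$values[, real, drop = FALSE]
  rep <- frequency_contaminant_score(
    t, setNames(co$samples$dna_conc[real], co$samples$sample_id[real]))
  flagged <- rep$feature_id[rep$contaminant]
  truth <- co$truth$contaminant_ids
  expect_gte(mean(truth %in% flagged), 0.9)
  expect_lte(mean(setdiff(rep$feature_id, truth) %in% flagged), 0.1)
})
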