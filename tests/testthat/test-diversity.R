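test_that("rarefaction preserves depth and degenerates correctly", {
  set.seed(2)
  t <- make_counts(matrix(rpois(50, 40), 10, 5))
  depth <- min(colSums(t$values))
  r <- rarefy(t, depth, seed = 5)
  expect_equal(unname(colSums(r$values)), rep(depth, 5))
  expect_true(all(r$values <= t$values))
  # depth equal to a column's total leaves that column unchanged
  j <- which.min(colSums(t$values))
  expect_equal(r$values[, j], t$values[, j])
  r1 <- rarefy(t, 1, seed = 1)
  expect_true(all(colSums(r1$values > 0) == 1))
  expect_error(rarefy(t, max(colSums(t$values)) + 1), "below depth")
})

test_that("expected rarefied counts follow the hypergeometric mean", {
  counts <- c(a = 50, b = 30, c = 20)
  t <- make_counts(cbind(s1 = counts))
  depth <- 40
  draws <- vapply(1:1000, function(s) rarefy(t, depth, seed = s)$values[, 1],
                  counts + 0)
  m <- rowMeans(draws)
  expected <- depth * counts / sum(counts)
  se <- sqrt(apply(draws, 1, var) / 1000)
  expect_true(all(abs(m - expected) <= 3 * se + 1e-9))
})

test_that("alpha diversity identities hold on uniform and star-tree cases", {
  t <- make_counts(matrix(c(5, 5, 5, 5), 4, 1))
  expect_equal(unname(alpha_diversity(t, "shannon")), log(4))
  expect_equal(unname(alpha_diversity(t, "simpson")), 0.75)
  expect_equal(unname(alpha_diversity(t, "richness")), 4)
  # Faith's PD on the unit star tree with 3 of 5 tips observed
  tips <- paste0("f", 1:5)
  tr <- star_tree(tips)
  obs <- make_counts(rbind(c(1), c(1), c(1), c(0), c(0)), features = tips)
  expect_equal(unname(alpha_diversity(obs, "faith_pd", tree = tr)), 3)
  missing <- make_counts(matrix(1, 2, 1), features = c("f1", "zz"))
  expect_error(alpha_diversity(missing, "faith_pd", tree = tr), "zz")
})

test_that("fisher's alpha solves S = alpha * log(1 + N/alpha)", {
  # independent bisection oracle
  bisect <- function(S, N) {
    f <- function(a) a * log(1 + N / a) - S
    lo <- 1e-9; hi <- 1e6
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  counts <- c(rep(1, 15), 20, 30, 10, 15, 10)  # S = 20, N = 100
  t <- make_counts(cbind(s1 = counts))
  got <- unname(alpha_diversity(t, "fisher_alpha"))
  expect_equal(got, bisect(20, 100), tolerance = 1e-7)
  expect_equal(20, got * log(1 + 100 / got), tolerance = 1e-6)
})

test_that("rarefaction-averaged alpha diversity is deterministic and unbiased", {
  set.seed(9)
  t <- make_counts(matrix(rpois(30, 60), 6, 5))
  depth <- min(colSums(t$values))
  a1 <- rarefied_alpha(t, depth, "shannon", n_iter = 3, seed = 4)
  a2 <- rarefied_alpha(t, depth, "shannon", n_iter = 3, seed = 4)
  expect_identical(a1$mean, a2$mean)
  # at depth == column total the average equals the single-draw value exactly
  j <- which.min(colSums(t$values))
  single <- alpha_diversity(t, "shannon")
  expect_equal(a1$mean[j], single[j])
  # richness mean matches the closed-form hypergeometric expectation
  counts <- c(40, 25, 20, 10, 5)
  tt <- make_counts(cbind(s1 = counts))
  d <- 30
  N <- sum(counts)
  expected <- sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
  ra <- rarefied_alpha(tt, d, "richness", n_iter = 400, seed = 8)
  sims <- vapply(1:400, function(s)
    unname(alpha_diversity(rarefy(tt, d, seed = s + 1000), "richness")), 0)
  se <- sd(sims) / sqrt(400)
  expect_lt(abs(ra$mean[1] - expected), 3 * se + 1e-9)
})

test_that("beta distances satisfy identity, bounds, and hand-computed toys", {
  # identical columns are distance 0 in every metric
  tips <- paste0("f", 1:3)
  tr <- star_tree(tips)
  t_same <- make_counts(matrix(c(3, 2, 1, 3, 2, 1), 3, 2), features = tips)
  for (m in c("bray_curtis", "aitchison", "unweighted_unifrac",
              "weighted_unifrac"))
    expect_equal(max(as.matrix(beta_distance(t_same, m, tree = tr))), 0,
                 info = m)
  # disjoint supports: bray = 1, unweighted unifrac = 1 on a star tree
  t_disj <- make_counts(rbind(c(5, 0), c(3, 0), c(0, 7)), features = tips)
  expect_equal(as.numeric(beta_distance(t_disj, "bray_curtis")), 1)
  expect_equal(as.numeric(beta_distance(t_disj, "unweighted_unifrac",
                                        tree = tr)), 1)
  # two samples on 3 taxa against the formulas evaluated directly
  x <- c(0.5, 0.3, 0.2)
  y <- c(0.2, 0.3, 0.5)
  t2 <- make_counts(cbind(s1 = x * 100, s2 = y * 100), features = tips)
  bc <- sum(abs(x - y)) / sum(x + y)
  expect_equal(as.numeric(beta_distance(t2, "bray_curtis")), bc)
  clrv <- function(v) { l <- log(v + 1e-6); l - mean(l) }
  expect_equal(as.numeric(beta_distance(t2, "aitchison")),
               sqrt(sum((clrv(x) - clrv(y))^2)))
  # weighted unifrac on the unit star tree: sum|x-y| / sum(x+y)
  expect_equal(as.numeric(beta_distance(t2, "weighted_unifrac", tree = tr)),
               sum(abs(x - y)) / sum(x + y))
  expect_error(beta_distance(t2, "weighted_unifrac"), "tree")
})

test_that("unifrac agrees with an independent reference implementation", {
  skip_if_not_installed("phyloseq")
  set.seed(14)
  for (rep in 1:3) {
    nt <- 12
    tr <- ape::rcoal(nt, tip.label = paste0("f", 1:nt))
    m <- matrix(rpois(nt * 4, 8), nt, 4)
    m[m < 3] <- 0
    m[1, ] <- m[1, ] + 5  # keep columns nonzero
    t <- make_counts(m, features = paste0("f", 1:nt))
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(t$values, taxa_are_rows = TRUE), phyloseq::phy_tree(tr))
    got_u <- as.matrix(beta_distance(t, "unweighted_unifrac", tree = tr))
    ref_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
    expect_equal(got_u, ref_u[rownames(got_u), colnames(got_u)],
                 tolerance = 1e-8)
    got_w <- as.matrix(beta_distance(t, "weighted_unifrac", tree = tr))
    ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
    expect_equal(got_w, ref_w[rownames(got_w), colnames(got_w)],
                 tolerance = 1e-8)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  set.seed(3)
  nt <- 10
  tr <- ape::rcoal(nt, tip.label = paste0("f", 1:nt))
  m <- matrix(rpois(nt * 6, 20), nt, 6)
  m[1, ] <- m[1, ] + 1
  t <- make_counts(m, features = paste0("f", 1:nt))
  for (metric in c("bray_curtis", "aitchison", "unweighted_unifrac",
                   "weighted_unifrac")) {
    d <- as.matrix(beta_distance(t, metric, tree = tr))
    expect_equal(d, t(d), info = metric)
    expect_equal(unname(diag(d)), rep(0, 6), info = metric)
    expect_true(all(d >= 0), info = metric)
    if (metric != "aitchison") expect_true(all(d <= 1 + 1e-12), info = metric)
  }
})
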