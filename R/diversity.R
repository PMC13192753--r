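#' Rarefy a count table to even depth
#'
#' Each sample is subsampled uniformly without replacement to exactly `depth`
#' reads (multivariate hypergeometric draw).
#'
#' @param t a `feature_table` of counts.
#' @param depth target depth; every sample must have at least `depth` reads.
#' @param seed optional integer seed; the draw is deterministic given it.
#' @return a rarefied `feature_table[counts]` with column sums equal to `depth`.
#' @export
rarefy <- function(t, depth, seed = NULL) {
  stopifnot(inherits(t, "feature_table"), t$kind == "counts", depth >= 1)
  cs <- colSums(t$values)
  if (any(cs < depth))
    stop("sample(s) below depth ", depth, ": ",
         paste(colnames(t$values)[cs < depth], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- apply(t$values, 2, rhyper_multi, depth = depth)
  dimnames(out) <- dimnames(t$values)
  feature_table(out, "counts")
}

# multivariate hypergeometric draw: a uniform without-replacement subsample
# of `depth` reads from one sample's count vector, via sequential rhyper
rhyper_multi <- function(counts, depth) {
  out <- numeric(length(counts))
  remaining <- sum(counts)
  need <- depth
  for (i in seq_along(counts)) {
    if (need == 0) break
    k <- if (remaining == counts[i]) need
         else stats::rhyper(1, counts[i], remaining - counts[i], need)
    out[i] <- k
    need <- need - k
    remaining <- remaining - counts[i]
  }
  out
}

#' Alpha diversity of a count table (single draw)
#'
#' @param t a `feature_table` of counts.
#' @param metric one of `"richness"`, `"shannon"` (natural log),
#'   `"simpson"` (1 - sum p^2), `"fisher_alpha"` (unique positive root of
#'   S = alpha * log(1 + N/alpha)) or `"faith_pd"` (total branch length of the
#'   minimal rooted subtree spanning the observed taxa, including the path to
#'   the root).
#' @param tree rooted `phylo` with branch lengths; required for `faith_pd` and
#'   must contain every observed feature as a tip.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(t, metric = c("richness", "shannon", "simpson",
                                          "fisher_alpha", "faith_pd"),
                            tree = NULL) {
  stopifnot(inherits(t, "feature_table"), t$kind == "counts")
  metric <- match.arg(metric)
  x <- t(t$values)  # samples x features, as vegan expects
  out <- switch(metric,
    richness = rowSums(x > 0),
    shannon = vegan::diversity(x, index = "shannon"),
    simpson = vegan::diversity(x, index = "simpson"),
    fisher_alpha = apply(x, 1, fisher_alpha_root),
    faith_pd = {
      if (is.null(tree)) stop("faith_pd requires a rooted tree")
      check_tree_tips(tree, feature_ids(t))
      pd <- picante::pd(x, tree, include.root = TRUE)
      stats::setNames(pd$PD, rownames(pd))
    })
  stats::setNames(as.numeric(out), colnames(t$values))
}

# unique positive root of S = alpha * log(1 + N/alpha), by safeguarded bisection
fisher_alpha_root <- function(counts, tol = 1e-10) {
  counts <- counts[counts > 0]
  S <- length(counts)
  N <- sum(counts)
  if (S == 0) return(0)
  if (S >= N) return(Inf)  # equation has no finite root when every read is unique
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

check_tree_tips <- function(tree, features) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(features, tree$tip.label)
  if (length(missing) > 0)
    stop("tree is missing tips: ", paste(missing, collapse = ", "))
  invisible(tree)
}

#' Rarefaction-averaged alpha diversity
#'
#' Mean of an alpha-diversity metric over `n_iter` independent rarefactions
#' to a common depth.
#'
#' @inheritParams alpha_diversity
#' @param depth rarefaction depth.
#' @param n_iter number of rarefaction draws (default 1000).
#' @param seed integer seed making the whole procedure deterministic.
#' @return list with `mean` (named per-sample vector), `depth`, `n_iter`,
#'   `metric`.
#' @export
rarefied_alpha <- function(t, depth, metric = "shannon", n_iter = 1000,
                           seed = 1L, tree = NULL) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  acc <- 0
  for (i in seq_len(n_iter))
    acc <- acc + alpha_diversity(rarefy(t, depth), metric = metric, tree = tree)
  list(mean = acc / n_iter, depth = depth, n_iter = n_iter, metric = metric)
}

#' Beta-diversity distance matrix
#'
#' @param t a `feature_table` of counts or relative abundances (counts are
#'   total-sum scaled internally).
#' @param metric `"bray_curtis"`, `"aitchison"` (Euclidean distance between
#'   CLR vectors), `"unweighted_unifrac"` (unique / total branch length over
#'   presence sets) or `"weighted_unifrac"` (normalized:
#'   sum b_e |A_e - B_e| / sum b_e (A_e + B_e)).
#' @param tree rooted `phylo`, required for the UniFrac metrics.
#' @param pseudocount CLR pseudocount for the Aitchison metric.
#' @return a `dist` object with sample labels; access the square form with
#'   `as.matrix()`.
#' @export
beta_distance <- function(t, metric = c("bray_curtis", "aitchison",
                                        "unweighted_unifrac", "weighted_unifrac"),
                          tree = NULL, pseudocount = 1e-6) {
  stopifnot(inherits(t, "feature_table"))
  metric <- match.arg(metric)
  ra <- if (t$kind == "relative_abundance") t else tss(t)
  if (metric == "bray_curtis")
    return(vegan::vegdist(t(ra$values), method = "bray"))
  if (metric == "aitchison")
    return(stats::dist(t(clr(ra, pseudocount)$values)))
  if (is.null(tree)) stop(metric, " requires a rooted tree")
  check_tree_tips(tree, feature_ids(t))
  unifrac_dist(ra$values, tree, weighted = metric == "weighted_unifrac")
}

# edge-based UniFrac on a relative-abundance matrix (taxa x samples)
unifrac_dist <- function(ra, tree, weighted) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  ns <- ncol(ra)
  # abundance fraction descending each edge, accumulated tips-up
  node_ab <- matrix(0, n_tip + n_node, ns)
  node_ab[seq_len(n_tip), ] <- ra[tree$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    node_ab[p, ] <- node_ab[p, ] + node_ab[ch, ]
  }
  A <- node_ab[tree$edge[, 2], , drop = FALSE]  # edges x samples
  b <- tree$edge.length
  d <- matrix(0, ns, ns, dimnames = list(colnames(ra), colnames(ra)))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    ai <- A[, i]; aj <- A[, j]
    d[j, i] <- d[i, j] <- if (weighted) {
      denom <- sum(b * (ai + aj))
      if (denom == 0) 0 else sum(b * abs(ai - aj)) / denom
    } else {
      pi <- ai > 0; pj <- aj > 0
      union_len <- sum(b[pi | pj])
      if (union_len == 0) 0 else sum(b[xor(pi, pj)]) / union_len
    }
  }
  stats::as.dist(d)
}
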