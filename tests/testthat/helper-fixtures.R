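# shared fixture builders; everything is generated in code at test time

make_table <- function(m, kind = "counts", features = NULL, samples = NULL) {
  if (is.null(features)) features <- paste0("f", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  feature_table(m, kind)
}

make_counts <- function(m, features = NULL, samples = NULL)
  make_table(m, "counts", features, samples)

make_ordination <- function(coords, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(coords)))
  rownames(coords) <- ids
  structure(list(coordinates = coords,
                 eigenvalues = rep(1, ncol(coords)),
                 proportion_explained = rep(1 / ncol(coords), ncol(coords)),
                 sample_ids = ids),
            class = "ordination")
}

random_orthogonal <- function(k) qr.Q(qr(matrix(stats::rnorm(k * k), k)))

# a small cohort config used by several suites
small_cohort <- function(seed = 11, ...) {
  generate_cohort(synth_config(
    n_samples_per_region = 20, n_regions = 3, n_patients = 30,
    n_genes = 120, n_taxa = 60, n_contaminants = 8,
    n_negative_controls = 2, seed = seed, ...))
}

# star tree over `tips` with unit branch lengths
star_tree <- function(tips) {
  ape::read.tree(text = paste0("(", paste0(tips, ":1", collapse = ","), "):0;"))
}
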