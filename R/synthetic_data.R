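#' Configuration for the synthetic paired-cohort generator
#'
#' Describes a paired microbiome/transcriptome cohort sampled across several
#' intestinal regions, with shared latent factors linking sparse gene modules
#' to sparse microbe groups, sparse direct gene-to-microbe effects, fixed
#' covariates, patient-level random intercepts, inverse-DNA-concentration
#' contaminant taxa and negative-control samples. Defaults are the desk-scale
#' study conditions used throughout the package's tests and vignette.
#'
#' @param n_samples_per_region samples per intestinal region.
#' @param n_regions number of regions.
#' @param n_patients number of patients; must not exceed the total number of
#'   biological samples. Patients may contribute samples in several regions.
#' @param n_genes,n_taxa feature-space sizes.
#' @param n_latent_factors shared latent factors coupling the two tables.
#' @param factor_gene_sparsity,factor_taxon_sparsity fraction of features in
#'   each factor's support, in (0, 1].
#' @param factor_effect_gene,factor_effect_taxon loading magnitude on the log
#'   scale for support features.
#' @param n_direct_pairs number of direct gene-to-microbe effects.
#' @param effect_size_direct log-relative-abundance shift per SD of the
#'   driving gene's latent expression.
#' @param nb_dispersion negative-binomial dispersion (1/size) of gene counts.
#' @param sequencing_depth_mean mean per-sample microbiome depth; realized
#'   depths are log-normal around it.
#' @param n_contaminants taxa whose expected abundance scales as
#'   1/DNA-concentration.
#' @param n_negative_controls extraction-blank samples carrying only
#'   contaminant signal.
#' @param covariate_spec data.frame with columns `name`, `type`
#'   (`"binary"`/`"continuous"`) and `effect` (per-feature effect scale).
#' @param gene_bio_sd SD of per-gene per-sample biological variation on the
#'   log scale, beyond covariates, patient and factor structure; this
#'   idiosyncratic component is what direct gene-to-microbe effects transmit.
#' @param patient_sd SD of patient random intercepts (log scale).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_samples_per_region = 30,
                         n_regions = 3,
                         n_patients = 45,
                         n_genes = 500,
                         n_taxa = 130,
                         n_latent_factors = 2,
                         factor_gene_sparsity = 0.04,
                         factor_taxon_sparsity = 0.04,
                         factor_effect_gene = 1.0,
                         factor_effect_taxon = 2.0,
                         n_direct_pairs = 10,
                         effect_size_direct = 2.0,
                         nb_dispersion = 0.3,
                         sequencing_depth_mean = 65467L,
                         n_contaminants = 20,
                         n_negative_controls = 3,
                         covariate_spec = data.frame(
                           name = c("sex", "age", "batch"),
                           type = c("binary", "continuous", "binary"),
                           effect = c(0.3, 0.2, 0.2),
                           stringsAsFactors = FALSE),
                         gene_bio_sd = 0.8,
                         patient_sd = 0.5,
                         seed = 1L) {
  cfg <- list(n_samples_per_region = as.integer(n_samples_per_region),
              n_regions = as.integer(n_regions),
              n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes), n_taxa = as.integer(n_taxa),
              n_latent_factors = as.integer(n_latent_factors),
              factor_gene_sparsity = factor_gene_sparsity,
              factor_taxon_sparsity = factor_taxon_sparsity,
              factor_effect_gene = factor_effect_gene,
              factor_effect_taxon = factor_effect_taxon,
              n_direct_pairs = as.integer(n_direct_pairs),
              effect_size_direct = effect_size_direct,
              nb_dispersion = nb_dispersion,
              sequencing_depth_mean = as.integer(sequencing_depth_mean),
              n_contaminants = as.integer(n_contaminants),
              n_negative_controls = as.integer(n_negative_controls),
              covariate_spec = covariate_spec,
              gene_bio_sd = gene_bio_sd,
              patient_sd = patient_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_samples_per_region >= 1, cfg$n_regions >= 1,
            cfg$n_genes >= 1, cfg$n_taxa >= 1,
            cfg$n_latent_factors >= 0, cfg$n_direct_pairs >= 0,
            cfg$nb_dispersion > 0, cfg$sequencing_depth_mean >= 1,
            cfg$n_contaminants >= 0, cfg$n_negative_controls >= 0,
            cfg$gene_bio_sd >= 0, cfg$patient_sd >= 0)
  if (cfg$factor_gene_sparsity <= 0 || cfg$factor_gene_sparsity > 1 ||
      cfg$factor_taxon_sparsity <= 0 || cfg$factor_taxon_sparsity > 1)
    stop("sparsity fractions must lie in (0, 1]")
  n_bio <- cfg$n_samples_per_region * cfg$n_regions
  if (cfg$n_patients < 1 || cfg$n_patients > n_bio)
    stop("invalid config: n_patients must be in [1, total biological samples]")
  if (cfg$n_direct_pairs > cfg$n_genes * cfg$n_taxa)
    stop("invalid config: n_direct_pairs exceeds n_genes * n_taxa")
  if (cfg$n_contaminants > cfg$n_taxa)
    stop("invalid config: n_contaminants exceeds n_taxa")
  invisible(cfg)
}

#' Generate a synthetic paired cohort with known ground truth
#'
#' Gene counts are negative-binomial with log-mean = baseline + covariate
#' effects + patient offset + sum of factor loading x factor score. Taxon
#' counts are multinomial per sample at a log-normal depth, with
#' log-relative-abundance composed the same way plus the direct gene effects
#' for designated gene/taxon pairs. Contaminant taxa get expected abundance
#' proportional to 1/DNA-concentration; negative controls contain only
#' contaminant signal. A random rooted bifurcating coalescent tree with
#' positive branch lengths is emitted over the taxa.
#'
#' @param config a [synth_config()].
#' @return list with elements `microbiome` and `expression`
#'   (`feature_table[counts]`), `samples` (metadata data.frame), `tree`
#'   (`ape::phylo`, rooted) and `truth` (a `synthetic_truth` list with
#'   `factor_gene_support`, `factor_taxon_support`, `direct_pairs`,
#'   `contaminant_ids`, `covariate_effects`, `patient_offsets`,
#'   `factor_scores`).
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  n_bio <- config$n_samples_per_region * config$n_regions
  regions <- paste0("region", rep(seq_len(config$n_regions),
                                  each = config$n_samples_per_region))
  sample_id <- sprintf("S%03d", seq_len(n_bio))
  gene_id <- sprintf("gene%04d", seq_len(config$n_genes))
  taxon_id <- sprintf("taxon%03d", seq_len(config$n_taxa))

  # patients: every patient used at least once, remainder assigned at random
  patient <- sprintf("P%03d", c(seq_len(config$n_patients),
                                sample.int(config$n_patients,
                                           n_bio - config$n_patients,
                                           replace = TRUE)))
  patient <- patient[sample.int(n_bio)]

  cov_spec <- config$covariate_spec
  covs <- matrix(0, n_bio, nrow(cov_spec),
                 dimnames = list(sample_id, cov_spec$name))
  for (j in seq_len(nrow(cov_spec)))
    covs[, j] <- if (cov_spec$type[j] == "binary")
      stats::rbinom(n_bio, 1, 0.5) else stats::rnorm(n_bio)

  dna_conc <- stats::rlnorm(n_bio, meanlog = log(10), sdlog = 1.2)

  patient_offsets <- stats::rnorm(config$n_patients, 0, config$patient_sd)
  names(patient_offsets) <- sprintf("P%03d", seq_len(config$n_patients))
  offset <- patient_offsets[patient]

  K <- config$n_latent_factors
  scores <- matrix(stats::rnorm(n_bio * max(K, 1)), n_bio, max(K, 1))
  if (K == 0) scores <- scores[, 0, drop = FALSE]

  n_g_sup <- max(1L, round(config$factor_gene_sparsity * config$n_genes))
  n_t_sup <- max(1L, round(config$factor_taxon_sparsity * config$n_taxa))
  n_real <- config$n_taxa - config$n_contaminants
  if (K > 0 && n_real < 1) stop("invalid config: no non-contaminant taxa left")
  gene_support <- lapply(seq_len(K), function(k)
    sort(sample.int(config$n_genes, n_g_sup)))
  taxon_support <- lapply(seq_len(K), function(k)
    sort(sample.int(n_real, n_t_sup)))

  L_gene <- matrix(0, config$n_genes, max(K, 1))
  L_taxon <- matrix(0, config$n_taxa, max(K, 1))
  for (k in seq_len(K)) {
    L_gene[gene_support[[k]], k] <- config$factor_effect_gene
    L_taxon[taxon_support[[k]], k] <- config$factor_effect_taxon
  }

  # fixed covariate effects: dense, small
  B_gene <- matrix(stats::rnorm(config$n_genes * nrow(cov_spec)),
                   config$n_genes) %*% diag(cov_spec$effect, nrow(cov_spec))
  B_taxon <- matrix(stats::rnorm(config$n_taxa * nrow(cov_spec)),
                    config$n_taxa) %*% diag(cov_spec$effect, nrow(cov_spec))

  # --- expression ---
  baseline_g <- stats::rnorm(config$n_genes, log(50), 1)
  log_mu <- outer(baseline_g, rep(1, n_bio)) + B_gene %*% t(covs) +
    outer(rep(1, config$n_genes), offset) +
    (if (K > 0) L_gene %*% t(scores) else 0) +
    matrix(stats::rnorm(config$n_genes * n_bio, 0, config$gene_bio_sd),
           config$n_genes, n_bio)
  dimnames(log_mu) <- list(gene_id, sample_id)
  expr <- matrix(stats::rnbinom(length(log_mu), mu = exp(log_mu),
                                size = 1 / config$nb_dispersion),
                 config$n_genes, n_bio, dimnames = list(gene_id, sample_id))

  # latent (noiseless) gene signal driving the direct effects, standardized
  gene_signal <- log_mu - rowMeans(log_mu)
  sds <- apply(gene_signal, 1, stats::sd)
  gene_signal <- gene_signal / ifelse(sds > 0, sds, 1)

  # --- direct gene->taxon pairs (distinct non-contaminant target taxa) ---
  n_dp <- min(config$n_direct_pairs, n_real)
  if (n_dp < config$n_direct_pairs)
    warning("n_direct_pairs reduced to the number of non-contaminant taxa")
  direct_pairs <- if (n_dp > 0) {
    data.frame(gene = gene_id[sample.int(config$n_genes, n_dp, replace = TRUE)],
               taxon = taxon_id[sample.int(n_real, n_dp)],
               coefficient = config$effect_size_direct,
               stringsAsFactors = FALSE)
  } else data.frame(gene = character(), taxon = character(),
                    coefficient = numeric(), stringsAsFactors = FALSE)

  # --- microbiome ---
  contaminant_ids <- if (config$n_contaminants > 0)
    taxon_id[(n_real + 1):config$n_taxa] else character()
  base_t <- stats::rnorm(config$n_taxa, 0, 1.5)
  log_ra <- outer(base_t, rep(1, n_bio)) + B_taxon %*% t(covs) +
    outer(rep(1, config$n_taxa), offset) +
    (if (K > 0) L_taxon %*% t(scores) else 0)
  dimnames(log_ra) <- list(taxon_id, sample_id)
  for (r in seq_len(nrow(direct_pairs)))
    log_ra[direct_pairs$taxon[r], ] <- log_ra[direct_pairs$taxon[r], ] +
      direct_pairs$coefficient[r] * gene_signal[direct_pairs$gene[r], ]
  # contaminants: expected abundance proportional to 1/concentration
  if (length(contaminant_ids) > 0)
    log_ra[contaminant_ids, ] <- outer(base_t[(n_real + 1):config$n_taxa] + 0.5,
                                       rep(1, n_bio)) -
      outer(rep(1, config$n_contaminants), log(dna_conc))

  depth <- pmax(1L, round(stats::rlnorm(n_bio,
                                        log(config$sequencing_depth_mean), 0.3)))
  micro <- matrix(0L, config$n_taxa, n_bio, dimnames = list(taxon_id, sample_id))
  for (i in seq_len(n_bio)) {
    p <- exp(log_ra[, i] - max(log_ra[, i]))
    micro[, i] <- stats::rmultinom(1, depth[i], p / sum(p))
  }

  samples <- data.frame(sample_id = sample_id, patient_id = patient,
                        location = regions, dna_conc = dna_conc,
                        is_control = FALSE, covs,
                        check.names = FALSE, stringsAsFactors = FALSE)

  # --- negative controls: contaminant-only signal at low concentration ---
  if (config$n_negative_controls > 0 && config$n_contaminants > 0) {
    nc_id <- sprintf("NC%02d", seq_len(config$n_negative_controls))
    nc_conc <- stats::rlnorm(config$n_negative_controls, log(0.5), 0.3)
    nc_depth <- pmax(1L, round(stats::rlnorm(config$n_negative_controls,
                                             log(config$sequencing_depth_mean / 10), 0.3)))
    nc <- matrix(0L, config$n_taxa, config$n_negative_controls,
                 dimnames = list(taxon_id, nc_id))
    for (i in seq_len(config$n_negative_controls)) {
      lp <- base_t[(n_real + 1):config$n_taxa] - log(nc_conc[i])
      p <- exp(lp - max(lp))
      nc[contaminant_ids, i] <- stats::rmultinom(1, nc_depth[i], p / sum(p))
    }
    micro <- cbind(micro, nc)
    nc_meta <- samples[rep(1, config$n_negative_controls), , drop = FALSE]
    nc_meta$sample_id <- nc_id
    nc_meta$patient_id <- NA_character_
    nc_meta$location <- "control"
    nc_meta$dna_conc <- nc_conc
    nc_meta$is_control <- TRUE
    nc_meta[, cov_spec$name] <- 0
    samples <- rbind(samples, nc_meta)
    rownames(samples) <- NULL
  }

  tree <- ape::rcoal(config$n_taxa, tip.label = taxon_id)

  truth <- structure(list(
    factor_gene_support = lapply(gene_support, function(ix) gene_id[ix]),
    factor_taxon_support = lapply(taxon_support, function(ix) taxon_id[ix]),
    direct_pairs = direct_pairs,
    contaminant_ids = contaminant_ids,
    covariate_effects = list(gene = B_gene, taxon = B_taxon),
    patient_offsets = patient_offsets,
    factor_scores = scores,
    gene_signal = gene_signal), class = "synthetic_truth")

  list(microbiome = feature_table(micro + 0, "counts"),
       expression = feature_table(expr + 0, "counts"),
       samples = samples, tree = tree, truth = truth)
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Emits TSV count tables, a metadata TSV, a newick tree and TSV truth files
#' that round-trip losslessly through the package readers.
#'
#' @param cohort output of [generate_cohort()].
#' @param directory output directory (created if absent).
#' @return named character vector of the paths written.
#' @export
write_fixture <- function(cohort, directory) {
  if (!is.character(directory) || length(directory) != 1 || !nzchar(directory))
    stop("`directory` must be a non-empty path")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  paths <- c(
    microbiome = file.path(directory, "microbiome_counts.tsv"),
    expression = file.path(directory, "expression_counts.tsv"),
    samples = file.path(directory, "samples.tsv"),
    tree = file.path(directory, "tree.nwk"),
    direct_pairs = file.path(directory, "truth_direct_pairs.tsv"),
    supports = file.path(directory, "truth_factor_support.tsv"),
    contaminants = file.path(directory, "truth_contaminants.tsv"))
  write_feature_table(cohort$microbiome, paths["microbiome"])
  write_feature_table(cohort$expression, paths["expression"])
  utils::write.table(cohort$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(cohort$tree, paths["tree"])
  utils::write.table(cohort$truth$direct_pairs, paths["direct_pairs"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sup <- do.call(rbind, c(
    lapply(seq_along(cohort$truth$factor_gene_support), function(k)
      data.frame(factor = k, modality = "gene",
                 feature = cohort$truth$factor_gene_support[[k]])),
    lapply(seq_along(cohort$truth$factor_taxon_support), function(k)
      data.frame(factor = k, modality = "taxon",
                 feature = cohort$truth$factor_taxon_support[[k]]))))
  if (is.null(sup)) sup <- data.frame(factor = integer(), modality = character(),
                                      feature = character())
  utils::write.table(sup, paths["supports"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(taxon = cohort$truth$contaminant_ids),
                     paths["contaminants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
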