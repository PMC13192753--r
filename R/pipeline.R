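#' Pipeline configuration
#'
#' Collects inputs and tuning parameters for the full three-level analysis.
#' Inputs may be in-memory objects (as produced by [generate_cohort()]) or
#' file paths understood by the package readers.
#'
#' @param taxa microbiome `feature_table[counts]` or TSV path.
#' @param genes expression `feature_table[counts]` or TSV path.
#' @param samples metadata data.frame or TSV path (must carry `sample_id`,
#'   `patient_id`, the region column and the covariates).
#' @param tree rooted `phylo` or newick path; only needed for UniFrac.
#' @param gene_sets named list of gene sets or GMT path; enables the
#'   enrichment stage.
#' @param covariates fixed-covariate column names regressed out of both
#'   modalities.
#' @param region_col metadata column holding the intestinal location.
#' @param dna_conc_col metadata column with DNA concentrations (contaminant
#'   scoring is skipped when absent).
#' @param min_rel_abund,prevalence_frac taxon prevalence filter thresholds.
#' @param min_count,count_frac gene count filter thresholds.
#' @param variance_quantile lowest-variance quantile of genes to drop.
#' @param clr_pseudocount CLR/Aitchison pseudocount.
#' @param log_cpm_prior prior count for log-CPM.
#' @param contaminant_threshold score cutoff for contaminant removal.
#' @param rarefaction_depth,rarefaction_iters optional alpha-diversity stage:
#'   depth (NULL skips the stage) and rarefaction iterations.
#' @param beta_metrics beta-diversity metrics to emit (UniFrac needs `tree`).
#' @param n_perm Procrustes permutations (default 99999).
#' @param scca_grid penalty-fraction grid (vector or data.frame, see
#'   [tune_penalties_loocv()]).
#' @param scca_k number of sparse CCA components (default 10).
#' @param scca_alpha adjusted-p cutoff for component significance.
#' @param enet_alpha_grid,enet_folds,enet_repeats,enet_n_lambda elastic-net
#'   tuning controls.
#' @param ora_min_size,ora_alpha enrichment thresholds.
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir directory for tables and the run manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(taxa, genes, samples, tree = NULL,
                            gene_sets = NULL,
                            covariates = character(),
                            region_col = "location",
                            dna_conc_col = "dna_conc",
                            min_rel_abund = 1e-4, prevalence_frac = 0.10,
                            min_count = 10, count_frac = 0.33,
                            variance_quantile = 0.25,
                            clr_pseudocount = 1e-6, log_cpm_prior = 0.5,
                            contaminant_threshold = 0.1,
                            rarefaction_depth = NULL, rarefaction_iters = 1000,
                            beta_metrics = c("bray_curtis", "aitchison"),
                            n_perm = 99999,
                            scca_grid = seq(0.1, 1, by = 0.1), scca_k = 10,
                            scca_alpha = 0.1,
                            enet_alpha_grid = seq(0.1, 1, by = 0.1),
                            enet_folds = 5, enet_repeats = 5,
                            enet_n_lambda = 100,
                            ora_min_size = 10, ora_alpha = 0.1,
                            seed = 1L, output_dir = tempfile("triome_run_")) {
  if (is.character(taxa)) taxa <- read_feature_table(taxa, "counts")
  if (is.character(genes)) genes <- read_feature_table(genes, "counts")
  if (is.character(samples)) samples <- read_sample_frame(samples)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  validate_sample_frame(samples)
  missing_cols <- setdiff(c(region_col, covariates, "patient_id"),
                          names(samples))
  if (length(missing_cols) > 0)
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(beta_metrics, c("bray_curtis", "aitchison",
                                 "unweighted_unifrac", "weighted_unifrac"))
  if (length(bad) > 0) stop("unknown beta metric(s): ", paste(bad, collapse = ", "))
  if (any(grepl("unifrac", beta_metrics)) && is.null(tree))
    stop("UniFrac metrics requested but no tree supplied")
  stopifnot(n_perm >= 1, scca_k >= 1, enet_folds >= 2, enet_repeats >= 1)
  structure(list(taxa = taxa, genes = genes, samples = samples, tree = tree,
                 gene_sets = gene_sets, covariates = covariates,
                 region_col = region_col, dna_conc_col = dna_conc_col,
                 min_rel_abund = min_rel_abund,
                 prevalence_frac = prevalence_frac,
                 min_count = min_count, count_frac = count_frac,
                 variance_quantile = variance_quantile,
                 clr_pseudocount = clr_pseudocount,
                 log_cpm_prior = log_cpm_prior,
                 contaminant_threshold = contaminant_threshold,
                 rarefaction_depth = rarefaction_depth,
                 rarefaction_iters = rarefaction_iters,
                 beta_metrics = beta_metrics,
                 n_perm = as.integer(n_perm),
                 scca_grid = scca_grid, scca_k = as.integer(scca_k),
                 scca_alpha = scca_alpha,
                 enet_alpha_grid = enet_alpha_grid,
                 enet_folds = as.integer(enet_folds),
                 enet_repeats = as.integer(enet_repeats),
                 enet_n_lambda = as.integer(enet_n_lambda),
                 ora_min_size = ora_min_size, ora_alpha = ora_alpha,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

# stage seeds derived deterministically from the master seed
stage_seed <- function(config, offset) (config$seed * 131L + offset) %% 2147483647L

# shared preprocessing for one sample set; include_location toggles the
# location fixed effect (intestine-wide yes, within-region no)
prepare_matrices <- function(config, samples, include_location) {
  taxa <- config$taxa
  genes <- config$genes
  shared <- Reduce(intersect, list(samples$sample_id[!samples$is_control],
                                   sample_ids(taxa), sample_ids(genes)))
  if (length(shared) == 0) stop("no overlapping samples across modalities")
  meta <- samples[match(shared, samples$sample_id), , drop = FALSE]
  taxa$values <- taxa$values[, shared, drop = FALSE]
  genes$values <- genes$values[, shared, drop = FALSE]

  # contaminant scoring (frequency method) before any other taxon filter
  contam <- NULL
  if (!is.null(config$dna_conc_col) &&
      config$dna_conc_col %in% names(meta)) {
    conc <- stats::setNames(meta[[config$dna_conc_col]], meta$sample_id)
    contam <- frequency_contaminant_score(taxa, conc,
                                          threshold = config$contaminant_threshold)
    drop_taxa <- contam$feature_id[contam$contaminant]
    if (length(drop_taxa) > 0)
      taxa$values <- taxa$values[!rownames(taxa$values) %in% drop_taxa, ,
                                 drop = FALSE]
  }

  taxa_f <- filter_taxa_prevalence(taxa, config$min_rel_abund,
                                   config$prevalence_frac)
  taxa_clr <- clr(taxa_f, config$clr_pseudocount)

  genes_f <- filter_genes(genes, config$min_count, config$count_frac)
  genes_n <- log_cpm(genes_f, config$log_cpm_prior)

  covs <- config$covariates
  if (include_location) covs <- c(covs, config$region_col)
  design <- covariate_design(meta, covs)
  taxa_res <- suppressWarnings(lmm_residualize(taxa_clr, design))
  genes_res <- suppressWarnings(lmm_residualize(genes_n, design))
  genes_res <- variance_filter(genes_res, config$variance_quantile)

  list(meta = meta, contaminants = contam,
       taxa_counts = taxa_f, taxa_clr = taxa_clr,
       X = t(genes_res$values),   # samples x genes
       Z = t(taxa_res$values))    # samples x taxa
}

# optional diversity stage: rarefaction-averaged alpha and beta matrices
run_diversity <- function(config, prep, dir_out) {
  if (is.null(config$rarefaction_depth)) return(invisible(NULL))
  alpha <- lapply(c("richness", "shannon", "simpson"), function(m)
    rarefied_alpha(prep$taxa_counts, config$rarefaction_depth, m,
                   n_iter = config$rarefaction_iters,
                   seed = stage_seed(config, 7L))$mean)
  names(alpha) <- c("richness", "shannon", "simpson")
  utils::write.table(
    data.frame(sample_id = names(alpha[[1]]), as.data.frame(alpha)),
    file.path(dir_out, "alpha_diversity.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in config$beta_metrics) {
    d <- as.matrix(beta_distance(prep$taxa_counts, m, tree = config$tree,
                                 pseudocount = config$clr_pseudocount))
    utils::write.table(data.frame(sample_id = rownames(d), d,
                                  check.names = FALSE),
                       file.path(dir_out, paste0("beta_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

# the three-level battery on prepared matrices
run_levels <- function(config, prep, label) {
  X <- prep$X
  Z <- prep$Z
  # global: Procrustes on PCoA of Euclidean distances of the residual
  # matrices (CLR residuals carry covariate-corrected Aitchison geometry)
  ord_genes <- pcoa(stats::dist(X))
  ord_taxa <- suppressWarnings(pcoa(stats::dist(Z)))
  proc <- procrustes_permutation_test(ord_genes, ord_taxa,
                                      n_perm = config$n_perm,
                                      seed = stage_seed(config, 11L))
  # group-group: sparse CCA with LOOCV-tuned penalties
  tuned <- tune_penalties_loocv(X, Z, grid = config$scca_grid)
  k_use <- min(config$scca_k, ncol(X), ncol(Z))
  signif <- suppressWarnings(component_significance_loocv(
    X, Z, tuned$c1_frac, tuned$c2_frac, K = k_use, alpha = config$scca_alpha))
  model <- attr(signif, "model")
  # individual: elastic net per microbe
  fits <- list()
  skipped <- character()
  for (j in seq_len(ncol(Z))) {
    mb <- colnames(Z)[j]
    fits[[mb]] <- tryCatch(
      fit_elastic_net(Z[, j], X, alpha_grid = config$enet_alpha_grid,
                      n_lambda = config$enet_n_lambda,
                      folds = config$enet_folds,
                      repeats = config$enet_repeats,
                      seed = stage_seed(config, 13L + j)),
      error = function(e) {
        skipped <<- c(skipped, mb)
        NULL
      })
  }
  fits <- Filter(Negate(is.null), fits)
  pairs <- if (length(fits) > 0)
    extract_pairs(fits, X = X, Z = Z, region = label)
  else data.frame(gene = character(), microbe = character(),
                  coefficient = numeric(), rho = numeric(),
                  pval = numeric(), region = character(),
                  stringsAsFactors = FALSE)
  # enrichment of genes in significant components
  enrich <- NULL
  if (!is.null(config$gene_sets)) {
    sig_k <- signif$component[signif$significant]
    query <- rownames(model$u)[rowSums(model$u[, sig_k, drop = FALSE] != 0) > 0]
    enrich <- ora(query, colnames(X), config$gene_sets,
                  min_size = config$ora_min_size, alpha = config$ora_alpha)
  }
  list(label = label, ordination_genes = ord_genes, ordination_taxa = ord_taxa,
       procrustes = proc, scca_tuning = tuned, scca_model = model,
       scca_significance = signif, enet_fits = fits, enet_skipped = skipped,
       pairs = pairs, enrichment = enrich)
}

write_bundle <- function(config, prep, levels, dir_out) {
  dir.create(dir_out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir_out, f)
  if (!is.null(prep$contaminants))
    utils::write.table(prep$contaminants, p("contaminant_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_table(prep$taxa_counts, p("taxa_filtered_counts.tsv"))
  write_feature_table(feature_table(t(prep$Z) + 0, "residual"),
                      p("taxa_clr_residual.tsv"))
  write_feature_table(feature_table(t(prep$X) + 0, "residual"),
                      p("genes_residual.tsv"))
  write_ordination(levels$ordination_genes, p("ordination_genes.tsv"))
  write_ordination(levels$ordination_taxa, p("ordination_taxa.tsv"))
  pr <- levels$procrustes
  utils::write.table(data.frame(rho = pr$rho, m12_squared = pr$m12_squared,
                                p_value = pr$p_value,
                                n_permutations = pr$n_permutations,
                                n_samples = pr$n_samples),
                     p("procrustes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(levels$scca_tuning$grid, p("scca_penalty_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sparse_cca_loadings(levels$scca_model, p("scca_loadings.tsv"))
  utils::write.table(levels$scca_significance, p("scca_significance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pair_table(levels$pairs, p("gene_microbe_pairs.tsv"))
  if (!is.null(levels$enrichment))
    utils::write.table(levels$enrichment, p("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    label = levels$label,
    seed = config$seed,
    parameters = config[c("covariates", "region_col", "min_rel_abund",
                          "prevalence_frac", "min_count", "count_frac",
                          "variance_quantile", "clr_pseudocount",
                          "log_cpm_prior", "contaminant_threshold",
                          "n_perm", "scca_k", "scca_alpha", "enet_folds",
                          "enet_repeats", "enet_n_lambda", "ora_min_size",
                          "ora_alpha")],
    stage_seeds = list(procrustes = stage_seed(config, 11L)),
    n_samples = nrow(prep$meta),
    n_genes_final = ncol(prep$X),
    n_taxa_final = ncol(prep$Z),
    scca_penalties = list(c1_frac = levels$scca_tuning$c1_frac,
                          c2_frac = levels$scca_tuning$c2_frac),
    procrustes = list(rho = pr$rho, p_value = pr$p_value),
    n_pairs = nrow(levels$pairs),
    enet_skipped = levels$enet_skipped,
    stages_completed = c("prep", "global", "group_group", "individual",
                         if (!is.null(levels$enrichment)) "enrichment"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir_out)
}

#' Run the intestine-wide three-level analysis
#'
#' Executes filter, normalization, mixed-model residualization (with location
#' as a fixed effect), variance filtering, global Procrustes concordance,
#' sparse CCA (penalty tuning, fit, LOOCV significance), per-microbe elastic
#' net and, when gene sets are supplied, enrichment of the genes loading on
#' significant components. All intermediate tables and a machine-readable run
#' manifest are written to `config$output_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the prepared matrices, level results and
#'   `output_dir`.
#' @export
run_intestine_wide <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  prep <- prepare_matrices(config, config$samples, include_location = TRUE)
  levels <- run_levels(config, prep, label = "intestine_wide")
  out <- file.path(config$output_dir, "intestine_wide")
  write_bundle(config, prep, levels, out)
  run_diversity(config, prep, out)
  invisible(list(prep = prep, levels = levels, output_dir = out))
}

#' Run the per-region three-level analysis
#'
#' Splits samples by region before any transformation (so CLR and all filters
#' are computed within region), then runs the same three-level battery per
#' region without the location fixed effect. Regions with fewer than 3
#' samples are skipped with a warning.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list of per-region results (as in
#'   [run_intestine_wide()]).
#' @export
run_per_region <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  meta <- config$samples[!config$samples$is_control, , drop = FALSE]
  regions <- unique(meta[[config$region_col]])
  out <- list()
  for (rg in regions) {
    sub <- meta[meta[[config$region_col]] == rg, , drop = FALSE]
    if (nrow(sub) < 3) {
      warning("skipping region with <3 samples: ", rg)
      next
    }
    prep <- prepare_matrices(config, sub, include_location = FALSE)
    levels <- run_levels(config, prep, label = rg)
    dir_rg <- file.path(config$output_dir, paste0("region_", rg))
    write_bundle(config, prep, levels, dir_rg)
    run_diversity(config, prep, dir_rg)
    out[[rg]] <- list(prep = prep, levels = levels, output_dir = dir_rg)
  }
  invisible(out)
}
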