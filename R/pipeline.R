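#' Default pipeline configuration
#'
#' Thresholds mirror the published analysis: prevalence filter 0.1% in >= 3
#' samples, consistency filter 0.05% in >= 90% of samples, trend and
#' breakpoint alpha 0.05, specialist thresholds p < 0.01 and FDR < 0.05,
#' interaction BH alpha 0.01, ANOSIM with 10,000 permutations, 100
#' permutation-null replicates.
#'
#' @return Named list of default parameters.
#' @export
default_pipeline_config <- function() {
  list(
    prevalence_min_abund = 0.001, prevalence_min_samples = 3,
    consistency_min_abund = 0.0005, consistency_min_frac = 0.9,
    alpha_trend = 0.05, alpha_break = 0.05,
    p_hs = 0.01, fdr_hs = 0.05,
    interaction_alpha = 0.01, pseudocount = 0.5,
    anosim_perms = 10000, null_perms = 100,
    sparcc_inner = 20, sparcc_outer = 10, sparcc_threshold = 0.1,
    seed = 1
  )
}

.validate_config <- function(cfg) {
  for (a in c("prevalence_min_abund", "consistency_min_abund",
              "consistency_min_frac", "alpha_trend", "alpha_break",
              "p_hs", "fdr_hs", "interaction_alpha")) {
    v <- cfg[[a]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("config: ", a, " must be in [0, 1], got ", v)
  }
  for (a in c("prevalence_min_samples", "anosim_perms", "null_perms",
              "seed"))
    if (!is.numeric(cfg[[a]]) || cfg[[a]] < 0)
      stop("config: ", a, " must be a non-negative number")
  invisible(cfg)
}

#' Run the full spatial/temporal analysis pipeline
#'
#' Chains the stages: read inputs, common scaling, prevalence/consistency
#' filtering, diversity and ordination, spatial classification of the
#' biopsy table, pairwise interaction inference from the fecal time series
#' with the permutation robustness check, temporal and spatial Spearman and
#' SparCC co-occurrence, and the concordance report. Every artifact is
#' written to `out_dir` along with a manifest (input hashes, parameters,
#' seed, package version); rerunning with the same config is bit-identical.
#'
#' @param counts_path Path to the combined TSV count table (raw counts).
#' @param metadata_path Path to the sample metadata TSV.
#' @param taxonomy_path Optional taxonomy TSV (enables the within- versus
#'   between-rank contrast).
#' @param out_dir Output directory (created if absent).
#' @param config Named list overriding entries of
#'   [default_pipeline_config()], or a path to a YAML file of overrides.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(counts_path, metadata_path, taxonomy_path = NULL,
                         out_dir, config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  .validate_config(cfg)
  for (p in c(counts_path, metadata_path, taxonomy_path))
    if (!file.exists(p)) stop("missing input: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  counts <- read_count_table(counts_path)
  metadata <- read_sample_metadata(metadata_path)
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)
  paths <- list()
  save_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  save_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null")
    paths[[name]] <<- p
  }

  md <- metadata[match(sample_ids(counts), metadata$sample_id), ]
  if (any(is.na(md$sample_id)))
    stop("metadata missing for some samples in the count table")
  is_biopsy <- md$sample_type == "biopsy"
  scaled <- common_scale(remove_singletons(counts))
  p <- file.path(out_dir, "scaled_counts.tsv")
  write_count_table(scaled, p); paths[["scaled_counts.tsv"]] <- p

  # --- diversity and ordination (scaled, singleton-removed, unfiltered)
  div <- merge(diversity_table(scaled), metadata, by = "sample_id",
               sort = FALSE)
  save_tsv(div, "diversity.tsv")
  prevalent <- filter_prevalence(scaled, cfg$prevalence_min_abund,
                                 cfg$prevalence_min_samples)
  bc <- bray_curtis(prevalent)
  ord <- nmds(bc, k = 2)
  save_tsv(data.frame(sample_id = rownames(ord$points),
                      nmds1 = ord$points[, 1], nmds2 = ord$points[, 2],
                      stress = ord$stress), "nmds.tsv")
  an_type <- anosim_test(bc, md$sample_type, n_perm = cfg$anosim_perms)
  an_out <- list(fecal_vs_biopsy = an_type[c("statistic", "p_value")])
  if (sum(is_biopsy) >= 4) {
    bc_bio <- bray_curtis(subset_table(prevalent, samples = is_biopsy))
    an_site <- anosim_test(bc_bio, md$site[is_biopsy],
                           n_perm = cfg$anosim_perms)
    an_out$site <- an_site[c("statistic", "p_value")]
  }
  save_json(an_out, "anosim.json")

  # --- spatial classification (biopsy samples, raw counts for exact tests)
  biopsy_raw <- subset_table(counts, samples = md$sample_id[is_biopsy])
  biopsy_scaled <- subset_table(prevalent, samples = is_biopsy)
  keep <- taxa_ids(biopsy_raw) %in% taxa_ids(biopsy_scaled)
  spatial <- classify_spatial(subset_table(biopsy_raw, taxa = keep),
                              metadata, scaled = biopsy_scaled,
                              alpha_trend = cfg$alpha_trend,
                              alpha_break = cfg$alpha_break,
                              p_hs = cfg$p_hs, fdr_hs = cfg$fdr_hs)
  save_tsv(spatial, "spatial_classes.tsv")

  # --- time-series interactions (fecal samples, consistency-filtered)
  fecal <- subset_table(scaled, samples = !is_biopsy)
  fecal <- filter_consistency(fecal, cfg$consistency_min_abund,
                              cfg$consistency_min_frac)
  series <- to_log_relative(fecal, metadata, cfg$pseudocount)
  im <- build_interaction_matrix(series)
  n <- length(im$taxa_ids)
  off <- !diag(n)
  save_tsv(data.frame(
    response = rep(im$taxa_ids, times = n)[off],
    predictor = rep(im$taxa_ids, each = n)[off],
    alpha = im$alpha[off], beta = im$beta[off],
    p_raw = im$p_raw[off], p_bh = im$p_bh[off]), "interactions.tsv")
  save_tsv(classify_interactions(im, cfg$interaction_alpha),
           "interaction_classes.tsv")
  nullres <- permutation_null(series, n_perm = cfg$null_perms,
                              seed = cfg$seed, alpha = cfg$interaction_alpha)
  save_json(nullres[c("pooled_mean_p_raw", "n_pooled", "n_perm",
                      "n_sig_per_rep")], "permutation_null.json")
  if (!is.null(taxonomy)) {
    contrast <- tryCatch(
      taxonomic_contrast(im, taxonomy, "phylum", cfg$interaction_alpha),
      error = function(e) list(error = conditionMessage(e)))
    save_json(contrast, "taxonomic_contrast.json")
  }

  # --- co-occurrence, temporal and spatial
  t_spear <- spearman_matrix(fecal, "temporal")
  t_sparcc <- sparcc_matrix(fecal, cfg$sparcc_outer, cfg$sparcc_threshold,
                            cfg$sparcc_inner, seed = cfg$seed,
                            flavor = "temporal")
  biopsy_same <- subset_table(biopsy_raw, taxa = taxa_ids(fecal))
  prof <- spatial_profile_table(biopsy_same, metadata)
  s_spear <- spearman_matrix(prof, "spatial")
  s_sparcc <- sparcc_matrix(biopsy_same, cfg$sparcc_outer,
                            cfg$sparcc_threshold, cfg$sparcc_inner,
                            seed = cfg$seed, flavor = "spatial")
  for (nm in c("t_spear", "t_sparcc", "s_spear", "s_sparcc")) {
    cm <- get(nm)
    save_tsv(data.frame(taxon = cm$taxa_ids, cm$values,
                        check.names = FALSE),
             paste0("cooccurrence_", cm$flavor, "_", cm$method, ".tsv"))
  }

  # --- concordance
  report <- concordance_report(im, t_spear, t_sparcc, s_spear, s_sparcc,
                               alpha = cfg$interaction_alpha)
  save_json(report, "concordance.json")

  inputs <- c(counts = counts_path, metadata = metadata_path,
              taxonomy = taxonomy_path)
  manifest <- list(
    inputs = as.list(tools::md5sum(inputs)),
    parameters = cfg,
    n_taxa_interaction = n,
    package_version = as.character(utils::packageVersion("gutmosaic")),
    r_version = R.version.string
  )
  save_json(manifest, "manifest.json")
  invisible(paths)
}
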