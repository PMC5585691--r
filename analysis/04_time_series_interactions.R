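#!/usr/bin/env Rscript
# Step 4 -- pairwise interaction inference from the fecal time series.
#
# Consistency-filter the fecal samples (0.05% of reads in >= 90% of days),
# transform to log relative abundances, fit all n^2 - n ordered pairwise
# models, BH-correct at p < 0.01, classify the ecological interaction
# categories, contrast within- vs between-phylum coefficients, and run the
# predictor-permutation robustness check.

suppressPackageStartupMessages(library(gutmosaic))

counts <- read_count_table("results/data/counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")
tax <- read_taxonomy("results/data/taxonomy.tsv")

fecal_ids <- meta$sample_id[meta$sample_type == "fecal"]
fecal <- subset_table(common_scale(subset_table(counts,
                                                samples = fecal_ids)))
fecal <- filter_consistency(fecal, 0.0005, 0.9)
cat("Consistency filter kept", nrow(counts_matrix(fecal)), "of",
    nrow(counts_matrix(counts)), "OTUs for time-series modeling.\n")

series <- to_log_relative(fecal, meta, pseudocount = 0.5)
im <- build_interaction_matrix(series)
n <- length(im$taxa_ids)
off <- !diag(n)
sig <- sum(im$p_bh[off] < 0.01)
cat(sprintf("%d of %d pairwise models significant after BH at p < 0.01 (%.0f%%).\n",
            sig, n^2 - n, 100 * sig / (n^2 - n)))

write.table(data.frame(
  response = rep(im$taxa_ids, times = n)[off],
  predictor = rep(im$taxa_ids, each = n)[off],
  alpha = im$alpha[off], beta = im$beta[off],
  p_raw = im$p_raw[off], p_bh = im$p_bh[off]),
  "results/interactions.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cls <- classify_interactions(im, alpha = 0.01)
write.table(cls, "results/interaction_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Interaction categories among classified pairs:\n")
print(table(cls$category[cls$category != "none"]))

contrast <- tryCatch(taxonomic_contrast(im, tax, "phylum", alpha = 0.01),
                     error = function(e) NULL)
if (!is.null(contrast))
  cat(sprintf(paste0("Within-phylum vs between-phylum significant ",
                     "coefficients: %.3f vs %.3f (one-sided Wilcoxon ",
                     "p = %.2g).\n"),
              contrast$mean_within, contrast$mean_between,
              contrast$p_value))

nullres <- permutation_null(series, n_perm = 100, seed = 11, alpha = 0.01)
cat(sprintf(paste0("Permutation null: mean raw p = %.3f over %d models; ",
                   "%.0f%% of permuted replicates had zero significant ",
                   "models.\n"),
            nullres$pooled_mean_p_raw, nullres$n_pooled,
            100 * mean(nullres$n_sig_per_rep == 0)))

jsonlite::write_json(list(
  n_taxa = n, n_models = n^2 - n, n_significant = sig,
  taxonomic_contrast = contrast,
  permutation_null = nullres[c("pooled_mean_p_raw", "n_pooled",
                               "n_sig_per_rep")]
), "results/interaction_summary.json", auto_unbox = TRUE, digits = NA)
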