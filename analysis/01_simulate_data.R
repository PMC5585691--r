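#!/usr/bin/env Rscript
# Step 1 -- generate the ground-truthed study data.
#
# One simulated subject: a 139-day daily fecal count time series driven by a
# known sparse interaction matrix (competitive pairs), plus a triplicate
# 7-site biopsy table in which the members of each competitive pair share a
# spatial niche (niche_coupling = 1), plus a separate biopsy table built
# from the six spatial archetypes, plus a hierarchical taxonomy.
# Everything downstream runs from these files.

suppressPackageStartupMessages(library(gutmosaic))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20170905

cs <- simulate_coupled_study(n_taxa = 40, n_days = 139, n_pairs = 10,
                             strength = 0.7, niche_coupling = 1,
                             seed = seed)
combined <- cbind(counts_matrix(cs$fecal$counts),
                  counts_matrix(cs$biopsy$counts))
write_count_table(count_table(combined), file.path(out, "counts.tsv"))
write_sample_metadata(rbind(cs$fecal$metadata, cs$biopsy$metadata),
                      file.path(out, "metadata.tsv"))

tax <- generate_taxonomy(n_phyla = 4, genera_per_phylum = 2,
                         otus_per_genus = 5)           # covers 40 OTUs
write.table(tax, file.path(out, "taxonomy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# archetype biopsy table for the spatial-category analysis (step 3)
labels <- spatial_labels(c(flat = 24, MGA = 2, MGD = 2, GAB = 2, GDB = 2,
                           HS = 2, HA = 2))
sp <- simulate_spatial(labels, fold = 4, dispersion = 0.2, seed = seed + 1)
write_count_table(sp$counts, file.path(out, "biopsy_archetypes.tsv"))
write_sample_metadata(sp$metadata,
                      file.path(out, "biopsy_archetypes_metadata.tsv"))
write.table(labels, file.path(out, "biopsy_archetypes_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- list(
  seed = seed,
  beta_true = cs$beta_true,
  competitive_pairs = cs$pairs,
  niche_centers = cs$niche_centers
)
jsonlite::write_json(truth, file.path(out, "truth.json"), digits = NA)

cat("Simulated", nrow(combined), "taxa:",
    ncol(counts_matrix(cs$fecal$counts)), "daily fecal samples and",
    ncol(counts_matrix(cs$biopsy$counts)), "biopsy samples;",
    nrow(cs$pairs), "competitive pairs sharing spatial niches.\n")
cat("Archetype biopsy table:", nrow(labels), "OTUs,",
    sum(labels$category != "flat"), "with true spatial structure.\n")
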