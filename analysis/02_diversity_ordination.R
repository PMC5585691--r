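#!/usr/bin/env Rscript
# Step 2 -- alpha diversity and sample ordination.
#
# Common-scale the combined table (singletons removed, no further filtering
# for diversity), compute per-sample Shannon/richness/evenness, then
# Bray-Curtis distances on the prevalence-filtered table, NMDS, and ANOSIM
# of fecal-vs-biopsy and of biopsy site groupings.

suppressPackageStartupMessages(library(gutmosaic))

counts <- read_count_table("results/data/counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")
dir.create("results", showWarnings = FALSE)

scaled <- common_scale(remove_singletons(counts))
div <- merge(diversity_table(scaled), meta, by = "sample_id", sort = FALSE)
write.table(div, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

site_means <- aggregate(shannon ~ site, div[div$sample_type == "biopsy", ],
                        mean)
site_means <- site_means[order(match(site_means$site, gi_sites)), ]
cat("Mean Shannon index along the GI tract:\n")
print(site_means, row.names = FALSE)

prevalent <- filter_prevalence(scaled, 0.001, 3)
bc <- bray_curtis(prevalent)
ord <- nmds(bc, k = 2, seed = 1)
write.table(data.frame(sample_id = rownames(ord$points),
                       nmds1 = ord$points[, 1], nmds2 = ord$points[, 2]),
            "results/nmds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("NMDS stress: %.3f\n", ord$stress))

md <- meta[match(sample_ids(prevalent), meta$sample_id), ]
a1 <- anosim_test(bc, md$sample_type, n_perm = 10000, seed = 2)
cat(sprintf("ANOSIM fecal vs biopsy: R = %.3f, p = %.2g\n",
            a1$statistic, a1$p_value))
bio <- md$sample_type == "biopsy"
a2 <- anosim_test(bray_curtis(subset_table(prevalent, samples = bio)),
                  md$site[bio], n_perm = 10000, seed = 3)
cat(sprintf("ANOSIM biopsy sites: R = %.3f, p = %.2g\n",
            a2$statistic, a2$p_value))

# genus-collapse robustness: distance structure should survive collapsing
tax <- read_taxonomy("results/data/taxonomy.tsv")
bc_gen <- bray_curtis(collapse_to_rank(prevalent, tax, "genus"))
r <- matrix_correlation(bc, bc_gen)
cat(sprintf("Pearson correlation of OTU- and genus-level distances: %.3f\n",
            r))
jsonlite::write_json(list(
  anosim_fecal_vs_biopsy = a1[c("statistic", "p_value")],
  anosim_site = a2[c("statistic", "p_value")],
  nmds_stress = ord$stress,
  genus_collapse_distance_correlation = r
), "results/ordination.json", auto_unbox = TRUE, digits = NA)
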