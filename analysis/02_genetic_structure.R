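#!/usr/bin/env Rscript
# Genetic-structure arm: filter the simulated read counts, run the
# allele-frequency Gibbs sampler, and summarize individual-level structure
# (genotype PCA), population-level differentiation (pairwise G_ST with 95%
# credible intervals, NMDS) and within-population diversity (pi, Watterson
# theta). Tables land in results/genetics/.

library(popwing)

src <- file.path("results", "simulated")
out <- file.path("results", "genetics")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rcm <- read_read_counts_tsv(file.path(src, "read_counts.tsv"))
flt <- filter_dataset(rcm)
cat(sprintf("filter: %d of %d sites and %d of %d individuals retained\n",
            length(flt$rcm$loci), length(rcm$loci),
            length(flt$rcm$ind), length(rcm$ind)))
utils::write.table(flt$log, file.path(out, "filter_log.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

gib <- gibbs_allele_frequency(flt$rcm, err = 0.005, steps = 2000,
                              burnin = 500, thin = 5, seed = 7001)

pca <- genotype_pca(gib$gp)
cat(sprintf("genotype PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2]))
utils::write.table(
  data.frame(ind = rownames(pca$scores), pop = flt$rcm$pop,
             pca$scores[, 1:4]),
  file.path(out, "genotype_pca_scores.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

gst <- pairwise_gst(gib$afp)
cat("pairwise G_ST (posterior means):\n")
print(round(gst$estimate, 3))
utils::write.table(popwing:::format_gst_table(gst),
                   file.path(out, "gst_table.tsv"), sep = "\t",
                   quote = FALSE, col.names = NA)
utils::write.table(popwing:::gst_long_table(gst),
                   file.path(out, "gst_long.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

nm <- nmds_embed(gst$estimate, dims = 2, restarts = 8, seed = 7002)
cat(sprintf("NMDS of G_ST: stress-1 = %.4f\n", nm$stress))
utils::write.table(data.frame(pop = rownames(nm$scores), nm$scores),
                   file.path(out, "gst_nmds.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

div <- diversity_estimates(flt$rcm, err = 0.005)
cat("diversity estimates:\n")
print(div)
utils::write.table(div, file.path(out, "diversity.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
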