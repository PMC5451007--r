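#!/usr/bin/env Rscript
# Wing-shape arm: generalized Procrustes superimposition, allometry
# correction by regression on centroid size, covariance PCA with per-PC
# ANOVA + Tukey, canonical variate analysis with 95% mean ellipses, and
# pairwise Procrustes distances with permutation tests.

library(popwing)

src <- file.path("results", "simulated")
out <- file.path("results", "wing_shape")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lms <- read_landmarks_csv(file.path(src, "landmarks.csv"))
gpa <- generalized_procrustes(lms)
cat(sprintf("GPA converged in %d iterations; centroid size %.1f-%.1f\n",
            gpa$iterations, min(gpa$centroid_size), max(gpa$centroid_size)))

res <- allometry_correction(gpa)
cat(sprintf("allometry: %.2f%% of shape variance predicted by size\n",
            100 * res$percent_predicted))

pca <- shape_pca(res)
cat(sprintf("shape PCA: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%\n",
            100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2],
            100 * pca$variance_fraction[3]))
utils::write.table(
  data.frame(specimen = rownames(pca$scores), group = res$group,
             pca$scores[, 1:3]),
  file.path(out, "pca_scores.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

for (axis in 1:3) {
  an <- one_way_anova(pca$scores[, axis], res$group)
  cat(sprintf("PC%d ANOVA: F(%d,%d) = %.2f, p = %.2g\n", axis,
              an$df_between, an$df_within, an$F, an$p))
  utils::write.table(tukey_hsd(pca$scores[, axis], res$group),
                     file.path(out, sprintf("pc%d_tukey.tsv", axis)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

cva <- canonical_variates(res)
cat("CVA eigenvalues:", round(cva$eigenvalues, 3), "\n")
utils::write.table(
  data.frame(specimen = rownames(res$residuals), group = res$group,
             cva$scores),
  file.path(out, "cva_scores.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(group_ellipses(cva$scores[, 1:2], res$group),
                   file.path(out, "cva_ellipses.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

pd <- procrustes_distances(gpa, permutations = 10000, seed = 7201)
cat("pairwise Procrustes distances:\n")
print(round(pd$distance, 4))
cat("permutation p-values:\n")
print(signif(pd$p_value, 3))
utils::write.table(pd$distance, file.path(out, "procrustes_distances.tsv"),
                   sep = "\t", quote = FALSE, col.names = NA)
utils::write.table(pd$p_value, file.path(out, "procrustes_pvalues.tsv"),
                   sep = "\t", quote = FALSE, col.names = NA)
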