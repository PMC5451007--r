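#!/usr/bin/env Rscript
# Admixture arm: pseudo-haploid sampling of the admixed cohort, Gibbs
# admixture inference across K = 1..6 with replicate runs, Evanno delta-K
# model choice, and a STRUCTURE-style Q table for the chosen K, compared
# against the generating admixture proportions.

library(popwing)

src <- file.path("results", "simulated")
out <- file.path("results", "admixture")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rcm <- read_read_counts_tsv(file.path(src, "admixed_read_counts.tsv"))
phm <- pseudo_haploid_sample(rcm, seed = 7101)

scan <- admixture_k_scan(phm, k_range = 1:6, replicates = 10, steps = 1500,
                         burnin = 500, thin = 5, seed = 7102)
utils::write.table(scan$lnp, file.path(out, "lnp_by_k.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(scan$delta_k, file.path(out, "delta_k.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
best_k <- scan$delta_k$K[which.max(scan$delta_k$delta_k)]
cat("Evanno delta-K table:\n")
print(scan$delta_k)
cat("chosen K =", best_k, "\n")

q <- scan$Q_best[[as.character(best_k)]]
utils::write.table(data.frame(ind = rownames(q), pop = attr(phm, "pop"), q),
                   file.path(out, "q_matrix.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

q_true <- as.matrix(utils::read.table(file.path(src, "admixture_q_true.tsv"),
                                      header = TRUE, row.names = 1))
if (ncol(q) == ncol(q_true)) {
  al <- align_replicates(list(q_true, q))
  cat(sprintf("mean absolute error of Q against truth: %.3f\n",
              mean(abs(al[[2]] - al[[1]]))))
}
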