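#!/usr/bin/env Rscript
# Generate the synthetic study cohort used by the downstream analysis
# scripts: GBS-style read counts for temporally/geographically structured
# populations, admixed individuals for the clustering arm, wing landmark
# configurations, and melanization measurements. Everything is written as
# plain text under results/simulated/ together with a truth ledger.
#
# The cohort emulates the study design the package targets: several
# populations of a univoltine butterfly, including a sympatric early/late
# flight pair with modest differentiation, plus a strongly diverged
# outgroup population.

library(popwing)

out <- file.path("results", "simulated")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20240401
set.seed(seed)

# --- genetic arm ----------------------------------------------------------
# F = 0.06 puts the flight pair at the low end of the differentiation the
# method is expected to resolve; the outgroup sits near F = 0.45.
pops <- c("early", "late", "outgroup")
freqs <- sim_pop_frequencies(2000, pops, F = 0.06, seed = seed)
# push the outgroup further from the ancestral frequencies
freqs$p["outgroup", ] <- sim_pop_frequencies(2000, "outgroup", F = 0.45,
                                             seed = seed + 1)$p[1, ]
sim <- sim_read_counts(freqs, n_per_pop = 25, coverage = 8, err = 0.005,
                       missing_rate = 0.05, seed = seed + 2)
write_read_counts_tsv(sim$rcm, file.path(out, "read_counts.tsv"))
write_read_counts_vcf(sim$rcm, file.path(out, "read_counts.vcf"))
write_truth_json(list(F_flight_pair = 0.06, F_outgroup = 0.45,
                      n_per_pop = 25, coverage = 8, err = 0.005,
                      seed = seed),
                 file.path(out, "genetics_truth.json"))
cat("wrote read counts:", nrow(sim$rcm$ref), "individuals x",
    ncol(sim$rcm$ref), "loci\n")

# --- admixture arm --------------------------------------------------------
q <- rbind(diag(3)[rep(1:3, each = 30), ], matrix(1 / 3, 10, 3))
adm <- sim_admixed_read_counts(K = 3, loci = 1000, F = 0.1, q = q,
                               coverage = 8, err = 0.005, seed = seed + 3)
write_read_counts_tsv(adm$rcm, file.path(out, "admixed_read_counts.tsv"))
utils::write.table(adm$truth$q_true,
                   file.path(out, "admixture_q_true.tsv"),
                   sep = "\t", quote = FALSE, col.names = NA)
cat("wrote admixed cohort: 90 cluster members + 10 admixed individuals\n")

# --- wing shape -----------------------------------------------------------
eff <- matrix(0, 12, 2)
eff[3, 2] <- 1; eff[5, 2] <- 0.6; eff[9, 1] <- -0.8; eff[11, 2] <- -0.5
eff <- eff / sqrt(sum(eff^2)) * 0.02
av <- matrix(rnorm(24), 12, 2); av <- av / sqrt(sum(av^2)) * 0.01
lms <- sim_landmarks(c(early = 25, late = 25, outgroup = 25),
                     shape_effects = list(early = eff, late = -eff,
                                          outgroup = 2 * eff),
                     allometric_vector = av, noise_sd = 0.01,
                     seed = seed + 4)
write_landmarks_csv(lms, file.path(out, "landmarks.csv"))
write_landmarks_tps(lms, file.path(out, "landmarks.tps"))
cat("wrote", length(lms$specimens), "landmark configurations\n")

# --- melanization ---------------------------------------------------------
mel <- sim_melanization(c(early = 25, late = 25, outgroup = 25),
                        slope = 0.2,
                        group_offsets = list(early = 8, late = -8,
                                             outgroup = 0),
                        noise_sd = 3, seed = seed + 5)
utils::write.table(mel[, c("specimen", "group", "area_1", "area_2",
                           "melanization_1", "melanization_2")],
                   file.path(out, "melanization.csv"),
                   sep = ",", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(mel), "melanization records\n")
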