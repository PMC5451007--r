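Package: popwing
Title: Population Genomics and Wing Phenotypes for Temporally Isolated Insect Flights
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether sympatric, temporally isolated insect
    flights are genetically and phenotypically differentiated, from
    genotyping-by-sequencing read counts and wing measurements. Implements
    Bayesian genotype and allele-frequency inference from read counts by
    Gibbs sampling, Nei's pairwise G_ST with credible intervals and NMDS
    summaries, STRUCTURE-style admixture inference on pseudo-haploid calls
    with Evanno delta-K model choice, EM-based diversity estimation
    (nucleotide diversity and Watterson's theta), generalized Procrustes
    landmark morphometrics with allometry correction and canonical variate
    analysis, and wing melanization measurement with size-corrected
    ANOVA/Tukey comparisons. A synthetic-data module generates read counts,
    landmark configurations and melanization tables with known truth for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
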