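test_that("site and individual filters fire on their thresholds", {
  # 10 individuals; locus 1 covered in only 2 (< 25%); locus 2 leaves pop B
  # with 14 reads (< 15); locus 3 passes everywhere.
  ref <- matrix(0L, 10, 3)
  alt <- matrix(0L, 10, 3)
  ref[1:2, 1] <- 20L                      # locus 1: 2/10 individuals covered
  ref[1:5, 2] <- 10L                      # locus 2: pop A rich ...
  ref[6:10, 2] <- c(3L, 3L, 3L, 3L, 2L)   # ... pop B total 14 reads
  ref[, 3] <- 4L                          # locus 3: fine
  pop <- rep(c("A", "B"), each = 5)
  res <- filter_dataset(make_rcm(ref, alt, pop))
  expect_equal(res$rcm$loci, "locus3")
  expect_setequal(res$log$rule[res$log$item == "locus1"], "site_coverage")
  expect_true(grepl("min_reads_population:B",
                    res$log$rule[res$log$item == "locus2"]))
  # boundary: exactly 15 reads survives
  ref[10, 2] <- 3L
  res2 <- filter_dataset(make_rcm(ref, alt, pop))
  expect_true("locus2" %in% res2$rcm$loci)
})

test_that("multiallelic sites and high-missingness individuals are dropped", {
  ref <- matrix(5L, 8, 4)
  ref[1, ] <- 0L                          # individual 1: 100% missing
  res <- filter_dataset(make_rcm(ref, matrix(0L, 8, 4), rep("A", 8)),
                        allele_count_per_site = c(2L, 3L, 2L, 4L))
  expect_setequal(res$rcm$loci, c("locus1", "locus3"))
  expect_false("ind1" %in% res$rcm$ind)
  expect_setequal(res$log$rule[res$log$type == "individual"],
                  "individual_missingness")
  # all sites removed is an explicit empty status
  empty <- filter_dataset(make_rcm(matrix(0L, 4, 2), matrix(0L, 4, 2),
                                   rep("A", 4)))
  expect_identical(empty$status, "empty")
  expect_null(empty$rcm)
})

test_that("filtering is idempotent on generated data", {
  fr <- sim_pop_frequencies(150, c("A", "B"), F = 0.1, seed = 91)
  sim <- sim_read_counts(fr, n_per_pop = 12, coverage = 5,
                         missing_rate = 0.25, seed = 92)
  f1 <- filter_dataset(sim$rcm)
  f2 <- filter_dataset(f1$rcm)
  expect_identical(f2$rcm, f1$rcm)
  expect_equal(nrow(f2$log), 0)
})

test_that("genotype PCA separates simulated clusters", {
  fr <- sim_pop_frequencies(400, c("A", "B"), F = 0.1, seed = 95)
  sim <- sim_read_counts(fr, n_per_pop = 15, coverage = 10, seed = 96)
  gib <- gibbs_allele_frequency(sim$rcm, steps = 800, burnin = 200, thin = 4,
                                seed = 97)
  pca <- genotype_pca(gib$gp)
  s1 <- pca$scores[sim$rcm$pop == "A", 1]
  s2 <- pca$scores[sim$rcm$pop == "B", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))
  expect_gt(pca$variance_fraction[1], pca$variance_fraction[2])
  expect_lte(sum(pca$variance_fraction), 1 + 1e-9)
})

test_that("identical individuals give a degenerate PCA", {
  gp <- array(rep(c(0.2, 0.5, 0.3), each = 12), c(4, 3, 3))
  pca <- genotype_pca(gp)
  expect_lt(max(abs(pca$scores)), 1e-10)
  expect_equal(sum(pca$variance_fraction), 0)
  expect_error(genotype_pca(array(0.3, c(1, 3, 3))), "2 individuals")
})

test_that("G_ST closed forms match hand arithmetic", {
  expect_equal(gst_pair(0.5, 0.5), 0)
  expect_equal(gst_pair(1, 0), 1)
  expect_equal(gst_pair(0.2, 0.8), 0.36, tolerance = 1e-12)
  expect_true(is.na(gst_pair(c(0, 1), c(0, 1))) ||
                gst_pair(c(0, 1), c(0, 1)) >= 0)  # monomorphic pair handled
  expect_true(is.na(gst_pair(0, 0)))
})

test_that("pairwise G_ST matrices are well-formed with covering intervals", {
  fr <- sim_pop_frequencies(200, c("A", "B", "C"), F = 0.15, seed = 101)
  sim <- sim_read_counts(fr, n_per_pop = 10, coverage = 10, seed = 102)
  gib <- gibbs_allele_frequency(sim$rcm, steps = 900, burnin = 300, thin = 3,
                                seed = 103)
  gst <- pairwise_gst(gib$afp)
  expect_equal(gst$estimate, t(gst$estimate))
  expect_true(all(diag(gst$estimate) == 0))
  off <- upper.tri(gst$estimate)
  expect_true(all(gst$estimate[off] >= 0 & gst$estimate[off] <= 1))
  expect_true(all(gst$ci_low[off] <= gst$estimate[off] + 1e-12))
  expect_true(all(gst$ci_high[off] >= gst$estimate[off] - 1e-12))
  tab <- popwing:::format_gst_table(gst)
  expect_match(tab[1, 2], "^0\\.\\d+-0\\.\\d+$")
  expect_match(tab[2, 1], "^0\\.\\d+$")
})

test_that("pseudo-haploid sampling follows read proportions", {
  rcm <- make_rcm(cbind(rep(10L, 4), rep(0L, 4), rep(5L, 4)),
                  cbind(rep(0L, 4), rep(0L, 4), rep(5L, 4)),
                  rep("A", 4))
  ph <- pseudo_haploid_sample(rcm, seed = 5)
  expect_true(all(ph[, 1] == 1L))          # all-reference reads
  expect_true(all(is.na(ph[, 2])))         # zero depth is missing
  # balanced reads: call-2 frequency 0.5 within binomial error
  big <- make_rcm(matrix(5L, 4000, 1), matrix(5L, 4000, 1), rep("A", 4000))
  phb <- pseudo_haploid_sample(big, seed = 6)
  expect_lt(abs(mean(phb == 2L) - 0.5), 0.025)
  expect_identical(pseudo_haploid_sample(big, seed = 6), phb)
})
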