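test_that("F-model frequencies have the Beta mean/variance structure", {
  # fixed p0, many replicate loci: sample variance approaches F*p0*(1-p0)
  fr <- sim_pop_frequencies(10000, c("A", "B"), F = 0.1,
                            p0_range = c(0.5, 0.5 + 1e-9), seed = 11)
  v <- var(fr$p[1, ])
  se <- 0.025 * sqrt(2 / 9999)        # approx SE of a variance estimate
  expect_lt(abs(v - 0.025), 4 * se)
  expect_lt(abs(mean(fr$p[2, ]) - 0.5), 0.005)
  expect_true(all(fr$p >= 0 & fr$p <= 1))
})

test_that("F near zero collapses population frequencies onto p0", {
  fr <- sim_pop_frequencies(200, c("A", "B"), F = 1e-7, seed = 2)
  expect_lt(max(abs(sweep(fr$p, 2, fr$p0))), 0.01)
})

test_that("generators are pure functions of their seed", {
  f1 <- sim_pop_frequencies(100, c("A", "B"), F = 0.1, seed = 7)
  f2 <- sim_pop_frequencies(100, c("A", "B"), F = 0.1, seed = 7)
  expect_identical(f1, f2)
  s1 <- sim_read_counts(f1, n_per_pop = 5, coverage = 8, seed = 3)
  s2 <- sim_read_counts(f1, n_per_pop = 5, coverage = 8, seed = 3)
  expect_identical(s1, s2)
  m1 <- sim_melanization(c(a = 10, b = 10), seed = 5)
  m2 <- sim_melanization(c(a = 10, b = 10), seed = 5)
  expect_identical(m1, m2)
  l1 <- sim_landmarks(c(a = 5, b = 5), seed = 9)
  l2 <- sim_landmarks(c(a = 5, b = 5), seed = 9)
  expect_identical(l1, l2)
  a1 <- sim_admixed_read_counts(2, 50, F = 0.2, q = 1, n_ind = 8, seed = 4)
  a2 <- sim_admixed_read_counts(2, 50, F = 0.2, q = 1, n_ind = 8, seed = 4)
  expect_identical(a1, a2)
})

test_that("invalid generator parameters are rejected", {
  expect_error(sim_pop_frequencies(10, "A", F = 0), "F")
  expect_error(sim_pop_frequencies(10, "A", F = 1.2), "F")
  fr <- sim_pop_frequencies(10, "A", F = 0.1, seed = 1)
  expect_error(sim_read_counts(fr, n_per_pop = 0, seed = 1), "individual")
  expect_error(sim_read_counts(fr, n_per_pop = 2, err = 0.7, seed = 1), "err")
  badq <- matrix(c(0.6, 0.6), 1, 2)
  expect_error(sim_admixed_read_counts(2, 10, F = 0.1, q = badq, seed = 1),
               "sum to 1")
  expect_error(sim_landmarks(c(a = 3), base_shape = matrix(1, 12, 2)),
               "degenerate")
  expect_error(sim_melanization(c(a = 5), area_range = c(-1, 5)), "positive")
})

test_that("read-count channel has the stated depth and error structure", {
  fr <- sim_pop_frequencies(400, "A", F = 0.1, seed = 21)
  sim <- sim_read_counts(fr, n_per_pop = 25, coverage = 8, err = 0,
                         missing_rate = 0.1, seed = 22)
  depth <- sim$rcm$ref + sim$rcm$alt
  # Poisson(8) thinned by 10% missingness
  expect_lt(abs(mean(depth) - 8 * 0.9), 3 * sqrt(8 / length(depth)) + 0.05)
  # err = 0: homozygotes give pure reads
  hom2 <- sim$truth$genotypes == 2
  expect_true(all(sim$rcm$ref[hom2] == 0))
  hom0 <- sim$truth$genotypes == 0
  expect_true(all(sim$rcm$alt[hom0] == 0))
  # HWE genotype proportions at the generating frequencies (3 SE at n=1e4)
  p <- as.vector(fr$p[1, ])
  exp_het <- mean(2 * p * (1 - p))
  obs_het <- mean(sim$truth$genotypes == 1)
  expect_lt(abs(obs_het - exp_het),
            3 * sqrt(exp_het * (1 - exp_het) / length(sim$truth$genotypes)))
})

test_that("admixture generator degenerates correctly", {
  # q = (1, 0): alleles drawn solely from cluster 1
  q <- matrix(rep(c(1, 0), each = 6), 6, 2)
  sim <- sim_admixed_read_counts(2, 300, F = 0.9, q = q, coverage = 30,
                                 err = 0, seed = 31)
  p1 <- sim$truth$frequencies$p[1, ]
  fixed_ref <- which(p1 < 1e-4)     # cluster-1 loci fixed for allele 1
  expect_true(all(sim$truth$genotypes[, fixed_ref] == 0))
  # K = 1 reduces to a single-population HWE draw
  sim1 <- sim_admixed_read_counts(1, 100, F = 0.1,
                                  q = matrix(1, 5, 1), seed = 32)
  expect_true(all(sim1$truth$q_true == 1))
  expect_equal(dim(sim1$rcm$ref), c(5L, 100L))
})

test_that("landmark generator round-trips through GPA at zero noise", {
  lms <- sim_landmarks(c(A = 8), noise_sd = 0, seed = 41)
  g <- generalized_procrustes(lms)
  x <- flatten_shapes(g)
  expect_lt(max(dist(x)), 1e-8)
  # and the aligned mean matches the base shape up to similarity transform
  base <- lms$truth$base_shape / centroid_size(lms$truth$base_shape)
  rot <- popwing:::rotate_onto(scale(base, scale = FALSE), g$mean_shape)
  expect_lt(sqrt(sum((rot - g$mean_shape)^2)), 1e-8)
})

test_that("melanization residuals recover offsets exactly in a balanced design", {
  # identical area sets in both groups make the offsets orthogonal to area,
  # so zero-noise residuals equal the centered offsets exactly
  areas <- seq(160, 340, length.out = 12)
  tab <- data.frame(group = rep(c("a", "b"), each = 12),
                    wing_area = c(areas, areas),
                    total_melanization = c(0.2 * areas + 5, 0.2 * areas - 5))
  res <- melanization_residuals(tab)
  ra <- mean(res$records$residual_melanization[tab$group == "a"])
  rb <- mean(res$records$residual_melanization[tab$group == "b"])
  expect_equal(ra - rb, 10, tolerance = 1e-9)
  expect_equal(res$slope, 0.2, tolerance = 1e-9)
  # the stochastic generator approaches this as group sizes grow
  big <- sim_melanization(c(a = 150, b = 150), slope = 0.2,
                          group_offsets = list(a = 5, b = -5),
                          noise_sd = 0, measurement_sd = 0, seed = 51)
  rb2 <- melanization_residuals(big)
  d2 <- diff(rev(tapply(rb2$records$residual_melanization, big$group, mean)))
  expect_lt(abs(d2 - 10), 1)
})

test_that("rendered wing images carry exact pixel bookkeeping", {
  img <- render_wing_image(12000, 2000, px_per_mm = 100)
  expect_identical(sum(img$image == 0), 10000L)
  expect_equal(img$black_px, 10000)
  img2 <- render_wing_image(900, 0, px_per_mm = 10)
  expect_identical(sum(img2$image == 0), 900L)
})
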