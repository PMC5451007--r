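test_that("centroid size matches hand arithmetic and scales linearly", {
  expect_equal(centroid_size(rbind(c(0, 0), c(2, 0))), sqrt(2))
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(square), sqrt(2))
  cfg <- matrix(rnorm(24), 12, 2)
  expect_equal(centroid_size(cfg * 3.7), 3.7 * centroid_size(cfg))
  expect_warning(cs0 <- centroid_size(matrix(1, 5, 2)), "degenerate")
  expect_equal(cs0, 0)
})

test_that("GPA aligns copies of one shape exactly", {
  lms <- sim_landmarks(c(A = 10), noise_sd = 0, seed = 3)
  g <- generalized_procrustes(lms)
  expect_lt(max(dist(flatten_shapes(g))), 1e-8)
  expect_true(g$converged)
  # aligned configurations are centered; mean shape has unit size
  for (i in 1:10)
    expect_lt(max(abs(colMeans(g$coords[, , i]))), 1e-9)
  expect_equal(centroid_size(g$mean_shape), 1, tolerance = 1e-9)
})

test_that("two-shape alignment is symmetric", {
  lms <- sim_landmarks(c(A = 2), noise_sd = 0.05, seed = 7)
  swapped <- landmark_set(lms$coords[, , 2:1], lms$group, c("s2", "s1"))
  g1 <- generalized_procrustes(lms)
  g2 <- generalized_procrustes(swapped)
  d1 <- sqrt(sum((g1$coords[, , 1] - g1$coords[, , 2])^2))
  d2 <- sqrt(sum((g2$coords[, , 1] - g2$coords[, , 2])^2))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("downstream statistics are similarity-invariant", {
  eff <- list(A = shape_effect(0.02), B = -shape_effect(0.02))
  lms <- sim_landmarks(c(A = 14, B = 14), shape_effects = eff,
                       noise_sd = 0.01, seed = 13)
  tr <- apply_similarity(lms, global_scale = 2.3, seed = 14)
  g1 <- generalized_procrustes(lms)
  g2 <- generalized_procrustes(tr)
  r1 <- allometry_correction(g1)
  r2 <- allometry_correction(g2)
  p1 <- shape_pca(r1); p2 <- shape_pca(r2)
  expect_lt(max(abs(p1$eigenvalues - p2$eigenvalues)), 1e-8)
  c1 <- canonical_variates(r1); c2 <- canonical_variates(r2)
  expect_lt(max(abs(c1$eigenvalues - c2$eigenvalues)), 1e-6)
  pd1 <- procrustes_distances(g1, permutations = 120, seed = 1)
  pd2 <- procrustes_distances(g2, permutations = 120, seed = 1)
  expect_lt(max(abs(pd1$distance - pd2$distance)), 1e-8)
})

test_that("allometry correction recovers the generating size effect", {
  set.seed(23)
  av <- matrix(rnorm(24), 12, 2)
  av <- av / sqrt(sum(av^2)) * 0.02
  lms <- sim_landmarks(c(A = 40), allometric_vector = av, noise_sd = 0.005,
                       seed = 24)
  res <- allometry_correction(generalized_procrustes(lms))
  expect_gt(res$percent_predicted, 0.3)
  # residuals are exactly uncorrelated with centroid size
  cs_c <- res$centroid_size - mean(res$centroid_size)
  expect_lt(max(abs(crossprod(res$residuals, cs_c))), 1e-9)
  # no generating allometry: nothing predicted
  lms0 <- sim_landmarks(c(A = 25), noise_sd = 0.01, seed = 25)
  res0 <- allometry_correction(generalized_procrustes(lms0))
  expect_lt(res0$percent_predicted, 0.1)
})

test_that("allometry regression direction matches the truth at low noise", {
  set.seed(27)
  av <- matrix(rnorm(24), 12, 2)
  av <- av / sqrt(sum(av^2)) * 0.05
  g <- generalized_procrustes(
    sim_landmarks(c(A = 50), allometric_vector = av, noise_sd = 0.005,
                  seed = 28))
  res <- allometry_correction(g)
  # the aligned frame sits at an arbitrary global rotation relative to the
  # generator's base frame: express the truth vector there before comparing
  lms <- sim_landmarks(c(A = 50), allometric_vector = av, noise_sd = 0.005,
                       seed = 28)
  v <- truth_in_aligned_frame(av, lms$truth$base_shape, g$mean_shape)
  expect_gt(cosine(res$regression_vector, v), 0.95)
})

test_that("shape PCA satisfies the trace identity and rank bound", {
  eff <- list(A = shape_effect(0.03), B = -shape_effect(0.03))
  lms <- sim_landmarks(c(A = 20, B = 20), shape_effects = eff,
                       noise_sd = 0.01, seed = 33)
  g <- generalized_procrustes(lms)
  res <- allometry_correction(g)
  pca <- shape_pca(res)
  expect_equal(sum(pca$eigenvalues),
               sum(scale(res$residuals, scale = FALSE)^2) / (nrow(res$residuals) - 1),
               tolerance = 1e-9)
  expect_lte(sum(pca$eigenvalues > 1e-12 * pca$eigenvalues[1]), 20)
  # PC1 tracks the group-difference direction at low noise (the truth
  # vector must first be expressed in the aligned frame)
  dvec <- truth_in_aligned_frame(eff$A - eff$B, lms$truth$base_shape,
                                 g$mean_shape)
  expect_gt(cosine(pca$rotation[, 1], dvec), 0.8)
})

test_that("CVA matches an independent Fisher-discriminant solve at g = 2", {
  eff <- list(A = shape_effect(0.02), B = -shape_effect(0.02))
  lms <- sim_landmarks(c(A = 18, B = 18), shape_effects = eff,
                       noise_sd = 0.01, seed = 43)
  res <- allometry_correction(generalized_procrustes(lms))
  cva <- canonical_variates(res)
  expect_equal(length(cva$eigenvalues), 1L)
  # independent solve in an independently-built full-rank basis
  xc <- scale(res$residuals, scale = FALSE)
  sv <- svd(xc)
  keep <- sv$d^2 > 1e-10 * sv$d[1]^2
  z <- xc %*% sv$v[, keep]
  fisher <- fisher_direction(z, res$group)
  cva_dir <- crossprod(sv$v[, keep], cva$axes[, 1])
  expect_gt(cosine(fisher, as.vector(cva_dir)), 0.9999)
  # scores have unit pooled within-group variance
  w <- unlist(lapply(unique(res$group), function(g)
    scale(cva$scores[res$group == g, 1], scale = FALSE)))
  expect_equal(sum(w^2) / (length(w) - 2), 1, tolerance = 1e-9)
})

test_that("CVA degenerates correctly and bounds its axis count", {
  set.seed(47)
  x <- matrix(rnorm(40 * 6), 40, 6)
  g4 <- rep(letters[1:4], each = 10)
  cva <- canonical_variates(x, g4)
  expect_lte(length(cva$eigenvalues), 3)
  expect_equal(sum(cva$percent_among_variance), 100, tolerance = 1e-6)
  # exactly identical group means (duplicated data): eigenvalues are zero
  z <- matrix(rnorm(60), 10, 6)
  cva0 <- canonical_variates(rbind(z, z), rep(c("a", "b"), each = 10))
  expect_lt(cva0$eigenvalues[1], 1e-8)
  expect_error(canonical_variates(x[1:11, ], c(rep("a", 10), "b")),
               "fewer than 2")
  # eigenvalues are invariant to a nonsingular affine transform
  A <- matrix(rnorm(36), 6, 6) + diag(6)
  cva_t <- canonical_variates(x %*% A, g4)
  expect_equal(cva$eigenvalues, cva_t$eigenvalues, tolerance = 1e-6)
})

test_that("Procrustes distances separate distinct groups via permutation", {
  eff <- list(A = shape_effect(0.03), B = -shape_effect(0.03))
  lms <- sim_landmarks(c(A = 20, B = 20), shape_effects = eff,
                       noise_sd = 0.01, seed = 53)
  g <- generalized_procrustes(lms)
  pd <- procrustes_distances(g, permutations = 500, seed = 54)
  expect_equal(pd$distance, t(pd$distance))
  expect_true(all(diag(pd$distance) == 0))
  expect_lt(pd$p_value[1, 2], 0.05)
  # identical groups: distance near 0, p near 1
  same <- landmark_set(lms$coords, rep(c("x", "y"), 20))
  pd0 <- procrustes_distances(generalized_procrustes(same),
                              permutations = 200, seed = 55)
  expect_gt(pd0$p_value[1, 2], 0.2)
  expect_warning(procrustes_distances(g, permutations = 50, seed = 1),
                 "coarse")
})

test_that("group separation power matches the generator's design", {
  # offset 3x the coordinate noise: permutation p < 0.05 almost always
  hits <- 0
  nrep <- 20
  for (r in seq_len(nrep)) {
    eff <- list(A = shape_effect(0.03), B = -shape_effect(0.03))
    lms <- sim_landmarks(c(A = 20, B = 20), shape_effects = eff,
                         noise_sd = 0.02, seed = 600 + r)
    pd <- procrustes_distances(generalized_procrustes(lms),
                               permutations = 200, seed = 700 + r)
    if (pd$p_value[1, 2] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, round(0.95 * nrep))
})

test_that("mean confidence ellipses have the advertised coverage", {
  # closed form for isotropic covariance
  set.seed(63)
  n <- 500
  s <- 2
  sc <- matrix(rnorm(2 * n, 0, s), n, 2)
  e <- mean_confidence_ellipse(sc)
  expect_lt(abs(e$semi_axes[1] - sqrt(5.991465 * s^2 / n)) / e$semi_axes[1],
            0.15)
  # degenerate input
  ident <- matrix(1, 5, 2)
  e0 <- mean_confidence_ellipse(ident)
  expect_equal(unname(e0$semi_axes), c(0, 0))
  expect_error(mean_confidence_ellipse(ident[1:2, ]), "at least 3")
  # coverage simulation: the true mean falls inside ~95% of ellipses.
  # The chi-square ellipse is asymptotic (it ignores covariance estimation
  # error), so coverage is checked at a moderately large group size.
  inside <- 0
  nrep <- 2000
  for (r in seq_len(nrep)) {
    x <- matrix(rnorm(150 * 2), 150, 2)
    S <- cov(x) / 150
    m <- colMeans(x)
    if (drop(t(-m) %*% solve(S, -m)) <= qchisq(0.95, 2)) inside <- inside + 1
  }
  expect_lt(abs(inside / nrep - 0.95), 0.02)
})

test_that("mirrored wings align with their originals after side reflection", {
  lms <- sim_landmarks(c(A = 6), noise_sd = 0, seed = 71)
  refl <- lms
  refl$coords[, 1, 4:6] <- -refl$coords[, 1, 4:6]   # right wings digitized
  refl <- landmark_set(refl$coords, refl$group, refl$specimens,
                       side = rep(c("L", "R"), each = 3))
  fixed <- mirror_side(refl, side = "R")
  g <- generalized_procrustes(fixed)
  expect_lt(max(dist(flatten_shapes(g))), 1e-8)
  expect_true(all(fixed$side == "L"))
  # without mirroring, rotation-only alignment cannot undo the reflection
  g_bad <- generalized_procrustes(landmark_set(refl$coords, refl$group,
                                               refl$specimens))
  expect_gt(max(dist(flatten_shapes(g_bad))), 0.1)
})
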