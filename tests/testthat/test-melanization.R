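test_that("image measurement is exact on constructed blobs", {
  img <- render_wing_image(12000, 2000, px_per_mm = 100)
  m <- measure_melanization(img$image, img$px_per_mm)
  expect_equal(m$black_area, 1.2)
  expect_equal(m$enclosed_white_area, 0.2)
  expect_equal(m$total_melanization, 1.0)
  # doubling the scale divides areas by 4
  m2 <- measure_melanization(img$image, 200)
  expect_equal(m2$black_area, 1.2 / 4)
  expect_equal(m2$total_melanization, 1.0 / 4)
  # all-white image: zeros with a warning
  expect_warning(m0 <- measure_melanization(matrix(1, 20, 20), 10,
                                            threshold = 0.5), "blank")
  expect_equal(m0$total_melanization, 0)
})

test_that("isodata binarization separates a bimodal image", {
  set.seed(5)
  img <- matrix(1, 50, 50)
  img[10:30, 10:40] <- 0.1                      # dark blob
  img <- img + matrix(rnorm(2500, 0, 0.02), 50, 50)
  thr <- popwing:::isodata_threshold(img)
  expect_gt(thr, 0.2); expect_lt(thr, 0.9)
  m <- measure_melanization(img, 10)
  expect_equal(m$black_area, 21 * 31 / 100, tolerance = 0.02)
})

test_that("melanization size correction has exact OLS identities", {
  set.seed(15)
  tab <- sim_melanization(c(a = 30, b = 30), slope = 0.2,
                          group_offsets = list(a = 6, b = -6), seed = 16)
  res <- melanization_residuals(tab)
  r <- res$records$residual_melanization
  expect_lt(abs(sum(r)), 1e-9)
  expect_lt(abs(sum(r * tab$wing_area)), 1e-6)
  # exactly linear data: R = 1, zero residuals
  lin <- data.frame(wing_area = 1:10, total_melanization = 2 + 3 * (1:10))
  rl <- melanization_residuals(lin)
  expect_equal(rl$R, 1)
  expect_lt(max(abs(rl$records$residual_melanization)), 1e-10)
  # constant area: undefined status, not an error
  const <- data.frame(wing_area = rep(2, 5),
                      total_melanization = rnorm(5))
  expect_identical(melanization_residuals(const)$status, "undefined")
})

test_that("regression slope is recovered at the generator's noise level", {
  tab <- sim_melanization(c(a = 100, b = 100), slope = 0.2, noise_sd = 0.05,
                          measurement_sd = 0, seed = 21)
  res <- melanization_residuals(tab)
  expect_lt(abs(res$slope - 0.2), 0.02)
  expect_gt(res$R, 0.9)
  expect_lt(res$p_value, 0.001)
})

test_that("one-way ANOVA matches hand sums of squares and a brute oracle", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  an <- one_way_anova(v, g)
  expect_equal(an$F, 13.5, tolerance = 1e-12)
  expect_equal(an$df_between, 1L)
  expect_equal(an$df_within, 4L)
  # identical groups: F = 0
  an0 <- one_way_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(an0$F, 0, tolerance = 1e-12)
  # random data against the two-loop oracle
  set.seed(25)
  for (rep in 1:5) {
    vals <- rnorm(40)
    grp <- sample(letters[1:4], 40, replace = TRUE)
    while (any(table(grp) < 2)) grp <- sample(letters[1:4], 40, replace = TRUE)
    expect_equal(one_way_anova(vals, grp)$F, brute_anova_F(vals, grp)$F,
                 tolerance = 1e-10)
  }
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")), "size 1")
})

test_that("Tukey HSD matches its formula, stats::TukeyHSD and the 2F identity", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  tk <- tukey_hsd(v, g)
  expect_equal(tk$q, 3 / sqrt(1 / 3), tolerance = 1e-12)
  # with 2 groups q^2 = 2F
  expect_equal(tk$q^2, 2 * one_way_anova(v, g)$F, tolerance = 1e-9)
  # identical means: q = 0, adjusted p = 1
  tk0 <- tukey_hsd(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(tk0$q, 0)
  expect_equal(tk0$p_adj, 1)
  # agreement with stats::TukeyHSD on unbalanced data
  set.seed(35)
  vals <- rnorm(33)
  grp <- rep(c("a", "b", "c"), c(10, 11, 12))
  ours <- tukey_hsd(vals, grp)
  ref <- stats::TukeyHSD(aov(vals ~ factor(grp)))$`factor(grp)`
  expect_equal(ours$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
  expect_equal(abs(ours$diff), unname(abs(ref[, "diff"])), tolerance = 1e-10)
})

test_that("ANOVA holds its nominal type-I error rate under the null", {
  set.seed(45)
  nrep <- 2000
  groups <- rep(letters[1:8], each = 25)
  gi <- as.integer(factor(groups))
  n <- length(groups)
  hits <- 0
  for (r in seq_len(nrep)) {
    vals <- rnorm(n)
    gm <- tapply(vals, gi, mean)
    ssb <- sum(25 * (gm - mean(vals))^2)
    ssw <- sum((vals - gm[gi])^2)
    F <- (ssb / 7) / (ssw / (n - 8))
    if (pf(F, 7, n - 8, lower.tail = FALSE) < 0.05) hits <- hits + 1
  }
  # 3-sigma band: SE of the rejection rate at 2000 replicates is ~0.005
  expect_lt(abs(hits / nrep - 0.05), 0.015)
  # the fast in-test statistic agrees with the package implementation
  vals <- rnorm(n)
  expect_equal(one_way_anova(vals, groups)$F, brute_anova_F(vals, groups)$F,
               tolerance = 1e-10)
})
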