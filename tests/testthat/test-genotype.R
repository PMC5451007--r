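test_that("genotype likelihoods follow the binomial read-error channel", {
  # zero depth carries no information
  expect_equal(unname(genotype_likelihoods(0, 0, 0.01)[1, ]), c(1, 1, 1))
  # ref=0, alt=10 at err=0.01: direct binomial arithmetic
  l <- genotype_likelihoods(0, 10, err = 0.01)
  expect_equal(unname(l[1, ]), c(0.01^10, 0.5^10, 0.99^10), tolerance = 1e-12)
  # with an HWE prior at p = 0.5 nearly all posterior mass is on g = 2
  post <- l[1, ] * c(0.25, 0.5, 0.25)
  expect_gt(post[3] / sum(post), 0.99)
  # balanced reads favour the heterozygote
  expect_equal(unname(which.max(genotype_likelihoods(5, 5, 0.001)[1, ])), 2L)
  # permuting individuals permutes rows identically
  l2 <- genotype_likelihoods(c(0, 5), c(10, 5), 0.01)
  expect_equal(l2[2:1, ], genotype_likelihoods(c(5, 0), c(5, 10), 0.01),
               ignore_attr = TRUE)
})

test_that("allele-frequency Gibbs recovers the prior with no data", {
  rcm <- make_rcm(matrix(0L, 8, 60), matrix(0L, 8, 60), rep("A", 8))
  res <- gibbs_allele_frequency(rcm, steps = 3000, burnin = 500, thin = 2,
                                seed = 5)
  draws <- as.vector(res$afp$draws)
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  q <- quantile(draws, c(0.025, 0.975))
  expect_lt(abs(q[[1]] - 0.025), 0.02)
  expect_lt(abs(q[[2]] - 0.975), 0.02)
  # genotype posterior triples sum to 1
  expect_lt(max(abs(apply(res$gp, c(1, 2), sum) - 1)), 1e-9)
})

test_that("abundant data recover genotypes and frequencies", {
  fr <- sim_pop_frequencies(200, "A", F = 0.1, seed = 61)
  sim <- sim_read_counts(fr, n_per_pop = 30, coverage = 50, err = 0.001,
                         seed = 62)
  res <- gibbs_allele_frequency(sim$rcm, err = 0.001, steps = 1500,
                                burnin = 400, thin = 2, seed = 63)
  mode_g <- apply(res$gp, c(1, 2), which.max) - 1L
  expect_gt(mean(mode_g == sim$truth$genotypes), 0.99)
  # Gibbs posterior means agree with EM point estimates at high coverage
  # (the Beta(1,1) prior keeps them within 1/(2n+2) of each other)
  em <- vapply(seq_len(200), function(l)
    em_allele_frequencies(genotype_likelihoods(sim$rcm$ref[, l],
                                               sim$rcm$alt[, l], 0.001)),
    numeric(1))
  expect_lt(max(abs(res$afp$posterior_mean[1, ] - em)), 0.02)
})

test_that("Gibbs chains are deterministic given the seed", {
  fr <- sim_pop_frequencies(40, c("A", "B"), F = 0.1, seed = 71)
  sim <- sim_read_counts(fr, n_per_pop = 4, coverage = 6, seed = 72)
  r1 <- gibbs_allele_frequency(sim$rcm, steps = 300, burnin = 50, seed = 73)
  r2 <- gibbs_allele_frequency(sim$rcm, steps = 300, burnin = 50, seed = 73)
  expect_identical(r1$afp$draws, r2$afp$draws)
  expect_identical(r1$gp, r2$gp)
  # stored posterior mean is the mean of stored draws
  expect_equal(r1$afp$posterior_mean,
               apply(r1$afp$draws, c(1, 2), mean), tolerance = 1e-12)
})

test_that("EM allele-frequency estimation matches hand iteration", {
  # degenerate likelihoods fixing genotypes {2, 1}: p = 3/4 after one step
  lik <- rbind(c(0, 0, 1), c(0, 1, 0))
  expect_equal(em_allele_frequencies(lik, iterations = 1), 0.75)
  expect_equal(em_allele_frequencies(lik, iterations = 20), 0.75)
  # flat likelihoods leave any starting point fixed
  flat <- matrix(1, 5, 3)
  expect_equal(em_allele_frequencies(flat, iterations = 20, p_init = 0.3),
               0.3, tolerance = 1e-12)
  expect_error(em_allele_frequencies(matrix(0, 0, 3)), "empty")
})

test_that("EM ascends the observed-data log likelihood", {
  set.seed(81)
  for (rep in 1:5) {
    ref <- rpois(10, 4); alt <- rpois(10, 2)
    lik <- genotype_likelihoods(ref, alt, 0.01)
    p <- 0.5
    lls <- numeric(12)
    for (it in 1:12) {
      p <- em_allele_frequencies(lik, iterations = 1, p_init = p)
      lls[it] <- popwing:::em_loglik(lik, p)
    }
    expect_true(all(diff(lls) > -1e-9))
  }
})

test_that("diversity estimators match their closed forms", {
  expect_equal(watterson_theta(5, 10), 5 / sum(1 / 1:19), tolerance = 1e-12)
  expect_equal(watterson_theta(5, 10), 1.40934805910351, tolerance = 1e-9)
  # single site at p = 0.5 with n = 10: pi = 0.5 * 20/19
  ref <- matrix(c(rep(10L, 5), rep(0L, 5)), 10, 1)
  alt <- matrix(c(rep(0L, 5), rep(10L, 5)), 10, 1)
  rcm <- make_rcm(ref, alt, rep("A", 10))
  d <- diversity_estimates(rcm, err = 0.001)
  expect_equal(d$pi, 0.5 * 20 / 19, tolerance = 1e-6)
  expect_equal(d$S, 1L)
  # monomorphic data: everything zero
  rcm0 <- make_rcm(matrix(10L, 4, 6), matrix(0L, 4, 6), rep("A", 4))
  d0 <- diversity_estimates(rcm0, err = 0.001)
  expect_equal(c(d0$pi, d0$S, d0$theta_w), c(0, 0, 0))
  expect_error(diversity_estimates(make_rcm(matrix(1L, 1, 3),
                                            matrix(0L, 1, 3), "A")),
               "fewer than 2")
})
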