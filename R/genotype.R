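#' Genotype likelihoods from read counts
#'
#' Binomial read-count likelihoods for the three diploid genotypes (0, 1, 2
#' copies of the alternate allele) under a symmetric per-read miscall rate:
#' the probability that a read shows the alternate allele is `err`, 0.5 and
#' `1 - err` for genotypes 0, 1 and 2. Returned unnormalized; zero-depth
#' cells give (1, 1, 1), i.e. the data carry no information.
#'
#' @param ref,alt non-negative read counts (vectors of equal length).
#' @param err per-read miscall rate in [0, 0.5).
#' @return an n x 3 matrix of likelihoods, columns `g0`, `g1`, `g2`.
#' @examples
#' genotype_likelihoods(0, 10, err = 0.01)
#' @export
genotype_likelihoods <- function(ref, alt, err = 0.005) {
  if (any(ref < 0) || any(alt < 0)) stop("read counts must be non-negative")
  if (err < 0 || err >= 0.5) stop("`err` must be in [0, 0.5)")
  d <- ref + alt
  out <- cbind(g0 = dbinom(alt, d, err),
               g1 = dbinom(alt, d, 0.5),
               g2 = dbinom(alt, d, 1 - err))
  out
}

# Likelihood matrices for one population slice: list of three n x L matrices.
likelihood_matrices <- function(ref, alt, err) {
  d <- ref + alt
  list(l0 = matrix(dbinom(alt, d, err), nrow(ref), ncol(ref)),
       l1 = matrix(dbinom(alt, d, 0.5), nrow(ref), ncol(ref)),
       l2 = matrix(dbinom(alt, d, 1 - err), nrow(ref), ncol(ref)))
}

#' Gibbs sampler for population allele frequencies and genotypes
#'
#' Bayesian model treating genotypes and per-population allele frequencies
#' as parameters estimated jointly from read counts. Within each population
#' the sampler alternates between drawing each individual's genotype from
#' the categorical posterior proportional to `L(g) * HWE(g | p)` and drawing
#' the locus frequency from its conjugate Beta posterior
#' `Beta(a0 + sum g, b0 + sum(2 - g))` with a uniform `Beta(1, 1)` prior by
#' default. Populations are independent and run as separate chains.
#'
#' Defaults follow common practice for this model family (100,000 sweeps,
#' 10,000 burn-in); far shorter chains suffice for the synthetic data used
#' in tests because the full conditionals are strongly informative.
#'
#' @param rcm a [read_counts()] object.
#' @param err per-read miscall rate.
#' @param steps,burnin,thin MCMC sweeps, burn-in, and thinning of retained
#'   frequency draws.
#' @param prior length-2 Beta prior (alpha0, beta0) on allele frequencies.
#' @param seed integer seed (fixed seed gives bitwise-identical draws).
#' @return list with
#'   \item{afp}{allele-frequency posterior: `draws` (pop x locus x
#'     retained-draw array), `posterior_mean` (pop x locus), `mcmc_meta`.}
#'   \item{gp}{genotype posterior: n x L x 3 array of post-burn-in genotype
#'     sampling frequencies (each triple sums to 1).}
#' @export
gibbs_allele_frequency <- function(rcm, err = 0.005, steps = 100000,
                                   burnin = 10000, thin = 10,
                                   prior = c(1, 1), seed = 1L) {
  stopifnot(inherits(rcm, "read_counts"))
  if (!(steps > burnin && burnin >= 0)) stop("need steps > burnin >= 0")
  pops <- unique(rcm$pop)
  if (any(table(rcm$pop) < 1)) stop("population with zero individuals")
  n <- length(rcm$ind); L <- length(rcm$loci)
  nret <- length(seq.int(burnin + thin, steps, by = thin))
  draws <- array(NA_real_, c(length(pops), L, nret),
                 dimnames = list(pops, rcm$loci, NULL))
  gp <- array(NA_real_, c(n, L, 3),
              dimnames = list(rcm$ind, rcm$loci, c("g0", "g1", "g2")))
  set.seed(seed)
  for (k in seq_along(pops)) {
    rows <- which(rcm$pop == pops[k])
    lik <- likelihood_matrices(rcm$ref[rows, , drop = FALSE],
                               rcm$alt[rows, , drop = FALSE], err)
    res <- cpp_gibbs_allele_freq(lik$l0, lik$l1, lik$l2,
                                 as.integer(steps), as.integer(burnin),
                                 as.integer(thin), prior[1], prior[2])
    draws[k, , ] <- t(res$draws)
    m <- res$n_geno_sweeps
    gp[rows, , 1] <- res$g0 / m
    gp[rows, , 2] <- res$g1 / m
    gp[rows, , 3] <- res$g2 / m
  }
  afp <- structure(list(draws = draws,
                        posterior_mean = apply(draws, c(1, 2), mean),
                        populations = pops,
                        mcmc_meta = list(steps = steps, burnin = burnin,
                                         thin = thin, seed = seed, err = err,
                                         prior = prior)),
                   class = "allele_freq_posterior")
  list(afp = afp, gp = gp)
}

#' @export
print.allele_freq_posterior <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Allele-frequency posterior: %d populations x %d loci, %d retained draws\n",
              d[1], d[2], d[3]))
  cat(sprintf("MCMC: %d sweeps, %d burn-in, thin %d, seed %d\n",
              x$mcmc_meta$steps, x$mcmc_meta$burnin, x$mcmc_meta$thin,
              x$mcmc_meta$seed))
  invisible(x)
}

#' EM point estimate of an allele frequency from genotype likelihoods
#'
#' Expectation-maximization under Hardy-Weinberg proportions: the E-step
#' computes each individual's genotype posterior proportional to
#' `L(g) * HWE(g | p)`; the M-step sets `p` to the posterior-expected
#' alternate-allele count over `2N`. Twenty iterations is the conventional
#' stopping rule for this estimator and is the default.
#'
#' @param lik n x 3 matrix of genotype likelihoods for one locus in one
#'   population (columns g = 0, 1, 2).
#' @param iterations number of EM iterations (>= 1).
#' @param p_init starting frequency.
#' @return the final estimate `p_hat` in [0, 1].
#' @export
em_allele_frequencies <- function(lik, iterations = 20, p_init = 0.5) {
  lik <- as.matrix(lik)
  if (nrow(lik) < 1) stop("empty likelihood set")
  if (ncol(lik) != 3) stop("`lik` must have 3 columns (genotypes 0,1,2)")
  if (iterations < 1) stop("`iterations` must be >= 1")
  n <- nrow(lik)
  p <- p_init
  for (it in seq_len(iterations)) {
    w <- lik * rep(c((1 - p)^2, 2 * p * (1 - p), p^2), each = n)
    rs <- rowSums(w)
    rs[rs == 0] <- 1          # zero-information rows contribute the prior mean
    post <- w / rs
    p <- sum(post %*% c(0, 1, 2)) / (2 * n)
  }
  p
}

# Observed-data log likelihood of p for one locus (used in EM ascent tests).
em_loglik <- function(lik, p) {
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  sum(log(pmax(as.vector(lik %*% hwe), .Machine$double.xmin)))
}

#' Per-population diversity estimates (pi, Watterson's theta)
#'
#' For each population, per-locus allele frequencies are estimated with
#' [em_allele_frequencies()] from the read counts; a site is called
#' variable when the estimate is farther than `tol` from 0 and 1.
#' Nucleotide diversity `pi` is the mean over variable sites of the
#' bias-corrected expected heterozygosity `2 p (1-p) * 2n / (2n - 1)`;
#' Watterson's estimator is `S / H_{2n-1}` with `S` the segregating-site
#' count and `H` the harmonic number over `2n - 1` sequences.
#'
#' @param rcm a [read_counts()] object.
#' @param err per-read miscall rate.
#' @param iterations EM iterations per site.
#' @param tol variable-site calling tolerance on `|p - {0,1}|`.
#' @return data.frame, one row per population: `population`, `n` (diploids),
#'   `S`, `pi` (per variable site), `theta_w` (per variable-site set),
#'   `theta_w_per_site` (divided by the number of loci examined).
#' @export
diversity_estimates <- function(rcm, err = 0.005, iterations = 20,
                                tol = 1e-6) {
  stopifnot(inherits(rcm, "read_counts"))
  pops <- unique(rcm$pop)
  out <- lapply(pops, function(pk) {
    rows <- which(rcm$pop == pk)
    n <- length(rows)
    if (n < 2) stop("population '", pk, "' has fewer than 2 diploid individuals")
    ref <- rcm$ref[rows, , drop = FALSE]; alt <- rcm$alt[rows, , drop = FALSE]
    phat <- vapply(seq_len(ncol(ref)), function(l) {
      em_allele_frequencies(genotype_likelihoods(ref[, l], alt[, l], err),
                            iterations = iterations)
    }, numeric(1))
    variable <- phat > tol & phat < 1 - tol
    S <- sum(variable)
    an <- sum(1 / seq_len(2 * n - 1))
    pi <- if (S > 0)
      mean(2 * phat[variable] * (1 - phat[variable]) * 2 * n / (2 * n - 1))
    else 0
    theta <- S / an
    data.frame(population = pk, n = n, S = S, pi = pi, theta_w = theta,
               theta_w_per_site = theta / ncol(ref),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Watterson's theta from a segregating-site count
#'
#' `theta_w = S / H_{2n-1}`, the classical estimator from the number of
#' segregating sites `S` in a sample of `2n` sequences (`n` diploids).
#'
#' @param S segregating-site count.
#' @param n diploid sample size (>= 2).
#' @return numeric estimate.
#' @examples
#' watterson_theta(5, 10)  # 5 / H_19
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop("need at least 2 diploid individuals")
  S / sum(1 / seq_len(2 * n - 1))
}
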