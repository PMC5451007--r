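---
title: "Models and methods behind popwing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popwing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

popwing tests whether sympatric insect populations that fly at different
times of the year — and therefore cannot interbreed even though they share
a site — are genetically and phenotypically distinct. The genetic arm
works from genotyping-by-sequencing (GBS) read counts; the phenotypic arm
works from 12-landmark wing configurations and wing melanization
measurements. This vignette documents the models, the defaults and the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Genotype and allele-frequency model

Low-coverage GBS data do not support hard genotype calls, so genotypes
and allele frequencies are treated jointly as unknowns. For an individual
with $a$ alternate reads out of $d$ at a biallelic site, the read-count
likelihood of genotype $g \in \{0,1,2\}$ (copies of the alternate allele)
is binomial,

$$L(g) = \binom{d}{a}\, e(g)^a\, (1-e(g))^{d-a},
\qquad e(0)=\varepsilon,\; e(1)=\tfrac12,\; e(2)=1-\varepsilon,$$

with a single symmetric per-read miscall rate $\varepsilon$ (default
0.005; GBS libraries do not usually come with a calibrated error rate, so
the value is exposed in the configuration). Within each population,
genotypes follow Hardy–Weinberg proportions given the population allele
frequency $p$, and $p$ carries a uniform Beta(1, 1) prior.

The posterior is explored by Gibbs sampling: each individual's genotype
is drawn from the categorical posterior $\propto L(g)\,\mathrm{HWE}(g\mid
p)$, then $p \sim \mathrm{Beta}(1+\sum g,\ 1+\sum(2-g))$. Populations are
independent chains. The conventional full-scale settings for this model
family (100,000 sweeps, 10,000 burn-in) are the `full_scale`
configuration; the full conditionals are so strongly informative that on
the synthetic data used in the tests the chains equilibrate within a few
hundred sweeps, and test runs use 1,200–3,000 sweeps with a quarter
burn-in. Thinning (default 10) bounds the memory held by stored draws;
posterior means are taken over retained draws. A fixed seed makes chains
bitwise reproducible (all randomness flows through R's RNG, including
inside the compiled samplers).

A parallel EM estimator (E-step: genotype posteriors under HWE at the
current $p$; M-step: $p \leftarrow \sum E[g]/2N$; 20 iterations, the
conventional stopping rule) provides per-site point estimates for the
diversity summaries: $\pi$ is the mean over variable sites of the
bias-corrected heterozygosity $2\hat p(1-\hat p)\cdot 2n/(2n-1)$, $S$
counts sites with $\hat p$ farther than $10^{-6}$ from fixation, and
Watterson's $\hat\theta_W = S / \sum_{i=1}^{2n-1} i^{-1}$.

## Filtering

Sites are dropped, in order: more than two alleles (when upstream allele
counts are supplied); fewer than 25% of individuals with at least one
read ("coverage" is interpreted as the fraction of individuals covered,
the natural reading for GBS); total reads below 15 in any population
(interpreted per population-sample total — a per-individual reading would
discard essentially everything at GBS depths). Individuals missing more
than 98% of the retained loci are then removed. Every removal is logged
with the rule that fired.

## Differentiation: Nei's G_ST with credible intervals

For a pair of populations, per-locus $H_S$ is the mean of $2p_k(1-p_k)$
and $H_T = 2\bar p(1-\bar p)$ at the mean frequency. The multi-locus
statistic is the ratio of sums $\sum_\ell (H_T - H_S)/\sum_\ell H_T$,
which is stable at nearly monomorphic loci where per-locus ratios
explode. G_ST is computed per retained MCMC draw — pairing draws at
matched iterations across the independent population chains — giving a
posterior distribution whose mean is the point estimate and whose
2.5/97.5 percentiles form the 95% credible interval.

Two properties of this estimator are worth stating because the recovery
tests measure them. First, with only two demes the expected pairwise
G_ST under the F-model generator (below) is not $F$ but approximately
$F/(2-F)$: per locus $H_T - H_S = (p_1-p_2)^2/2$ with expectation
$F\,p_0(1-p_0)$, while $E[H_T] = 2p_0(1-p_0)(1-F/2)$. Second, the
plug-in estimator computed from a finite sample of $2n$ chromosomes is
biased upward by roughly $p(1-p)/n$ per locus in the numerator. At the
test design (25 diploids per population, 8× coverage) the two effects
approximately cancel for small $F$ — the estimate lands near $F$ itself
for $F \le 0.06$ — but for strong differentiation ($F = 0.45$) the
two-deme factor dominates and the estimate sits near $F/(2-F) \approx
0.29$. The credible interval quantifies read-level posterior uncertainty
only (width a few thousandths at 2,000 loci); it is not a confidence
interval for the generator parameter $F$ and is not expected to cover it.
The acceptance checks record this behaviour as measured.

The G_ST matrix is summarized by non-metric multidimensional scaling:
iterative majorization (Guttman transform) alternating with monotone
regression of configuration distances on dissimilarity ranks
(pool-adjacent-violators via `isoreg`), minimizing Kruskal's stress-1,
best of several random starts plus a classical-scaling start. Ties in
the dissimilarities are handled by the fixed ordering of `order()`
(primary approach); stress is scale-invariant, so no normalization of
the configuration is needed.

## Admixture model and K selection

The clustering arm follows the standard admixture model without linkage:
the data are pseudo-haploid calls — one read sampled per individual-locus
in proportion to read counts, coded 1/2/missing — so heterozygosity never
has to be asserted at low depth. Each call draws a latent cluster of
origin $z \sim \mathrm{Cat}(q_i \odot f)$ and the conjugate updates are
$q_i \sim \mathrm{Dir}(\alpha + \text{counts})$, $p_{kl} \sim
\mathrm{Beta}(1 + \#2, 1 + \#1)$. The Dirichlet parameter $\alpha$ is
fixed (default 1.0) rather than sampled, and exposed in the
configuration. The observed-data log likelihood $\sum \log \sum_k q_{ik}
f_{kl}$ is recorded each sweep; the marginal likelihood for a given K is
estimated as $\mathrm{mean} - \mathrm{var}/2$ of the retained trace, and
K is chosen by the Evanno $\Delta K$ statistic (absolute second
difference of mean $\ln P(X|K)$ normalized by the across-replicate
standard deviation, undefined at the endpoints of the K range and where
the spread is zero). Replicate runs are label-aligned greedily before Q
matrices are compared or averaged; the applied permutations are logged.

Two calibration notes. With a flat $\alpha = 1$ prior and ~1,000
moderately informative pseudo-haploid calls per individual (clusters at
$F = 0.1$), the exact posterior for a cluster member's $q$ has its mean
near 0.85–0.93, not at 1: the data genuinely do not support certainty,
so mean absolute error against a 0/1 truth matrix bottoms out around
0.1 even for a perfect sampler — cluster membership itself is recovered
essentially without error, which is what the tests assert. And Evanno's
$\Delta K$ needs converged replicate runs: with chains an order of
magnitude too short the spread of $\ln P(X|K)$ at the true K inflates
and the statistic misfires, so the K-scan tests run 1,000-sweep chains
(350 burn-in), the shortest length at which replicate spread reflects
genuine posterior variability on data of this strength.

## Geometric morphometrics

Wing shape is captured by 12 landmarks at vein junctions and
vein–margin intersections. Generalized Procrustes superimposition
centers each configuration, scales it to unit centroid size
($\sqrt{\sum \|x_j - \bar x\|^2}$, recorded before scaling), and
iteratively rotates each configuration onto the running mean shape
(rotation only, no reflection — left/right wings should be mirrored
explicitly before analysis), renormalizing the mean to unit size, until
the mean stabilizes (tolerance 1e-10). The aligned shapes are then
orthogonally projected onto the tangent space at the mean. The
projection is the default because the unit-size sphere leaves
second-order curvature variance in the scale and rotation directions:
without it, 12 two-dimensional landmarks span slightly more than the
nominal $2k-4 = 20$ shape dimensions (the 21st eigenvalue is of order
$10^{-5}$ of the first rather than numerically zero), which breaks the
rank accounting and the exact similarity-invariance that downstream
tests rely on. `tangent = FALSE` restores raw partial-Procrustes
coordinates.

Allometry is removed by ordinary least squares of every Procrustes
coordinate on centroid size (raw size, not log — sizes span a narrow
range); residuals feed all downstream analyses. Shape PCA is the
covariance eigendecomposition of the residuals. CVA solves the
generalized eigenproblem of among- versus pooled within-group
covariance after projecting onto principal components with eigenvalues
above $10^{-12}$ of the largest (the rank guard that superimposition
makes necessary); scores are scaled to unit pooled within-group
variance, and at two groups the single axis equals Fisher's
discriminant, which the tests verify against an independent solve.
Group separation is tested by pairwise Procrustes distances between
mean shapes with label permutations (add-one continuity correction).
Mean ellipses use the chi-square 0.95 quantile on two degrees of
freedom (5.991) applied to the sample covariance divided by $n$; this
is asymptotic — it ignores covariance estimation error, so realized
coverage at small $n$ runs a few percent under 95% (about 91.7% at $n =
20$), and the coverage test samples at $n = 150$.

## Melanization

Images are binarized by the iterative intermeans (isodata) threshold
(fixed cutoff available for reproducibility). The filled black region is
the black pixels plus enclosed white pixels (white not 4-connected to
the image border); total melanization is filled area minus enclosed
white area — i.e. the raw black pixel area. The alternative reading
(subtracting all white in the frame) would yield negative values and is
rejected. Areas are converted by the pixels-per-mm scale. Measurement
tables carry duplicate measurements, which are averaged before any
analysis. Size correction regresses total melanization on wing area
(Pearson correlation with a t-test reported alongside); residuals are
compared across groups by one-way ANOVA and Tukey–Kramer HSD
($q = |\bar x_i - \bar x_j| / \sqrt{\mathrm{MSW}(1/n_i + 1/n_j)/2}$,
p-values from the studentized-range distribution).

## Synthetic-data generators

The generators produce data with the statistical structure the analysis
assumes, paired with the generating truth for recovery tests.

* **Allele frequencies** follow an F-model: ancestral $p_0$ uniform on
  (0.05, 0.95) by default, population frequencies Beta-distributed with
  mean $p_0$ and variance $F p_0(1-p_0)$. The F-model was chosen because
  it makes differentiation a single testable dial; the two-deme G_ST
  consequences are derived above.
* **Read counts**: genotypes are HWE draws; depth is Poisson (default
  mean 8, a realistic GBS depth), zeroed with an i.i.d. missingness
  probability; alternate reads are binomial through the same
  $\varepsilon$-channel the model assumes (default 0.005). Real GBS
  missingness is structured by locus and library; i.i.d. missingness is
  a simplification, so filter behaviour on real data is only partially
  exercised.
* **Admixed cohorts** draw each of the two allele copies' cluster of
  origin from the individual's $q$, then the allele from that cluster's
  frequency.
* **Landmarks**: specimen shape = template wing + group effect +
  allometric vector × centered centroid size + i.i.d. Gaussian
  coordinate noise, rescaled to a target size (default 18–26 units) and
  hit with a random rotation and translation (no reflection, matching
  the alignment convention). Group effects must be genuine shape
  deformations; a constant offset is a translation and vanishes under
  alignment.
* **Melanization**: slope × area + group offset + noise, truncated at
  zero, with duplicate measurements carrying small measurement error;
  optionally a rendered binary blob with exactly known filled and hole
  pixel counts for exact-area tests.

Every generator is a pure function of its seed. What passing recovery
tests show is that the estimators invert the generative model they
assume; they do not show robustness to structured missingness, linked
loci, selection, digitization outliers or photographic artefacts, none
of which the generators emulate.

## Problem sizes used by the test suite

Tests run at reduced but honest sizes chosen so every sampler is
converged: G_ST recovery at 2,000 loci and 25 diploids per population
(1,200–1,500 sweeps); admixture recovery at 1,000 loci and 100
individuals (1,000–2,000 sweeps); the Evanno scan over K = 1..6 with 10
replicate runs per K across 5 independently simulated experiments; the
ANOVA null simulation at 2,000 replicates of 8 × 25; ellipse coverage at
2,000 replicates. The `full_scale` switch restores the full-scale MCMC
settings (100,000/10,000 and 100,000/50,000) for real-data use.

## Known limitations

* Only Nei's G_ST is provided (no Weir–Cockerham F_ST), matching the
  analysis this package reimplements.
* The admixture model has no linkage or correlated-frequencies prior,
  and $\alpha$ is fixed, so admixture proportions for weakly
  differentiated clusters are conservative (pulled toward $1/K$).
* The credible intervals on G_ST propagate read-level uncertainty only;
  locus sampling and deme sampling are outside the model.
* Thin-plate-spline deformation grids, semilandmarks and 3-D landmarks
  are out of scope.
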