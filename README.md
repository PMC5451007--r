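# popwing

Population genomics and wing phenotypes for temporally isolated insect
flights.

Some univoltine insects occur as two "flights" at the same site — one
emerging early in the season, one late — that never meet as adults.
popwing implements the analysis used to ask whether such sympatric,
temporally isolated flights are genetically and phenotypically
differentiated, working from genotyping-by-sequencing (GBS) read counts,
12-landmark wing-shape configurations, and wing melanization
measurements. Everything is exercisable on synthetic data with known
truth, so every estimator ships with parameter-recovery tests.

## What it computes

**Genetic arm** (from per-individual, per-locus ref/alt read counts):

- Bayesian genotype and allele-frequency inference. Genotypes and
  frequencies are estimated jointly by Gibbs sampling: the read-count
  likelihood of genotype *g* is binomial with alternate-read probability
  ε, ½, 1−ε for *g* = 0, 1, 2, genotypes follow Hardy–Weinberg
  proportions given the population frequency *p*, and *p* has a
  Beta(1, 1) prior with a conjugate update.
- Nei's pairwise differentiation with uncertainty:
  G_ST = Σ(H_T − H_S) / ΣH_T over loci (ratio of sums), computed per
  MCMC draw to give posterior means and 95% credible intervals; the
  matrix is summarized by non-metric multidimensional scaling (Kruskal
  stress-1, majorization with monotone regression).
- STRUCTURE-style admixture inference on pseudo-haploid calls (one
  sampled read per individual-locus), with marginal likelihoods
  (mean − var/2 of the log-likelihood trace) and Evanno ΔK model choice
  over replicate runs.
- Diversity: per-site allele frequencies by EM (20 iterations), π as
  bias-corrected expected heterozygosity, Watterson's θ = S / H_{2n−1}.
- The study's variant filters: ≥ 25% of individuals covered per site,
  biallelic only, ≥ 15 reads per population per site, ≤ 98% missing per
  individual — applied in that order with a removal log.

**Phenotypic arm**:

- Generalized Procrustes superimposition of 12-landmark wings (rotation
  only, tangent projection), centroid size, allometry correction by
  multivariate regression of shape on centroid size, covariance PCA,
  per-PC ANOVA + Tukey HSD, canonical variate analysis (Fisher's
  discriminant at two groups), pairwise Procrustes distances with
  permutation tests, 95% mean-confidence ellipses.
- Wing melanization from binary images (isodata threshold; melanization
  = filled black area − enclosed white area, in mm²) or measurement
  tables, size-corrected by regression on wing area, compared across
  groups by one-way ANOVA and Tukey–Kramer HSD.

**Synthetic-data module**: F-model population frequencies (Beta around
an ancestral *p₀* with variance F·p₀(1−p₀)), Poisson-depth read counts
through the ε-channel, admixed cohorts, landmark configurations with
group/allometry/noise effects and digitization transforms, melanization
tables and exact-area test images — each a pure function of its seed,
returning the generating truth.

## Worked example

```r
library(popwing)

freqs <- sim_pop_frequencies(800, c("early", "late"), F = 0.06, seed = 1)
sim   <- sim_read_counts(freqs, n_per_pop = 20, coverage = 8,
                         err = 0.005, seed = 2)
flt   <- filter_dataset(sim$rcm)
fit   <- gibbs_allele_frequency(flt$rcm, err = 0.005, steps = 2000,
                                burnin = 500, thin = 5, seed = 3)
pairwise_gst(fit$afp)
#> Pairwise G_ST (lower triangle: estimate; upper: 95% CI)
#>       early late
#> early       0.046-0.052
#> late  0.050

diversity_estimates(flt$rcm)
#>   population  n   S        pi  theta_w theta_w_per_site
#> 1      early 20 772 0.3589284 181.4958        0.2268697
#> 2       late 20 765 0.3585766 179.8501        0.2248126
```

Two flights simulated at F = 0.06 give a posterior-mean G_ST of 0.050
with a narrow 95% credible interval (0.046–0.052): the interval reflects
read-level uncertainty at 800 loci, and the estimate sits where theory
puts the two-deme pairwise G_ST for this generator (see the methods
vignette for why that is close to, but not identical to, F). Both
flights retain essentially all 800 loci as segregating (S = 772 and
765) with per-variable-site π ≈ 0.36.

The numbered scripts under `analysis/` run the full study workflow on a
simulated cohort — `01_simulate.R` through `06_full_pipeline_demo.R` —
writing tables under `results/`. `run_full_pipeline()` drives both arms
from a single YAML configuration (see
`inst/extdata/demo_config.yaml`); the `full_scale` switch restores
full-length MCMC (100,000/10,000 and 100,000/50,000).

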