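#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the per-population allele-frequency model.
//
// Likelihood matrices l0,l1,l2 (individuals x loci) hold the read-count
// likelihood of each genotype (0/1/2 copies of the alternate allele);
// they are constant across the chain, so they are computed once in R.
// The chain alternates: genotype g_{il} ~ Cat( L(g) * HWE(g | p_l) ),
// then p_l ~ Beta(a0 + sum g, b0 + sum (2 - g)).
// Uses R's RNG, so a set.seed() in the caller fixes the chain.
// [[Rcpp::export]]
List cpp_gibbs_allele_freq(NumericMatrix l0, NumericMatrix l1, NumericMatrix l2,
                           int steps, int burnin, int thin,
                           double a0, double b0) {
  int n = l0.nrow(), L = l0.ncol();
  std::vector<double> p(L, 0.5);
  std::vector<int> retained;
  for (int s = burnin + 1; s <= steps; ++s)
    if ((s - burnin) % thin == 0) retained.push_back(s);
  int nret = retained.size();
  NumericMatrix draws(nret, L);
  // post-burn-in genotype tallies (all post-burn-in sweeps, not thinned)
  NumericMatrix c0(n, L), c1(n, L), c2(n, L);
  int r = 0;
  for (int s = 1; s <= steps; ++s) {
    bool keep_geno = s > burnin;
    for (int l = 0; l < L; ++l) {
      double pl = p[l];
      double pr0 = (1.0 - pl) * (1.0 - pl);
      double pr1 = 2.0 * pl * (1.0 - pl);
      double pr2 = pl * pl;
      int sumg = 0;
      for (int i = 0; i < n; ++i) {
        double w0 = l0(i, l) * pr0;
        double w1 = l1(i, l) * pr1;
        double w2 = l2(i, l) * pr2;
        double tot = w0 + w1 + w2;
        int g;
        if (tot <= 0.0) {            // numerically degenerate: fall back to prior
          double u = unif_rand();
          g = (u < pr0) ? 0 : (u < pr0 + pr1 ? 1 : 2);
        } else {
          double u = unif_rand() * tot;
          g = (u < w0) ? 0 : (u < w0 + w1 ? 1 : 2);
        }
        sumg += g;
        if (keep_geno) {
          if (g == 0) c0(i, l) += 1.0;
          else if (g == 1) c1(i, l) += 1.0;
          else c2(i, l) += 1.0;
        }
      }
      p[l] = R::rbeta(a0 + sumg, b0 + 2.0 * n - sumg);
    }
    if (r < nret && s == retained[r]) {
      for (int l = 0; l < L; ++l) draws(r, l) = p[l];
      ++r;
    }
  }
  return List::create(_["draws"] = draws, _["g0"] = c0, _["g1"] = c1,
                      _["g2"] = c2, _["n_geno_sweeps"] = steps - burnin);
}

// STRUCTURE-style admixture Gibbs sampler on pseudo-haploid calls.
//
// calls: individuals x loci, 0 = missing, 1 = allele 1, 2 = allele 2.
// Latent origin z per non-missing call ~ Cat(q_i .* f), f the call's
// frequency under each cluster; conjugate updates
//   q_i ~ Dirichlet(alpha + per-cluster counts),
//   p_kl ~ Beta(1 + allele-2 count, 1 + allele-1 count).
// The per-sweep observed-data log likelihood sum log sum_k q_ik f_kl is a
// by-product of the z pass (evaluated at the pre-update state).
// [[Rcpp::export]]
List cpp_admixture_gibbs(IntegerMatrix calls, int K, int steps, int burnin,
                         int thin, double alpha) {
  int n = calls.nrow(), L = calls.ncol();
  // q stored transposed (K x n) so an individual's proportions are
  // contiguous; p is K x L so a locus' cluster frequencies are contiguous.
  std::vector<double> q(static_cast<size_t>(K) * n), p(static_cast<size_t>(K) * L);
  std::vector<double> pm1(static_cast<size_t>(K) * L);  // 1 - p cache
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    double* qi = &q[static_cast<size_t>(i) * K];
    for (int k = 0; k < K; ++k) { qi[k] = R::rgamma(1.0, 1.0); tot += qi[k]; }
    for (int k = 0; k < K; ++k) qi[k] /= tot;
  }
  for (size_t j = 0; j < p.size(); ++j) { p[j] = unif_rand(); pm1[j] = 1.0 - p[j]; }

  // calls transposed into a flat row-major copy (loci fastest) once
  std::vector<int> crow(static_cast<size_t>(n) * L);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) crow[static_cast<size_t>(i) * L + l] = calls(i, l);

  std::vector<int> retained;
  for (int s = burnin + 1; s <= steps; ++s)
    if ((s - burnin) % thin == 0) retained.push_back(s);
  int nret = retained.size();
  NumericMatrix Qsum(n, K), Psum(K, L);
  NumericVector loglik(steps);
  NumericVector loglik_retained(nret);

  std::vector<double> w(K);
  std::vector<double> nq(static_cast<size_t>(K) * n);
  std::vector<double> a1(static_cast<size_t>(K) * L), a2(static_cast<size_t>(K) * L);
  int r = 0;
  for (int s = 1; s <= steps; ++s) {
    std::fill(nq.begin(), nq.end(), 0.0);
    std::fill(a1.begin(), a1.end(), 0.0);
    std::fill(a2.begin(), a2.end(), 0.0);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* qi = &q[static_cast<size_t>(i) * K];
      double* nqi = &nq[static_cast<size_t>(i) * K];
      const int* ci = &crow[static_cast<size_t>(i) * L];
      for (int l = 0; l < L; ++l) {
        int c = ci[l];
        if (c == 0) continue;
        const double* f = (c == 2) ? &p[static_cast<size_t>(l) * K]
                                   : &pm1[static_cast<size_t>(l) * K];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) { w[k] = qi[k] * f[k]; tot += w[k]; }
        ll += std::log(tot > 0.0 ? tot : 1e-300);
        double u = unif_rand() * tot;
        int z = K - 1;
        double acc = 0.0;
        for (int k = 0; k < K - 1; ++k) { acc += w[k]; if (u < acc) { z = k; break; } }
        nqi[z] += 1.0;
        if (c == 2) a2[static_cast<size_t>(l) * K + z] += 1.0;
        else a1[static_cast<size_t>(l) * K + z] += 1.0;
      }
    }
    loglik[s - 1] = ll;
    // conjugate updates
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      double* qi = &q[static_cast<size_t>(i) * K];
      const double* nqi = &nq[static_cast<size_t>(i) * K];
      for (int k = 0; k < K; ++k) { qi[k] = R::rgamma(alpha + nqi[k], 1.0); tot += qi[k]; }
      if (tot <= 0.0) { for (int k = 0; k < K; ++k) qi[k] = 1.0 / K; }
      else for (int k = 0; k < K; ++k) qi[k] /= tot;
    }
    for (int l = 0; l < L; ++l)
      for (int k = 0; k < K; ++k) {
        size_t j = static_cast<size_t>(l) * K + k;
        p[j] = R::rbeta(1.0 + a2[j], 1.0 + a1[j]);
        pm1[j] = 1.0 - p[j];
      }
    if (r < nret && s == retained[r]) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += q[static_cast<size_t>(i) * K + k];
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          Psum(k, l) += p[static_cast<size_t>(l) * K + k];
      loglik_retained[r] = ll;
      ++r;
    }
  }
  if (nret > 0) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) Qsum(i, k) /= nret;
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) Psum(k, l) /= nret;
  }
  return List::create(_["Q"] = Qsum, _["P"] = Psum,
                      _["loglik_trace"] = loglik_retained,
                      _["loglik_full"] = loglik);
}

// Enclosed-white (hole) bookkeeping for binary wing images.
//
// black: logical matrix, true = black pixel. White pixels 4-connected to
// the image border are background; remaining white pixels are holes
// enclosed by black regions. Returns raw black count and hole count.
// [[Rcpp::export]]
List cpp_count_holes(LogicalMatrix black) {
  int nr = black.nrow(), nc = black.ncol();
  std::vector<char> visited(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack;
  stack.reserve(nr + nc);
  auto push = [&](int r, int c) {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return;
    size_t idx = static_cast<size_t>(c) * nr + r;
    if (visited[idx] || black(r, c)) return;
    visited[idx] = 1;
    stack.push_back(static_cast<int>(idx));
  };
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int r = idx % nr, c = idx / nr;
    push(r - 1, c); push(r + 1, c); push(r, c - 1); push(r, c + 1);
  }
  long black_count = 0, hole_count = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (black(r, c)) ++black_count;
      else if (!visited[static_cast<size_t>(c) * nr + r]) ++hole_count;
    }
  return List::create(_["black"] = black_count, _["holes"] = hole_count);
}
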