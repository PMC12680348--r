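#include <Rcpp.h>
using namespace Rcpp;

// One full Wright-Fisher trajectory on the allele grid.
//
// Per generation: mutation (vector-matrix product with the per-generation
// transition matrix), deterministic diploid selection with additive
// allele-averaged fitness, then multinomial drift at that generation's 2N.
// Uses R's RNG, so results are reproducible under set.seed().
//
// p0       initial allele frequencies (length n)
// tmat     n x n row-stochastic mutation matrix (row = source allele)
// fitness  per-allele fitness w(k), already floored at 0
// sizes    diploid effective size for each generation, past -> present
// [[Rcpp::export(name = ".wf_trajectory")]]
NumericVector wf_trajectory(NumericVector p0, NumericMatrix tmat,
                            NumericVector fitness, IntegerVector sizes) {
  const int n = p0.size();
  if (tmat.nrow() != n || tmat.ncol() != n || fitness.size() != n)
    stop("dimension mismatch between frequencies, matrix and fitness");
  std::vector<double> p(p0.begin(), p0.end()), q(n);
  std::vector<int> counts(n);

  for (R_xlen_t g = 0; g < sizes.size(); ++g) {
    // mutation: q_j = sum_i p_i * T[i, j]
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += p[i] * tmat(i, j);
      q[j] = acc;
    }
    // selection: reweight by marginal fitness (w_j + wbar) / 2
    double wbar = 0.0;
    for (int j = 0; j < n; ++j) wbar += q[j] * fitness[j];
    if (wbar <= 0.0) stop("degenerate fitness: population mean fitness <= 0");
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      q[j] *= (fitness[j] + wbar) / (2.0 * wbar);
      tot += q[j];
    }
    for (int j = 0; j < n; ++j) q[j] /= tot;
    // drift: multinomial sample of 2N alleles
    const int twoN = 2 * sizes[g];
    rmultinom(twoN, q.data(), n, counts.data());
    for (int j = 0; j < n; ++j) p[j] = static_cast<double>(counts[j]) / twoN;
  }
  return wrap(p);
}
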