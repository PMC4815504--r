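#include <Rcpp.h>
using namespace Rcpp;

// G (log-likelihood-ratio) statistic of a k1 x k2 contingency table
// built from two integer-coded genotype vectors (codes 0..k-1).
static double g_stat(const std::vector<int>& tab,
                     const std::vector<int>& rs,
                     const std::vector<int>& cs,
                     int k1, int k2, double n) {
  double g = 0.0;
  for (int i = 0; i < k1; ++i) {
    for (int j = 0; j < k2; ++j) {
      int o = tab[i * k2 + j];
      if (o > 0) {
        double e = (double)rs[i] * (double)cs[j] / n;
        g += o * std::log((double)o / e);
      }
    }
  }
  return 2.0 * g;
}

// Permutation p-value of the genotypic-association G test. g1 and g2 are
// genotype codes in 0..k-1 with no missing values; the second vector is
// permuted n_perm times and the (+1)/(+1)-corrected upper tail returned.
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
List ld_perm_core(IntegerVector g1, IntegerVector g2, int n_perm) {
  int n = g1.size();
  if (g2.size() != n) stop("genotype vectors differ in length");
  int k1 = 0, k2 = 0;
  for (int i = 0; i < n; ++i) {
    if (g1[i] + 1 > k1) k1 = g1[i] + 1;
    if (g2[i] + 1 > k2) k2 = g2[i] + 1;
  }
  std::vector<int> rs(k1, 0), cs(k2, 0), tab(k1 * k2, 0);
  for (int i = 0; i < n; ++i) {
    rs[g1[i]]++;
    cs[g2[i]]++;
    tab[g1[i] * k2 + g2[i]]++;
  }
  double obs = g_stat(tab, rs, cs, k1, k2, (double)n);

  std::vector<int> perm(g2.begin(), g2.end());
  int hits = 0;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      std::swap(perm[i], perm[j]);
    }
    std::fill(tab.begin(), tab.end(), 0);
    for (int i = 0; i < n; ++i) tab[g1[i] * k2 + perm[i]]++;
    double g = g_stat(tab, rs, cs, k1, k2, (double)n);
    if (g >= obs - 1e-12) hits++;
  }
  return List::create(
    _["statistic"] = obs,
    _["p_value"] = (hits + 1.0) / (n_perm + 1.0)
  );
}
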