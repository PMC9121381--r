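#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo sample of the Levene/Haldane conditional distribution of
// genotype arrays given allele counts: gene copies are shuffled and paired.
// Returns the number of sampled arrays whose conditional probability is
// less than or equal to that of the observed array (equal up to `eps`).
// `copies` holds 0-based allele codes of the 2n gene copies; `stat_obs` is
// h*log(2) - sum(lfactorial(f)) for the observed array (the part of the
// log conditional probability that varies across arrays).
// [[Rcpp::export]]
int cpp_hwe_mc_count(IntegerVector copies, int n_ind, int K, int reps,
                     double stat_obs, double eps) {
  int m = copies.size();
  std::vector<int> pool(copies.begin(), copies.end());
  std::vector<double> lfact(n_ind + 1);
  for (int i = 1; i <= n_ind; ++i) lfact[i] = lfact[i - 1] + std::log(i);
  std::vector<int> f(K * K);
  const double log2 = std::log(2.0);
  int count = 0;
  for (int r = 0; r < reps; ++r) {
    // Fisher-Yates shuffle with R's RNG (reproducible under set.seed)
    for (int i = m - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(pool[i], pool[j]);
    }
    std::fill(f.begin(), f.end(), 0);
    int h = 0;
    for (int i = 0; i < n_ind; ++i) {
      int a = pool[2 * i], b = pool[2 * i + 1];
      if (a != b) ++h;
      int lo = a < b ? a : b, hi = a < b ? b : a;
      ++f[lo * K + hi];
    }
    double stat = h * log2;
    for (int c = 0; c < K * K; ++c)
      if (f[c] > 1) stat -= lfact[f[c]];
    if (stat <= stat_obs + eps) ++count;
  }
  return count;
}
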