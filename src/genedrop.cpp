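#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo identity-by-descent relationship estimate by gene dropping.
// Founders receive two unique allele labels; every descendant inherits one
// uniformly chosen allele per parent. For animals i, j the replicate
// contribution is half the count of label matches over the four allele
// pairs, whose expectation is the numerator relationship a_ij (on the
// diagonal it equals 1 + F_i). Uses R's RNG so results are reproducible
// under set.seed().
//
// si, di: 1-based parent positions in pedigree order (0 = unknown).
// [[Rcpp::export]]
List ibd_genedrop_cpp(IntegerVector si, IntegerVector di, int n_rep) {
  const int n = si.size();
  std::vector<int> a1(n), a2(n);
  NumericMatrix acc(n, n), acc2(n, n);
  int next_label;
  for (int rep = 0; rep < n_rep; ++rep) {
    next_label = 0;
    for (int i = 0; i < n; ++i) {
      if (si[i] > 0) {
        int p = si[i] - 1;
        a1[i] = (unif_rand() < 0.5) ? a1[p] : a2[p];
      } else {
        a1[i] = next_label++;
      }
      if (di[i] > 0) {
        int p = di[i] - 1;
        a2[i] = (unif_rand() < 0.5) ? a1[p] : a2[p];
      } else {
        a2[i] = next_label++;
      }
    }
    for (int i = 0; i < n; ++i) {
      const int x1 = a1[i], x2 = a2[i];
      for (int j = i; j < n; ++j) {
        double s = 0.5 * ((x1 == a1[j]) + (x1 == a2[j]) +
                          (x2 == a1[j]) + (x2 == a2[j]));
        acc(i, j) += s;
        acc2(i, j) += s * s;
      }
    }
  }
  NumericMatrix mean(n, n), se(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double m = acc(i, j) / n_rep;
      double v = acc2(i, j) / n_rep - m * m;
      if (v < 0) v = 0;
      double s = std::sqrt(v / n_rep);
      mean(i, j) = mean(j, i) = m;
      se(i, j) = se(j, i) = s;
    }
  }
  return List::create(_["mean"] = mean, _["se"] = se);
}
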