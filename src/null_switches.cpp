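#include <Rcpp.h>
using namespace Rcpp;

// Null distribution of switch counts under within-fibril label shuffling.
//
// labels: 0/1 labeled segments, fibrils concatenated in order;
// start/len: 0-based offset and length of each fibril's slice.
// Returns an n_perm x n_fibril integer matrix of switch counts; each row is
// one independent shuffle of every fibril. Uses R's RNG, so results are
// reproducible after set.seed() on the R side.
// [[Rcpp::export]]
IntegerMatrix null_switch_matrix(IntegerVector labels, IntegerVector start,
                                 IntegerVector len, int n_perm) {
  const int nf = start.size();
  int maxlen = 0;
  for (int f = 0; f < nf; ++f) {
    if (len[f] > maxlen) maxlen = len[f];
  }
  std::vector<int> buf(maxlen);
  IntegerMatrix out(n_perm, nf);
  for (int b = 0; b < n_perm; ++b) {
    for (int f = 0; f < nf; ++f) {
      const int n = len[f];
      const int s0 = start[f];
      for (int i = 0; i < n; ++i) buf[i] = labels[s0 + i];
      // Fisher-Yates using R's uniform stream
      for (int i = n - 1; i > 0; --i) {
        int j = static_cast<int>(unif_rand() * (i + 1));
        if (j > i) j = i;  // guard against unif_rand() == 1.0
        std::swap(buf[i], buf[j]);
      }
      int sw = 0;
      for (int i = 1; i < n; ++i) {
        if (buf[i] != buf[i - 1]) ++sw;
      }
      out(b, f) = sw;
    }
  }
  return out;
}
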