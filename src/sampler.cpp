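#include <Rcpp.h>
using namespace Rcpp;

// Sequential 3'->5' codon sampler shared by the RRT generator and the
// synthetic-data encoder.
//
// aa_sets:  per position, 1-based indices of candidate (synonymous) codons
//           into base_w.
// base_w:   per-codon base weight (bin count, tilted probability, ...).
// mult:     61x61 matrix; mult(a, b) multiplies the weight of codon a when
//           codon b (1-based index) has been chosen at the next position.
//
// The last codon is drawn from base weights alone; each earlier codon from
// base weight x pair multiplier against the codon already chosen 3' of it.
// If all candidate weights vanish (e.g. multiplier 0 across the set), the
// draw falls back to base weights alone, then to uniform. Uses R's RNG so
// set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerVector sample_codons_chain(List aa_sets, NumericVector base_w, NumericMatrix mult) {
  const int L = aa_sets.size();
  IntegerVector out(L);
  int next = -1; // 0-based index of codon chosen at position i + 1
  std::vector<double> w;
  for (int i = L - 1; i >= 0; --i) {
    IntegerVector cand = aa_sets[i];
    const int k = cand.size();
    if (k == 1) {
      out[i] = cand[0];
      next = cand[0] - 1;
      continue;
    }
    w.assign(k, 0.0);
    double tot = 0.0;
    for (int j = 0; j < k; ++j) {
      double wj = base_w[cand[j] - 1];
      if (next >= 0) wj *= mult(cand[j] - 1, next);
      w[j] = wj;
      tot += wj;
    }
    if (!(tot > 0.0)) { // fall back to base weights alone
      tot = 0.0;
      for (int j = 0; j < k; ++j) {
        w[j] = base_w[cand[j] - 1];
        tot += w[j];
      }
    }
    if (!(tot > 0.0)) { // degenerate: uniform over the synonymous set
      for (int j = 0; j < k; ++j) w[j] = 1.0;
      tot = k;
    }
    double u = unif_rand() * tot;
    int j = 0;
    double acc = w[0];
    while (acc < u && j < k - 1) {
      ++j;
      acc += w[j];
    }
    out[i] = cand[j];
    next = cand[j] - 1;
  }
  return out;
}
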