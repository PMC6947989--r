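#include <Rcpp.h>
using namespace Rcpp;

// Circular-shift permutation null for CCV/feature overlap.
//
// Each capture region is circularized independently; all feature pieces of a
// transcript shift by one uniform offset delta in [0, L) with coordinates
// wrapping modulo the region length, so sizes and intra-transcript spacing
// are preserved. CCV positions stay fixed. For each permutation the count of
// distinct CCVs overlapping any shifted feature is returned.
//
// Feature pieces and CCVs arrive region-relative (0-based). A CCV at p
// overlaps a shifted piece (s, len) of transcript t iff
// ((p - s - delta[t]) mod L) < len.
//
// Draw order is fixed (transcript 0..T-1 within each permutation) and uses
// R's global RNG, so set.seed() gives exact replay.
// [[Rcpp::export]]
IntegerVector perm_overlap_counts(IntegerVector feat_start,
                                  IntegerVector feat_len,
                                  IntegerVector feat_tx,
                                  IntegerVector tx_region,
                                  IntegerVector ccv_pos,
                                  IntegerVector ccv_region,
                                  NumericVector region_len,
                                  int n_perm) {
  const int n_feat = feat_start.size();
  const int n_tx = tx_region.size();
  const int n_ccv = ccv_pos.size();
  const int n_reg = region_len.size();

  // features indexed by region for the per-CCV scan
  std::vector<std::vector<int>> reg_feats(n_reg);
  for (int f = 0; f < n_feat; ++f) {
    int r = tx_region[feat_tx[f]];
    reg_feats[r].push_back(f);
  }

  IntegerVector counts(n_perm);
  std::vector<long long> delta(n_tx);

  for (int p = 0; p < n_perm; ++p) {
    for (int t = 0; t < n_tx; ++t) {
      long long L = (long long)region_len[tx_region[t]];
      long long d = (long long)(unif_rand() * (double)L);
      if (d >= L) d = L - 1;  // guard unif_rand() == 1.0
      delta[t] = d;
    }
    int hit_total = 0;
    for (int c = 0; c < n_ccv; ++c) {
      int r = ccv_region[c];
      long long L = (long long)region_len[r];
      const std::vector<int>& feats = reg_feats[r];
      bool hit = false;
      for (size_t i = 0; i < feats.size() && !hit; ++i) {
        int f = feats[i];
        long long a = ((long long)ccv_pos[c] - feat_start[f] - delta[feat_tx[f]]) % L;
        if (a < 0) a += L;
        if (a < feat_len[f]) hit = true;
      }
      if (hit) ++hit_total;
    }
    counts[p] = hit_total;
  }
  return counts;
}
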