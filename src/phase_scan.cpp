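#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Slide a nine-cycle (cycles * period nt) window one nt at a time along a
// reference and, for each window holding enough occupied phase cells, score
// every register r in [0, period):
//   score_r = (k_r - 2) * ln(1 + 10 * P_r / (1 + U_r))   for k_r >= 3
// where k_r = occupied (position, strand) cells whose effective 5' position
// is congruent to r (mod period), P_r = summed count at those cells, and
// U_r = summed count at in-window off-register cells. Only reads whose
// length equals the period contribute (aggregation done by the caller).
//
// `pos` must be sorted ascending effective 0-based positions (one entry per
// occupied (position, strand) cell), `cnt` the matching summed counts.
// Windows whose best register reaches score >= threshold with k >=
// min_k are returned.
// [[Rcpp::export]]
DataFrame cpp_phase_scan(IntegerVector pos, NumericVector cnt, int ref_len,
                         int period, int cycles, int min_k, double threshold) {
  int n = pos.size();
  int w = period * cycles;
  std::vector<int> out_s, out_reg, out_k;
  std::vector<double> out_score, out_P, out_U;
  if (n == 0 || ref_len < w)
    return DataFrame::create(_["start0"] = out_s, _["register"] = out_reg,
                             _["score"] = out_score, _["k"] = out_k,
                             _["P"] = out_P, _["U"] = out_U);
  std::vector<double> P(period);
  std::vector<int> K(period);
  int needk = std::max(min_k, 3);
  int lo = 0, hi = 0; // entries with pos in [s, s + w)
  for (int s = 0; s + w <= ref_len; ++s) {
    while (lo < n && pos[lo] < s) ++lo;
    if (hi < lo) hi = lo;
    while (hi < n && pos[hi] < s + w) ++hi;
    if (hi - lo < needk) continue;
    double total = 0.0;
    for (int t = lo; t < hi; ++t) {
      int r = pos[t] % period;
      P[r] += cnt[t];
      K[r] += 1;
      total += cnt[t];
    }
    double best = -1.0;
    int bestr = -1, bestk = 0;
    double bestP = 0.0, bestU = 0.0;
    for (int t = lo; t < hi; ++t) {
      int r = pos[t] % period;
      if (K[r] == 0) continue; // already evaluated and reset marker below
      if (K[r] >= needk) {
        double U = total - P[r];
        double sc = (K[r] - 2) * std::log1p(10.0 * P[r] / (1.0 + U));
        if (sc > best || (sc == best && r < bestr)) {
          best = sc;
          bestr = r;
          bestk = K[r];
          bestP = P[r];
          bestU = U;
        }
      }
    }
    // reset touched registers
    for (int t = lo; t < hi; ++t) {
      int r = pos[t] % period;
      P[r] = 0.0;
      K[r] = 0;
    }
    if (bestr >= 0 && best >= threshold) {
      out_s.push_back(s);
      out_reg.push_back(bestr);
      out_score.push_back(best);
      out_k.push_back(bestk);
      out_P.push_back(bestP);
      out_U.push_back(total - bestP);
    }
  }
  return DataFrame::create(_["start0"] = out_s, _["register"] = out_reg,
                           _["score"] = out_score, _["k"] = out_k,
                           _["P"] = out_P, _["U"] = out_U);
}
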