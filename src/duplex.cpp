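#include <Rcpp.h>
#include <vector>
#include <string>
#include <cfloat>
using namespace Rcpp;

// sRNA:target duplex scoring.
//
// The sRNA is given 5'->3'; the target window is handled in reversed order
// (wrev[0] is the 3'-most window base), so sRNA position i aligns against
// wrev position i in an ungapped duplex. Penalties: Watson-Crick 0, G:U
// wobble `gu`, mismatch `mismatch`, each bulged nucleotide `bulge`; every
// penalty is multiplied by `outside_mult` when its sRNA position index falls
// outside [core_start, core_end]. A target-strand bulge takes the index of
// the 5'-adjacent consumed sRNA nucleotide and is only allowed internally
// (between sRNA positions 1 and m); terminal target overhangs are a window
// choice, not a bulge.

static const double INF = DBL_MAX / 4.0;
static const double EPS = 1e-9;

static inline int base_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return 4;
}

struct Scheme {
  double mismatch, gu, bulge, outside_mult;
  int core_start, core_end, cap;
};

static Scheme read_scheme(const List &scheme) {
  Scheme s;
  s.mismatch = as<double>(scheme["mismatch"]);
  s.gu = as<double>(scheme["gu_wobble"]);
  s.bulge = as<double>(scheme["bulge"]);
  s.outside_mult = as<double>(scheme["outside_multiplier"]);
  s.core_start = as<int>(scheme["core_start"]);
  s.core_end = as<int>(scheme["core_end"]);
  s.cap = as<int>(scheme["bulge_cap"]);
  return s;
}

static inline double mult(const Scheme &s, int i) {
  return (i >= s.core_start && i <= s.core_end) ? 1.0 : s.outside_mult;
}

// pair penalty between sRNA base a and target-strand base b (both forward
// sense characters; the duplex is antiparallel so WC means complementary)
static inline double pair_pen(const Scheme &s, char a, char b) {
  int ia = base_idx(a), ib = base_idx(b);
  if (ia == 4 || ib == 4) return s.mismatch; // ambiguity codes -> mismatch
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
      (a == 'G' && b == 'C') || (a == 'C' && b == 'G'))
    return 0.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return s.gu;
  return s.mismatch;
}

// Banded DP over (i = consumed sRNA, j = consumed reversed-window chars,
// b = bulged nucleotides so far). Fills D (dimension (m+1) x (n+1) x (cap+1),
// index ((i*(n+1))+j)*(cap+1)+b).
static void fill_dp(const std::string &srna, const std::string &wrev,
                    const Scheme &sc, std::vector<double> &D) {
  int m = srna.size(), n = wrev.size(), B = sc.cap;
  std::fill(D.begin(), D.end(), INF);
  size_t bs = B + 1, js = (n + 1) * bs;
  D[0] = 0.0;
  for (int i = 0; i <= m; ++i) {
    int jlo = std::max(0, i - B), jhi = std::min(n, i + B);
    for (int j = jlo; j <= jhi; ++j) {
      for (int b = 0; b <= B; ++b) {
        if (i == 0 && j == 0) continue;
        double best = INF;
        if (i > 0 && j > 0) {
          double v = D[(size_t)(i - 1) * js + (size_t)(j - 1) * bs + b];
          if (v < INF)
            best = v + pair_pen(sc, srna[i - 1], wrev[j - 1]) * mult(sc, i);
        }
        if (i > 0 && b > 0) { // sRNA nucleotide i bulged
          double v = D[(size_t)(i - 1) * js + (size_t)j * bs + (b - 1)];
          if (v < INF) {
            double cand = v + sc.bulge * mult(sc, i);
            if (cand < best) best = cand;
          }
        }
        if (j > 0 && b > 0 && i >= 1 && i <= m - 1) { // target nt bulged
          double v = D[(size_t)i * js + (size_t)(j - 1) * bs + (b - 1)];
          if (v < INF) {
            double cand = v + sc.bulge * mult(sc, i);
            if (cand < best) best = cand;
          }
        }
        D[(size_t)i * js + (size_t)j * bs + b] = best;
      }
    }
  }
}

// Optimal alignment of the full sRNA against the full window, with traceback.
// `window` is the target subsequence 5'->3'; sRNA position 1 pairs the
// window's 3'-most base.
// [[Rcpp::export]]
List cpp_duplex_align(std::string srna, std::string window, List scheme) {
  Scheme sc = read_scheme(scheme);
  int m = srna.size(), n = window.size(), B = sc.cap;
  if (m < 1) stop("empty sRNA");
  if (std::abs(n - m) > B)
    stop("window length outside sRNA length +/- bulge cap");
  std::string wrev(window.rbegin(), window.rend());
  std::vector<double> D((size_t)(m + 1) * (n + 1) * (B + 1));
  fill_dp(srna, wrev, sc, D);
  size_t bs = B + 1, js = (n + 1) * bs;

  int bbest = 0;
  double best = INF;
  for (int b = 0; b <= B; ++b) {
    double v = D[(size_t)m * js + (size_t)n * bs + b];
    if (v < best - EPS) { best = v; bbest = b; }
  }
  if (best >= INF) stop("no alignment within bulge cap");

  // traceback; deterministic preference: pair, then sRNA bulge, then target bulge
  std::string states;
  IntegerVector pair_j(m, NA_INTEGER);
  int i = m, j = n, b = bbest;
  while (i > 0 || j > 0) {
    double cur = D[(size_t)i * js + (size_t)j * bs + b];
    bool moved = false;
    if (i > 0 && j > 0) {
      double p = pair_pen(sc, srna[i - 1], wrev[j - 1]);
      double v = D[(size_t)(i - 1) * js + (size_t)(j - 1) * bs + b];
      if (v < INF && std::abs(v + p * mult(sc, i) - cur) < EPS) {
        states.push_back(p == 0.0 ? 'M' : (p == sc.gu && p != sc.mismatch ? 'W' : 'X'));
        pair_j[i - 1] = j;
        --i; --j;
        moved = true;
      }
    }
    if (!moved && i > 0 && b > 0) {
      double v = D[(size_t)(i - 1) * js + (size_t)j * bs + (b - 1)];
      if (v < INF && std::abs(v + sc.bulge * mult(sc, i) - cur) < EPS) {
        states.push_back('S');
        --i; --b;
        moved = true;
      }
    }
    if (!moved && j > 0 && b > 0 && i >= 1 && i <= m - 1) {
      double v = D[(size_t)i * js + (size_t)(j - 1) * bs + (b - 1)];
      if (v < INF && std::abs(v + sc.bulge * mult(sc, i) - cur) < EPS) {
        states.push_back('T');
        --j; --b;
        moved = true;
      }
    }
    if (!moved) stop("traceback failed"); // should not happen
  }
  std::reverse(states.begin(), states.end());
  return List::create(_["score"] = best, _["states"] = states,
                      _["pair_j"] = pair_j, _["n_bulges"] = bbest);
}

// Scan every alignment end position on a transcript and report ends whose
// optimal duplex score (window length within sRNA +/- bulge cap) is <=
// max_score. Returns a data.frame of (end0, len, score): the window occupies
// 0-based transcript positions [end0 - len + 1, end0], its 3'-most base
// pairing sRNA position 1.
// [[Rcpp::export]]
DataFrame cpp_duplex_scan(std::string srna, std::string tx, List scheme,
                          double max_score) {
  Scheme sc = read_scheme(scheme);
  int m = srna.size(), B = sc.cap, L = tx.size();
  int nmax = m + B;
  // penalty lookup: pen[i-1][base] = pair penalty * mult, bul[i-1] = bulge*mult
  std::vector<double> pen((size_t)m * 5), bul(m);
  const char bases[5] = {'A', 'C', 'G', 'T', 'N'};
  for (int i = 1; i <= m; ++i) {
    for (int c = 0; c < 5; ++c)
      pen[(size_t)(i - 1) * 5 + c] = pair_pen(sc, srna[i - 1], bases[c]) * mult(sc, i);
    bul[i - 1] = sc.bulge * mult(sc, i);
  }
  std::vector<int> txi(L);
  for (int p = 0; p < L; ++p) txi[p] = base_idx(tx[p]);

  size_t bs = B + 1, js = (nmax + 1) * bs;
  std::vector<double> D((size_t)(m + 1) * (nmax + 1) * (B + 1));
  std::vector<int> ends, lens;
  std::vector<double> scores;

  for (int e = m - B - 1; e < L; ++e) {
    int jcap = std::min(nmax, e + 1); // cannot consume past transcript start
    // column i = 0
    for (int j = 0; j <= std::min(jcap, B); ++j)
      for (int b = 0; b <= B; ++b)
        D[(size_t)j * bs + b] = (j == 0 && b == 0) ? 0.0 : INF;
    bool dead = false;
    for (int i = 1; i <= m && !dead; ++i) {
      double colmin = INF;
      int jlo = std::max(0, i - B), jhi = std::min(jcap, i + B);
      for (int j = jlo; j <= jhi; ++j) {
        int tb = (j >= 1) ? txi[e - (j - 1)] : 4;
        for (int b = 0; b <= B; ++b) {
          double best = INF;
          if (j > 0 && j - 1 >= (i - 1) - B) {
            double v = D[(size_t)(i - 1) * js + (size_t)(j - 1) * bs + b];
            if (v < INF) best = v + pen[(size_t)(i - 1) * 5 + tb];
          }
          if (b > 0 && j <= (i - 1) + B) {
            double v = D[(size_t)(i - 1) * js + (size_t)j * bs + (b - 1)];
            if (v < INF) {
              double cand = v + bul[i - 1];
              if (cand < best) best = cand;
            }
          }
          if (b > 0 && j > 0 && i >= 1 && i <= m - 1 && j - 1 <= i + B &&
              j - 1 >= i - B) {
            double v = D[(size_t)i * js + (size_t)(j - 1) * bs + (b - 1)];
            if (v < INF) {
              double cand = v + bul[i - 1];
              if (cand < best) best = cand;
            }
          }
          D[(size_t)i * js + (size_t)j * bs + b] = best;
          if (best < colmin) colmin = best;
        }
      }
      if (colmin > max_score) dead = true; // penalties never decrease
    }
    if (dead) continue;
    double best = INF;
    int jbest = -1;
    for (int j = std::max(1, m - B); j <= std::min(jcap, m + B); ++j) {
      for (int b = 0; b <= B; ++b) {
        double v = D[(size_t)m * js + (size_t)j * bs + b];
        if (v < best - EPS ||
            (v < best + EPS &&
             (std::abs(j - m) < std::abs(jbest - m) ||
              (std::abs(j - m) == std::abs(jbest - m) && j < jbest)))) {
          best = v;
          jbest = j;
        }
      }
    }
    if (jbest > 0 && best <= max_score + EPS) {
      ends.push_back(e);
      lens.push_back(jbest);
      scores.push_back(best);
    }
  }
  return DataFrame::create(_["end0"] = ends, _["len"] = lens,
                           _["score"] = scores);
}

// Semi-global prefilter: exact minimum duplex score over all alignments
// ending at each transcript position, computed in one pass with shared
// prefixes and clamping of cells above max_score. Returns the unique
// 0-based window-start positions (transcript coordinate of the 5'-most
// consumed base) of every alignment scoring <= max_score; each is then
// confirmed and enumerated by a local per-end scan. Sound: any qualifying
// alignment reports a start within `bulge_cap` of its true window start.
// [[Rcpp::export]]
IntegerVector cpp_duplex_prescan(std::string srna, std::string tx, List scheme,
                                 double max_score) {
  Scheme sc = read_scheme(scheme);
  int m = srna.size(), B = sc.cap, L = tx.size();
  // 6th alphabet slot: 'X' separator used to concatenate transcripts; it can
  // never be part of an alignment
  std::vector<double> pen((size_t)m * 6), bul(m);
  const char bases[5] = {'A', 'C', 'G', 'T', 'N'};
  for (int i = 1; i <= m; ++i) {
    for (int c = 0; c < 5; ++c)
      pen[(size_t)(i - 1) * 6 + c] = pair_pen(sc, srna[i - 1], bases[c]) * mult(sc, i);
    pen[(size_t)(i - 1) * 6 + 5] = 1e9;
    bul[i - 1] = sc.bulge * mult(sc, i);
  }
  std::vector<int> txi(L);
  for (int p = 0; p < L; ++p)
    txi[p] = (tx[p] == 'X') ? 5 : base_idx(tx[p]);

  size_t bs = B + 1;
  const double BIG = 1e7; // clamped sentinel; still addable without overflow
  const double thr = max_score + EPS;
  std::vector<double> prev((size_t)(m + 1) * bs, BIG), cur((size_t)(m + 1) * bs, BIG);
  // column 0: nothing consumed; leading sRNA bulges allowed
  prev[0] = 0.0;
  for (int i = 1; i <= m; ++i)
    for (int b = 1; b <= B; ++b) {
      double cand = prev[(size_t)(i - 1) * bs + (b - 1)] + bul[i - 1];
      prev[(size_t)i * bs + b] = (cand <= thr) ? cand : BIG;
    }
  int reach = 0;
  while (reach < m) {
    bool fin = false;
    for (int b = 0; b <= B; ++b)
      if (prev[(size_t)(reach + 1) * bs + b] < BIG) fin = true;
    if (!fin) break;
    ++reach;
  }
  std::vector<int> starts;
  for (int q = 1; q <= L; ++q) {
    int tb = txi[L - q]; // column q consumes tx position L - q
    // a path may advance one row by a pair plus up to B more rows via
    // chained sRNA bulges within the same column
    int top = std::min(m, reach + 1 + B);
    const double *pr = prev.data();
    double *cu = cur.data();
    cu[0] = 0.0;
    for (int b = 1; b <= B; ++b) cu[b] = BIG;
    int newreach = 0, stop = 0;
    for (int i = 1; i <= top; ++i) {
      const double pp = pen[(size_t)(i - 1) * 6 + tb];
      const double bb = bul[i - 1];
      const double *prow = pr + (size_t)(i - 1) * bs;
      const double *crow = cu + (size_t)(i - 1) * bs;
      double *out = cu + (size_t)i * bs;
      bool fin = false;
      for (int b = 0; b <= B; ++b) {
        double best = prow[b] + pp;
        if (b > 0) {
          double v = crow[b - 1] + bb;
          if (v < best) best = v;
          if (i <= m - 1) {
            v = pr[(size_t)i * bs + (b - 1)] + bb;
            if (v < best) best = v;
          }
        }
        if (best > thr) best = BIG;
        else fin = true;
        out[b] = best;
      }
      stop = i;
      if (fin) newreach = i;
      else if (i > reach + 1) break; // no deeper row can become finite
    }
    // invalidate any stale rows the next column may read
    int clear_to = std::min(m, newreach + 1 + B);
    for (int i = stop + 1; i <= clear_to; ++i)
      for (int b = 0; b <= B; ++b) cur[(size_t)i * bs + b] = BIG;
    if (newreach == m) {
      double best = BIG;
      for (int b = 0; b <= B; ++b)
        if (cur[(size_t)m * bs + b] < best) best = cur[(size_t)m * bs + b];
      if (best <= thr) starts.push_back(L - q);
    }
    std::swap(prev, cur);
    reach = newreach;
  }
  return wrap(starts);
}
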