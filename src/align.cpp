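#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global pairwise alignment under a two-piece affine gap cost:
// a gap run of length L costs min(O1 + E1*L, O2 + E2*L).  Five-state DP
// (match/mismatch plus two gap regimes per sequence).  Regime switches
// mid-run are representable but never optimal (the cost is subadditive),
// so the DP optimum equals the best whole-run-scored alignment.
//
// States: 0 = M (diagonal), 1/2 = gap in y (consume x), regimes 1/2,
//         3/4 = gap in x (consume y), regimes 1/2.
// Tie-breaking is fixed: diagonal, then gap-in-y, then gap-in-x; within a
// gap state, run extension beats re-opening.  Outputs are bit-reproducible.

static const double NEG = -1e18;

struct BandIdx {
  int n, m, lo, hi;
  std::vector<int> c0, c1;     // per-row column range
  std::vector<size_t> rowptr;  // flat offsets
  size_t cells;
  BandIdx(int n_, int m_, int lo_, int hi_) : n(n_), m(m_), lo(lo_), hi(hi_) {
    c0.resize(n + 1); c1.resize(n + 1); rowptr.resize(n + 2);
    rowptr[0] = 0;
    for (int i = 0; i <= n; ++i) {
      c0[i] = std::max(0, i + lo);
      c1[i] = std::min(m, i + hi);
      if (c1[i] < c0[i]) { c0[i] = 0; c1[i] = -1; }  // empty row (shouldn't happen)
      rowptr[i + 1] = rowptr[i] + (size_t)(c1[i] - c0[i] + 1);
    }
    cells = rowptr[n + 1];
  }
  inline bool in(int i, int j) const {
    return i >= 0 && i <= n && j >= c0[i] && j <= c1[i];
  }
  inline size_t at(int i, int j) const { return rowptr[i] + (size_t)(j - c0[i]); }
};

// [[Rcpp::export]]
List cpp_twopiece_align(std::string x, std::string y,
                        double match, double mismatch,
                        double O1, double E1, double O2, double E2,
                        int band_width, double max_cells) {
  const int n = (int)x.size(), m = (int)y.size();
  if (n == 0 && m == 0)
    return List::create(_["score"] = 0.0, _["ax"] = "", _["ay"] = "");

  int lo, hi;
  if (band_width < 0) { lo = -n; hi = m; }
  else {
    lo = std::min(0, m - n) - band_width;
    hi = std::max(0, m - n) + band_width;
  }
  BandIdx B(n, m, lo, hi);
  if ((double)B.cells > max_cells)
    stop("alignment DP would need %.0f cells (limit %.0f); shorten the interval or use a band",
         (double)B.cells, max_cells);

  std::vector<std::vector<double>> S(5, std::vector<double>(B.cells, NEG));
  std::vector<std::vector<uint8_t>> BP(5, std::vector<uint8_t>(B.cells, 255));
  const double Ogap[2] = {O1, O2}, Egap[2] = {E1, E2};

  for (int i = 0; i <= n; ++i) {
    for (int j = B.c0[i]; j <= B.c1[i]; ++j) {
      size_t c = B.at(i, j);
      if (i == 0 && j == 0) { S[0][c] = 0.0; continue; }
      // M: diagonal
      if (i > 0 && j > 0 && B.in(i - 1, j - 1)) {
        size_t p = B.at(i - 1, j - 1);
        double sub = (x[i - 1] == y[j - 1]) ? match : -mismatch;
        int bs = 0; double bv = S[0][p];
        for (int s = 1; s < 5; ++s) if (S[s][p] > bv) { bv = S[s][p]; bs = s; }
        if (bv > NEG / 2) { S[0][c] = bv + sub; BP[0][c] = (uint8_t)bs; }
      }
      // D regimes: consume x (gap character in y row)
      if (i > 0 && B.in(i - 1, j)) {
        size_t p = B.at(i - 1, j);
        for (int k = 0; k < 2; ++k) {
          int st = 1 + k;
          // candidate order: extend, then open from M, other-D, I1, I2
          int cand[5] = {st, 0, (st == 1 ? 2 : 1), 3, 4};
          double best = NEG; int bs = 255;
          for (int t = 0; t < 5; ++t) {
            int s = cand[t];
            double v = S[s][p] - Egap[k] - (s == st ? 0.0 : Ogap[k]);
            if (S[s][p] > NEG / 2 && v > best) { best = v; bs = s; }
          }
          if (bs != 255) { S[st][c] = best; BP[st][c] = (uint8_t)bs; }
        }
      }
      // I regimes: consume y (gap character in x row)
      if (j > 0 && B.in(i, j - 1)) {
        size_t p = B.at(i, j - 1);
        for (int k = 0; k < 2; ++k) {
          int st = 3 + k;
          int cand[5] = {st, 0, 1, 2, (st == 3 ? 4 : 3)};
          double best = NEG; int bs = 255;
          for (int t = 0; t < 5; ++t) {
            int s = cand[t];
            double v = S[s][p] - Egap[k] - (s == st ? 0.0 : Ogap[k]);
            if (S[s][p] > NEG / 2 && v > best) { best = v; bs = s; }
          }
          if (bs != 255) { S[st][c] = best; BP[st][c] = (uint8_t)bs; }
        }
      }
    }
  }

  if (!B.in(n, m)) stop("band does not contain the terminal cell");
  size_t cend = B.at(n, m);
  int st = 0; double sc = S[0][cend];
  for (int s = 1; s < 5; ++s) if (S[s][cend] > sc) { sc = S[s][cend]; st = s; }
  if (sc < NEG / 2) stop("no alignment found within the band");

  std::string ax, ay; ax.reserve(n + m); ay.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = B.at(i, j);
    uint8_t prev = BP[st][c];
    if (st == 0)      { ax.push_back(x[i - 1]); ay.push_back(y[j - 1]); --i; --j; }
    else if (st <= 2) { ax.push_back(x[i - 1]); ay.push_back('-');      --i; }
    else              { ax.push_back('-');      ay.push_back(y[j - 1]); --j; }
    if (prev == 255) break;  // reached origin
    st = prev;
  }
  std::reverse(ax.begin(), ax.end());
  std::reverse(ay.begin(), ay.end());
  return List::create(_["score"] = sc, _["ax"] = ax, _["ay"] = ay);
}

static inline int base2bits(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

// Exact k-mer seed hits of each query in one target sequence.
// Returns, per query, a two-column integer matrix of 0-based (qpos, tpos).
// Target k-mers occurring more than max_occ times are skipped as repetitive.
// [[Rcpp::export]]
List cpp_seed_hits(CharacterVector queries, std::string target, int k, int max_occ) {
  if (k < 4 || k > 31) stop("seed length k must be in [4, 31]");
  const int tn = (int)target.size();
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve(tn > 0 ? (size_t)tn : 1);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < tn; ++i) {
    int b = base2bits(target[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) index[h].push_back(i - k + 1);
  }
  List out(queries.size());
  for (int q = 0; q < queries.size(); ++q) {
    std::string qs = as<std::string>(queries[q]);
    std::vector<int> qp, tp;
    uint64_t qh = 0; int qrun = 0;
    for (int i = 0; i < (int)qs.size(); ++i) {
      int b = base2bits(qs[i]);
      if (b < 0) { qrun = 0; qh = 0; continue; }
      qh = ((qh << 2) | (uint64_t)b) & mask;
      if (++qrun >= k) {
        auto it = index.find(qh);
        if (it != index.end() && (int)it->second.size() <= max_occ)
          for (int t : it->second) { qp.push_back(i - k + 1); tp.push_back(t); }
      }
    }
    IntegerMatrix mat(qp.size(), 2);
    for (size_t r = 0; r < qp.size(); ++r) { mat(r, 0) = qp[r]; mat(r, 1) = tp[r]; }
    out[q] = mat;
  }
  return out;
}

// Canonical k-mer set (min of forward and reverse-complement 2-bit codes),
// returned as sorted unique doubles (exact for 2k <= 52 bits).
// [[Rcpp::export]]
NumericVector cpp_kmer_set(std::string seq, int k) {
  if (k < 4 || k > 26) stop("k must be in [4, 26] for exact double encoding");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<uint64_t> kmers;
  uint64_t f = 0, r = 0; int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (uint64_t)b) & mask;
    r = (r >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) kmers.push_back(std::min(f, r));
  }
  std::sort(kmers.begin(), kmers.end());
  kmers.erase(std::unique(kmers.begin(), kmers.end()), kmers.end());
  NumericVector out(kmers.size());
  for (size_t i = 0; i < kmers.size(); ++i) out[i] = (double)kmers[i];
  return out;
}
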