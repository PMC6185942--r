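// Exhaustive pairwise scan engines.
//
// Both engines walk all unordered SNP pairs (i < j, i fastest-varying
// second index) and, for each pair, build the 2x2 case/control contingency
// table under each of the 8 genotype interaction patterns and compute the
// uncorrected 1-d.f. Pearson chi-square statistic.  They differ only in
// how the tables are counted:
//   * lookup: word-wise sums over pre-computed 256x256 per-pattern tables
//     of black / mutually-non-missing counts (4 genotypes per byte word);
//   * naive: per-sample accumulation of the 4x4 joint genotype table,
//     then mask sums.
// Output contract is identical and bit-exact between the two.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline double pearson_chi2(double a, double b, double c, double d) {
  // a = n_db, b = n_dw, c = n_hb, d = n_hw
  double n = a + b + c + d;
  double denom = (a + b) * (c + d) * (a + c) * (b + d);
  if (n == 0.0 || denom == 0.0) return 0.0;  // degenerate margin
  double det = a * d - b * c;
  return n * det * det / denom;
}

struct HitStore {
  std::vector<int> i, j, pat;
  std::vector<double> a, b, c, d, chi2;
  void push(int i_, int j_, int t_, double a_, double b_, double c_,
            double d_, double x2) {
    i.push_back(i_); j.push_back(j_); pat.push_back(t_);
    a.push_back(a_); b.push_back(b_); c.push_back(c_); d.push_back(d_);
    chi2.push_back(x2);
  }
};

static List pack_result(long long n_pairs, NumericVector best_chi2,
                        IntegerVector best_pat, const HitStore &hs) {
  return List::create(
      _["n_pairs"] = (double)n_pairs,
      _["best_chi2"] = best_chi2,
      _["best_pattern"] = best_pat,
      _["hit_i"] = wrap(hs.i), _["hit_j"] = wrap(hs.j),
      _["hit_pattern"] = wrap(hs.pat),
      _["n_db"] = wrap(hs.a), _["n_dw"] = wrap(hs.b),
      _["n_hb"] = wrap(hs.c), _["n_hw"] = wrap(hs.d),
      _["hit_chi2"] = wrap(hs.chi2));
}

// wcase/wctrl: packed word matrices (n_words x m), values 0..255
// black: 8 x 65536 integer, column index x*256 + y; nonmiss: 65536
// chi2_keep: retain pair/pattern results with chi2 >= chi2_keep
// [[Rcpp::export]]
List scan_lookup_cpp(IntegerMatrix wcase, IntegerMatrix wctrl,
                     IntegerMatrix black, IntegerVector nonmiss,
                     double chi2_keep) {
  const int m = wcase.ncol();
  const int nwc = wcase.nrow(), nwh = wctrl.nrow();
  const long long n_pairs = (long long)m * (m - 1) / 2;
  NumericVector best_chi2(n_pairs);
  IntegerVector best_pat(n_pairs);
  HitStore hs;

  // fuse the eight per-pattern black counts of a word pair (values 0..4)
  // into one byte each of a 64-bit entry, and keep the mutually
  // non-missing count in a parallel byte table: the inner loop then does a
  // single 64-bit add per word pair, and byte lanes are unpacked once per
  // chunk of 63 words (63 * 4 = 252 < 256, so lanes cannot overflow)
  std::vector<uint64_t> tbl8(65536);
  std::vector<uint8_t> nm8(65536);
  for (int idx = 0; idx < 65536; ++idx) {
    uint64_t v = 0;
    for (int t = 0; t < 8; ++t)
      v |= (uint64_t)black(t, idx) << (8 * t);
    tbl8[idx] = v;
    nm8[idx] = (uint8_t)nonmiss[idx];
  }
  const int CHUNK = 63;

  long long q = 0;
  for (int i = 0; i < m - 1; ++i) {
    const int *ci = &wcase(0, i);
    const int *hi = &wctrl(0, i);
    for (int j = i + 1; j < m; ++j, ++q) {
      const int *cj = &wcase(0, j);
      const int *hj = &wctrl(0, j);
      int blk_case[8] = {0}, blk_ctrl[8] = {0};
      int nm_case = 0, nm_ctrl = 0;
      for (int w0 = 0; w0 < nwc; w0 += CHUNK) {
        const int wend = w0 + CHUNK < nwc ? w0 + CHUNK : nwc;
        uint64_t acc = 0;
        for (int w = w0; w < wend; ++w) {
          const int idx = (ci[w] << 8) | cj[w];
          acc += tbl8[idx];
          nm_case += nm8[idx];
        }
        for (int t = 0; t < 8; ++t) blk_case[t] += (acc >> (8 * t)) & 0xFF;
      }
      for (int w0 = 0; w0 < nwh; w0 += CHUNK) {
        const int wend = w0 + CHUNK < nwh ? w0 + CHUNK : nwh;
        uint64_t acc = 0;
        for (int w = w0; w < wend; ++w) {
          const int idx = (hi[w] << 8) | hj[w];
          acc += tbl8[idx];
          nm_ctrl += nm8[idx];
        }
        for (int t = 0; t < 8; ++t) blk_ctrl[t] += (acc >> (8 * t)) & 0xFF;
      }
      double bc = -1.0; int bt = 0;
      for (int t = 0; t < 8; ++t) {
        const double a = blk_case[t], b = nm_case - a;
        const double c = blk_ctrl[t], d = nm_ctrl - c;
        const double x2 = pearson_chi2(a, b, c, d);
        if (x2 > bc) { bc = x2; bt = t + 1; }
        if (x2 >= chi2_keep)
          hs.push(i + 1, j + 1, t + 1, a, b, c, d, x2);
      }
      best_chi2[q] = bc;
      best_pat[q] = bt;
    }
  }
  return pack_result(n_pairs, best_chi2, best_pat, hs);
}

// gcase/gctrl: raw genotype code matrices (n x m), values 0..3
// mask16: 8 x 16 integer, index c1*4 + c2 (0-based), 1 = black
// [[Rcpp::export]]
List scan_naive_cpp(IntegerMatrix gcase, IntegerMatrix gctrl,
                    IntegerMatrix mask16, double chi2_keep) {
  const int m = gcase.ncol();
  const int nca = gcase.nrow(), nco = gctrl.nrow();
  const long long n_pairs = (long long)m * (m - 1) / 2;
  NumericVector best_chi2(n_pairs);
  IntegerVector best_pat(n_pairs);
  HitStore hs;

  long long q = 0;
  for (int i = 0; i < m - 1; ++i) {
    const int *ci = &gcase(0, i);
    const int *hi = &gctrl(0, i);
    for (int j = i + 1; j < m; ++j, ++q) {
      const int *cj = &gcase(0, j);
      const int *hj = &gctrl(0, j);
      int joint_case[16] = {0}, joint_ctrl[16] = {0};
      for (int s = 0; s < nca; ++s) ++joint_case[(ci[s] << 2) | cj[s]];
      for (int s = 0; s < nco; ++s) ++joint_ctrl[(hi[s] << 2) | hj[s]];
      double nm_case = 0, nm_ctrl = 0;
      for (int c1 = 1; c1 <= 3; ++c1)
        for (int c2 = 1; c2 <= 3; ++c2) {
          nm_case += joint_case[(c1 << 2) | c2];
          nm_ctrl += joint_ctrl[(c1 << 2) | c2];
        }
      double bc = -1.0; int bt = 0;
      for (int t = 0; t < 8; ++t) {
        double a = 0, c = 0;
        for (int k = 0; k < 16; ++k) {
          if (mask16(t, k)) { a += joint_case[k]; c += joint_ctrl[k]; }
        }
        const double b = nm_case - a, d = nm_ctrl - c;
        const double x2 = pearson_chi2(a, b, c, d);
        if (x2 > bc) { bc = x2; bt = t + 1; }
        if (x2 >= chi2_keep)
          hs.push(i + 1, j + 1, t + 1, a, b, c, d, x2);
      }
      best_chi2[q] = bc;
      best_pat[q] = bt;
    }
  }
  return pack_result(n_pairs, best_chi2, best_pat, hs);
}
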