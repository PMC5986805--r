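#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Needleman-Wunsch (Gotoh) percent identity with free end gaps.
//
// Scoring: match +1, mismatch -1, an internal gap of length L costs
// gap_open + gap_ext * L (so the first gap base costs gap_open + gap_ext);
// terminal gaps are free. Identity excludes terminal-gap columns, but the
// denominator is floored at the shorter sequence's length: identity =
// 100 * matches / max(non-terminal-gap columns, min(m, n)). Without the
// floor, the score-optimal "alignment" of two unrelated sequences is a few
// perfectly matching terminal bases reporting near-100 identity; the floor
// turns that into the near-0 coverage-weighted identity it really is, while
// leaving honest prefix/substring alignments at 100. Traceback (full char
// matrices, rolling score rows) recovers the column composition.

static const double NEG_INF = -1e18;

// traceback codes: which state fed the cell (0 = M, 1 = Ix, 2 = Iy; -1 unset)
struct NwBuffers {
  std::vector<double> pM, pIx, pIy, cM, cIx, cIy;
  std::vector<signed char> tbM, tbIx, tbIy;
};

static double identity_one(const std::string& p, const std::string& s,
                           double match, double mismatch,
                           double gap_open, double gap_ext, NwBuffers& B) {
  const int m = (int)p.size();
  const int n = (int)s.size();
  if (m == 0 || n == 0) return 0.0;
  const double ext_t = 0.0;    // terminal gap extension: free
  const double open1 = gap_open + gap_ext;
  const double open1_t = 0.0;  // terminal gap open: free
  const size_t W = (size_t)n + 1;
  const size_t sz = (size_t)(m + 1) * W;

  B.pM.assign(W, NEG_INF); B.pIx.assign(W, NEG_INF); B.pIy.assign(W, NEG_INF);
  B.cM.resize(W); B.cIx.resize(W); B.cIy.resize(W);
  if (B.tbM.size() < sz) {
    B.tbM.resize(sz); B.tbIx.resize(sz); B.tbIy.resize(sz);
  }
  signed char* tbM = B.tbM.data();
  signed char* tbIx = B.tbIx.data();
  signed char* tbIy = B.tbIy.data();

  // row 0: only Iy (leading gaps in the pattern) is reachable beyond (0,0)
  B.pM[0] = 0.0;
  for (int j = 1; j <= n; ++j) {
    B.pIy[j] = -(gap_open + ext_t * j);
    tbIy[(size_t)j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    const char pc = p[i - 1];
    double* cM = B.cM.data(); double* cIx = B.cIx.data(); double* cIy = B.cIy.data();
    double* pM = B.pM.data(); double* pIx = B.pIx.data(); double* pIy = B.pIy.data();
    const size_t row = (size_t)i * W;
    cM[0] = NEG_INF;
    cIy[0] = NEG_INF;
    cIx[0] = -(gap_open + ext_t * i);
    tbIx[row] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= n; ++j) {
      // M: p[i] with s[j] (diagonal from previous row, j-1)
      double best = pM[j - 1]; signed char arg = 0;
      if (pIx[j - 1] >= best) { best = pIx[j - 1]; arg = 1; }
      if (pIy[j - 1] >= best) { best = pIy[j - 1]; arg = 2; }
      if (best > NEG_INF / 2) {
        cM[j] = best + ((pc == s[j - 1]) ? match : mismatch);
        tbM[row + j] = arg;
      } else {
        cM[j] = NEG_INF;
      }
      // Ix: p[i] with a gap (vertical: from previous row, same j);
      // a pattern gap in the last subject column is a trailing end gap
      const double oI = (j == n) ? open1_t : open1;
      const double eI = (j == n) ? ext_t : gap_ext;
      best = pM[j] - oI; arg = 0;
      if (pIx[j] - eI >= best) { best = pIx[j] - eI; arg = 1; }
      if (pIy[j] - oI >= best) { best = pIy[j] - oI; arg = 2; }
      cIx[j] = (best > NEG_INF / 2) ? best : NEG_INF;
      tbIx[row + j] = arg;
      // Iy: gap in pattern (horizontal: same row, j-1);
      // a subject gap in the last pattern row is a trailing end gap
      const double oJ = (i == m) ? open1_t : open1;
      const double eJ = (i == m) ? ext_t : gap_ext;
      best = cM[j - 1] - oJ; arg = 0;
      if (cIx[j - 1] - oJ >= best) { best = cIx[j - 1] - oJ; arg = 1; }
      if (cIy[j - 1] - eJ >= best) { best = cIy[j - 1] - eJ; arg = 2; }
      cIy[j] = (best > NEG_INF / 2) ? best : NEG_INF;
      tbIy[row + j] = arg;
    }
    std::swap(B.pM, B.cM); std::swap(B.pIx, B.cIx); std::swap(B.pIy, B.cIy);
  }

  // end state at (m, n): after the final swap the "previous" row is row m
  // ties prefer the gap states so equal-score end gaps stay terminal
  int state = 0; double best = B.pM[n];
  if (B.pIx[n] >= best) { best = B.pIx[n]; state = 1; }
  if (B.pIy[n] >= best) { best = B.pIy[n]; state = 2; }

  // traceback, columns recorded end-to-start: 0 match, 1 mismatch, 2 gap
  int i = m, j = n;
  int total = 0, matches = 0, lead_gap = 0, trail_gap = 0;
  std::vector<signed char> cols;
  cols.reserve((size_t)(m + n));
  while (i > 0 || j > 0) {
    if (state == 0) {
      cols.push_back((p[i - 1] == s[j - 1]) ? 0 : 1);
      state = tbM[(size_t)i * W + j];
      --i; --j;
    } else if (state == 1) {
      cols.push_back(2);
      state = tbIx[(size_t)i * W + j];
      --i;
    } else {
      cols.push_back(2);
      state = tbIy[(size_t)i * W + j];
      --j;
    }
  }
  total = (int)cols.size();
  // cols[0] is the LAST alignment column, cols[total-1] the first
  while (trail_gap < total && cols[(size_t)trail_gap] == 2) ++trail_gap;
  while (lead_gap < total - trail_gap &&
         cols[(size_t)(total - 1 - lead_gap)] == 2) ++lead_gap;
  const int counted = total - lead_gap - trail_gap;
  const int floor_len = (m < n) ? m : n;
  const int denom = (counted > floor_len) ? counted : floor_len;
  if (denom <= 0) return 0.0;
  for (int k = 0; k < total; ++k) if (cols[(size_t)k] == 0) ++matches;
  return 100.0 * matches / denom;
}

// [[Rcpp::export(name = ".nw_identity_cpp")]]
NumericVector nw_identity_cpp(CharacterVector patterns, std::string subject,
                              double match = 1.0, double mismatch = -1.0,
                              double gap_open = 1.0, double gap_ext = 1.0) {
  const int np = patterns.size();
  NumericVector out(np);
  NwBuffers B;
  for (int q = 0; q < np; ++q) {
    std::string p = as<std::string>(patterns[q]);
    out[q] = identity_one(p, subject, match, mismatch, gap_open, gap_ext, B);
  }
  return out;
}
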