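#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const double NEG = -1e18;

// Gotoh three-state affine-gap alignment.
// States: M (a[i] vs b[j]), X (gap in b, consumes a), Y (gap in a, consumes b).
// Tie-breaking is deterministic: M preferred over X preferred over Y, both for
// the final state and for every traceback predecessor.
// free_end_b: leading/trailing unaligned stretches of b are free (fragment
// placement mode); the returned alignment is clipped to the matched b region.
// band >= 0 restricts j - i to [min(0, m-n) - band, max(0, m-n) + band]; the
// caller must ensure the optimal path fits (e.g. seeded windows, or
// high-identity pairs of near-equal length).
// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      bool free_end_b, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const size_t W = (size_t)(m + 1);

  std::vector<double> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<double> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  std::vector<unsigned char> pM((size_t)(n + 1) * W, 0),
                             pX((size_t)(n + 1) * W, 0),
                             pY((size_t)(n + 1) * W, 0);

  const bool banded = (band >= 0);
  int loOff = 0, hiOff = 0;
  if (banded) {
    loOff = std::min(0, m - n) - band;
    hiOff = std::max(0, m - n) + band;
  }

  Mp[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (banded && j > hiOff) break;
    Yp[j] = free_end_b ? 0.0 : (gap_open + j * gap_extend);
    pY[j] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    int jlo = 1, jhi = m;
    if (banded) {
      jlo = std::max(1, i + loOff);
      jhi = std::min(m, i + hiOff);
      if (jlo > jhi) stop("band too narrow for these sequence lengths");
    }
    if (!banded || i + loOff <= 0) {
      const double fromM = Mp[0] + gap_open + gap_extend;
      const double fromX = Xp[0] + gap_extend;
      if (fromM >= fromX) { Xc[0] = fromM; pX[(size_t)i * W] = 0; }
      else               { Xc[0] = fromX; pX[(size_t)i * W] = 1; }
    }
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const size_t k = (size_t)i * W + j;
      // M
      double best = Mp[j - 1]; unsigned char pb = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; pb = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; pb = 2; }
      if (best > NEG / 2) {
        const char bj = b[j - 1];
        const double s = (ai == 'N' || bj == 'N') ? mismatch
                         : (ai == bj ? match : mismatch);
        Mc[j] = best + s; pM[k] = pb;
      }
      // X (gap in b)
      best = Mp[j] + gap_open + gap_extend; pb = 0;
      if (Xp[j] + gap_extend > best) { best = Xp[j] + gap_extend; pb = 1; }
      if (Yp[j] + gap_open + gap_extend > best) {
        best = Yp[j] + gap_open + gap_extend; pb = 2;
      }
      if (best > NEG / 2) { Xc[j] = best; pX[k] = pb; }
      // Y (gap in a)
      best = Mc[j - 1] + gap_open + gap_extend; pb = 0;
      if (Xc[j - 1] + gap_open + gap_extend > best) {
        best = Xc[j - 1] + gap_open + gap_extend; pb = 1;
      }
      if (Yc[j - 1] + gap_extend > best) { best = Yc[j - 1] + gap_extend; pb = 2; }
      if (best > NEG / 2) { Yc[j] = best; pY[k] = pb; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  int endJ = m, state = 0;
  double score;
  if (free_end_b) {
    double bestS = NEG;
    for (int j = 0; j <= m; ++j) {
      if (Mp[j] > bestS) { bestS = Mp[j]; endJ = j; state = 0; }
      if (Xp[j] > bestS) { bestS = Xp[j]; endJ = j; state = 1; }
    }
    score = bestS;
  } else {
    double bestS = Mp[m]; state = 0;
    if (Xp[m] > bestS) { bestS = Xp[m]; state = 1; }
    if (Yp[m] > bestS) { bestS = Yp[m]; state = 2; }
    score = bestS;
  }
  if (score < NEG / 2) stop("alignment infeasible under the given band");

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = endJ;
  while (i > 0 || (j > 0 && !free_end_b)) {
    const size_t k = (size_t)i * W + j;
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = pM[k]; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = pX[k]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = pY[k]; --j;
    }
  }
  const int bStart = free_end_b ? j : 0;  // leading b chars clipped
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  // column counts over the (clipped) alignment
  int matches = 0, mismatches = 0, gapCols = 0, gapOpenings = 0;
  bool inGapA = false, inGapB = false;
  for (size_t c = 0; c < ra.size(); ++c) {
    const char x = ra[c], y = rb[c];
    if (x == '-' || y == '-') {
      ++gapCols;
      if (x == '-') { if (!inGapA) { ++gapOpenings; inGapA = true; } }
      else inGapA = false;
      if (y == '-') { if (!inGapB) { ++gapOpenings; inGapB = true; } }
      else inGapB = false;
    } else {
      inGapA = inGapB = false;
      if (x == y && x != 'N') ++matches; else ++mismatches;
    }
  }

  return List::create(
    _["aligned_a"] = ra, _["aligned_b"] = rb, _["score"] = score,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["gap_openings"] = gapOpenings, _["gap_columns"] = gapCols,
    _["b_start"] = bStart, _["b_end"] = endJ);
}
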