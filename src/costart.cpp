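#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Co-start ("anchored at base 0 of both reads") alignment primitives for
// artificial-duplicate detection. The shorter read is aligned globally
// against a prefix of the longer one: score = max over j of D[m][j],
// where D is the usual global DP matrix under unit match reward and
// affine-free per-base penalties. Duplicates differ by few indels, so
// the production path restricts the DP to a diagonal band.

static const int NEG = INT_MIN / 4;

// Banded co-start alignment with traceback.
// Returns score, matches, mismatches, gapped bases and aligned columns
// of the best alignment of all of the shorter read against a prefix of
// the longer. Cells outside |i - j| <= band are unreachable; an optimal
// path that would leave the band is truncated at the last in-band cell.
// [[Rcpp::export]]
List costart_align_banded(std::string a, std::string b,
                          int match, int mismatch, int gap, int band) {
  const std::string &s = (a.size() <= b.size()) ? a : b;
  const std::string &l = (a.size() <= b.size()) ? b : a;
  int m = s.size(), n = l.size();
  int w = 2 * band + 1;
  // D[i][k] with k = j - i + band, j in [i-band, i+band]
  std::vector<int> D((m + 1) * w, NEG);
  std::vector<signed char> T((m + 1) * w, 0); // 1=diag 2=up(gap in l) 3=left
  for (int k = band; k <= 2 * band && k - band <= n; ++k) {
    D[k] = (k - band) * gap;               // row 0: j gaps
    T[k] = 3;
  }
  T[band] = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(n, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i + band;
      int best = NEG; signed char dir = 0;
      if (j > 0) {
        int diag = D[(i - 1) * w + k];     // (i-1, j-1) is same k
        if (diag > NEG) {
          int sc = diag + (s[i - 1] == l[j - 1] && s[i - 1] != 'N'
                             ? match : mismatch);
          if (sc > best) { best = sc; dir = 1; }
        }
      }
      if (k + 1 < w) {                     // up: (i-1, j) -> k+1
        int up = D[(i - 1) * w + k + 1];
        if (up > NEG && up + gap > best) { best = up + gap; dir = 2; }
      }
      if (k - 1 >= 0 && j > 0) {           // left: (i, j-1) -> k-1
        int left = D[i * w + k - 1];
        if (left > NEG && left + gap > best) { best = left + gap; dir = 3; }
      }
      if (i == 0 || best > NEG) {
        D[i * w + k] = best;
        T[i * w + k] = dir;
      }
    }
  }
  // best end cell: row m, any in-band column
  int best = NEG, bestk = -1;
  for (int j = std::max(0, m - band); j <= std::min(n, m + band); ++j) {
    int k = j - m + band;
    if (D[m * w + k] > best) { best = D[m * w + k]; bestk = k; }
  }
  int matches = 0, mismatches = 0, gaps = 0, cols = 0;
  if (bestk >= 0) {
    int i = m, k = bestk;
    while (i > 0 || k != band) {
      signed char dir = T[i * w + k];
      if (dir == 0) break;
      ++cols;
      if (dir == 1) {
        int j = k - band + i;
        if (s[i - 1] == l[j - 1] && s[i - 1] != 'N') ++matches;
        else ++mismatches;
        --i;                               // k unchanged
      } else if (dir == 2) { ++gaps; --i; ++k; }
      else { ++gaps; --k; }
    }
  }
  return List::create(_["score"] = (best <= NEG ? NA_INTEGER : best),
                      _["matches"] = matches,
                      _["mismatches"] = mismatches,
                      _["gaps"] = gaps,
                      _["aligned_len"] = cols);
}

// Unbanded co-start alignment score (full DP, two rolling rows).
// Independent of the banded path; used as the all-pairs oracle.
// [[Rcpp::export]]
int costart_score_full(std::string a, std::string b,
                       int match, int mismatch, int gap) {
  const std::string &s = (a.size() <= b.size()) ? a : b;
  const std::string &l = (a.size() <= b.size()) ? b : a;
  int m = s.size(), n = l.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j * gap;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * gap;
    for (int j = 1; j <= n; ++j) {
      int sc = prev[j - 1] + (s[i - 1] == l[j - 1] && s[i - 1] != 'N'
                                ? match : mismatch);
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      cur[j] = std::max(sc, std::max(up, left));
    }
    std::swap(prev, cur);
  }
  int best = NEG;
  for (int j = 0; j <= n; ++j) best = std::max(best, prev[j]);
  return best;
}
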