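#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// A gap run of length k costs gap_open + k * gap_extend (both <= 0).
// 'N' is a hard mask: any column touching it scores -1e6, so masked
// regions of a scaffold cannot be revisited during iterative scanning.

static inline double subst(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return -1e6;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  // M: column ends in an aligned pair; Ix: gap in b (consumes a); Iy: gap in a
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> Ix(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> Iy(n + 1, std::vector<double>(m + 1, NEG));

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(0.0, std::max(M[i-1][j-1],
                     std::max(Ix[i-1][j-1], Iy[i-1][j-1])));
      M[i][j] = diag + subst(a[i-1], b[j-1], match, mismatch);
      Ix[i][j] = std::max(M[i-1][j] + gap_open + gap_extend,
                          Ix[i-1][j] + gap_extend);
      Iy[i][j] = std::max(M[i][j-1] + gap_open + gap_extend,
                          Iy[i][j-1] + gap_extend);
      if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_aln"] = "", _["b_aln"] = "");
  }

  // traceback from the best M cell; local alignments start/end on pair columns
  std::string aa, bb;
  int i = bi, j = bj;
  int state = 0; // 0 = M, 1 = Ix, 2 = Iy
  const double eps = 1e-9;
  while (true) {
    if (state == 0) {
      aa.push_back(a[i-1]); bb.push_back(b[j-1]);
      double diag = M[i][j] - subst(a[i-1], b[j-1], match, mismatch);
      --i; --j;
      if (diag <= eps) break; // local start
      if (std::fabs(M[i][j] - diag) < eps) state = 0;
      else if (std::fabs(Ix[i][j] - diag) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      aa.push_back(a[i-1]); bb.push_back('-');
      double cur = Ix[i][j];
      --i;
      if (std::fabs(M[i][j] + gap_open + gap_extend - cur) < eps) state = 0;
      else state = 1;
    } else {
      aa.push_back('-'); bb.push_back(b[j-1]);
      double cur = Iy[i][j];
      --j;
      if (std::fabs(M[i][j] + gap_open + gap_extend - cur) < eps) state = 0;
      else state = 2;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["a_aln"] = aa, _["b_aln"] = bb);
}
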