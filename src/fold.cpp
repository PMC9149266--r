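#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
using namespace Rcpp;

// Energy-weighted Nussinov dynamic program: minimize the sum of base-pair
// energies over all nested (pseudoknot-free) structures with hairpin loops
// of at least min_loop unpaired bases. Pair energies (kcal/mol, <= 0):
// GC, AU, GU; anything else is unpairable. The empty structure has energy 0,
// so the minimum is always <= 0.

static inline double pair_e(char a, char b, double eGC, double eAU, double eGU) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return eGC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return eAU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return eGU;
  return 1.0; // unpairable sentinel (never chosen: positive)
}

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop,
                       double eGC, double eAU, double eGU) {
  const int n = seq.size();
  std::vector<std::vector<double>> E(n + 2, std::vector<double>(n + 2, 0.0));

  // E[i][j] over 1-based inclusive [i, j]; E = 0 for empty/short segments
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double v = E[i][j - 1]; // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double e = pair_e(seq[k - 1], seq[j - 1], eGC, eAU, eGU);
        if (e > 0) continue;
        double cand = e + (k > i ? E[i][k - 1] : 0.0) + E[k + 1][j - 1];
        if (cand < v) v = cand;
      }
      E[i][j] = v;
    }
  }

  // deterministic traceback: if any pairing (k, j) attains the optimum,
  // take the smallest such k (prefer the pair with the smaller 5' index)
  std::string db(n, '.');
  std::vector<int> pi(n + 1, 0), pj; // partner per position (0 = unpaired)
  std::stack<std::pair<int, int>> st;
  if (n > 0) st.push(std::make_pair(1, n));
  const double eps = 1e-9;
  while (!st.empty()) {
    int i = st.top().first, j = st.top().second;
    st.pop();
    if (j - i + 1 < min_loop + 2) continue;
    double v = E[i][j];
    bool paired = false;
    for (int k = i; k <= j - min_loop - 1; ++k) {
      double e = pair_e(seq[k - 1], seq[j - 1], eGC, eAU, eGU);
      if (e > 0) continue;
      double cand = e + (k > i ? E[i][k - 1] : 0.0) + E[k + 1][j - 1];
      if (std::fabs(cand - v) < eps) {
        db[k - 1] = '('; db[j - 1] = ')';
        pi[k] = j; pi[j] = k;
        if (k > i) st.push(std::make_pair(i, k - 1));
        st.push(std::make_pair(k + 1, j - 1));
        paired = true;
        break;
      }
    }
    if (!paired) st.push(std::make_pair(i, j - 1));
  }

  IntegerVector p1, p2;
  for (int k = 1; k <= n; ++k) {
    if (pi[k] > k) { p1.push_back(k); p2.push_back(pi[k]); }
  }
  return List::create(_["structure"] = db,
                      _["mfe"] = (n > 0 ? E[1][n] : 0.0),
                      _["pair_i"] = p1, _["pair_j"] = p2);
}
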