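#include <Rcpp.h>
using namespace Rcpp;

// Global alignment of two character strings maximising the number of
// positionally identical characters, with zero gap and mismatch penalties
// (scoring: match = 1, otherwise 0). Traceback is deterministic and places
// gaps as late as possible in the source string.
// [[Rcpp::export(name = ".align_chars")]]
List align_chars(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  // S has (n+1) x (m+1) cells; use ints
  std::vector<int> S((n + 1) * (m + 1), 0);
  auto at = [&](int i, int j) -> int& { return S[i * (m + 1) + j]; };
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int d = at(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? 1 : 0);
      int u = at(i - 1, j);
      int l = at(i, j - 1);
      at(i, j) = std::max(d, std::max(u, l));
    }
  }
  // Traceback preference (from the string ends backwards): diagonal
  // whenever score-consistent (matches first), then source gap, then
  // target gap. Diagonal preference keeps substituted characters
  // positionally aligned, so pairs whose source is a carbonized rewrite of
  // the target align with gaps confined to the source string, placed as
  // late as the optimum allows.
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    bool diag_ok = i > 0 && j > 0 &&
        at(i, j) == at(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? 1 : 0);
    if (diag_ok) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
    } else if (j > 0 && at(i, j) == at(i, j - 1)) {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    } else if (i > 0) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int score = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] == rb[k] && ra[k] != '-') ++score;
  }
  return List::create(_["aligned_source"] = ra, _["aligned_target"] = rb,
                      _["match_score"] = score);
}
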