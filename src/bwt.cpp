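#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <map>
using namespace Rcpp;

// Sort the n cyclic rotations of an integer-coded string by prefix doubling.
// Returns the 0-based start offsets of the rotations in lexicographic order;
// identical rotations (periodic inputs) are ordered by start offset, so the
// original rotation (offset 0) always takes the smallest sorted index among
// its duplicates.
// [[Rcpp::export]]
IntegerVector cyclic_order_cpp(IntegerVector s) {
  const int n = s.size();
  if (n < 1) stop("empty string");
  std::vector<int> ord(n), rank(n), newrank(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return s[a] < s[b]; });
  rank[ord[0]] = 0;
  for (int i = 1; i < n; ++i)
    rank[ord[i]] = rank[ord[i - 1]] + (s[ord[i]] != s[ord[i - 1]] ? 1 : 0);
  for (int k = 1; k < n && rank[ord[n - 1]] < n - 1; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank[a] != rank[b]) return rank[a] < rank[b];
      return rank[(a + k) % n] < rank[(b + k) % n];
    };
    std::sort(ord.begin(), ord.end(), cmp);
    newrank[ord[0]] = 0;
    for (int i = 1; i < n; ++i)
      newrank[ord[i]] = newrank[ord[i - 1]] + (cmp(ord[i - 1], ord[i]) ? 1 : 0);
    rank = newrank;
  }
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return rank[a] != rank[b] ? rank[a] < rank[b] : a < b;
  });
  return wrap(ord);
}

// Invert the cyclic Burrows-Wheeler transform by LF-mapping with stable
// ordering of equal characters. f holds integer codes of the last column,
// s is the 0-based sorted rank of the original rotation.
// [[Rcpp::export]]
IntegerVector bwt_inverse_cpp(IntegerVector f, int s) {
  const int n = f.size();
  if (n < 1) stop("empty transform");
  if (s < 0 || s >= n) stop("rank out of range");
  std::map<int, int> cnt;
  for (int i = 0; i < n; ++i) cnt[f[i]]++;
  std::map<int, int> smaller;
  int acc = 0;
  for (auto &kv : cnt) { smaller[kv.first] = acc; acc += kv.second; }
  std::vector<int> lf(n);
  std::map<int, int> seen;
  for (int i = 0; i < n; ++i) lf[i] = smaller[f[i]] + seen[f[i]]++;
  IntegerVector out(n);
  int row = s;
  for (int i = n - 1; i >= 0; --i) {
    out[i] = f[row];
    row = lf[row];
  }
  return out;
}
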