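#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Optimal string alignment distance: Levenshtein plus adjacent
// transpositions, without the unrestricted-edit property of full
// Damerau-Levenshtein (each substring is edited at most once).
static int osa_one(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev2(m + 1), prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int d = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        d = std::min(d, prev2[j - 2] + 1);
      cur[j] = d;
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[m];
}

static int lev_one(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector pair_distance_cpp(CharacterVector a, CharacterVector b, int method) {
  R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) {
      out[i] = NA_INTEGER;
      continue;
    }
    std::string sa = as<std::string>(a[i]);
    std::string sb = as<std::string>(b[i]);
    out[i] = (method == 1) ? osa_one(sa, sb) : lev_one(sa, sb);
  }
  return out;
}

// All (query, target) pairs with distance <= max_dist. Returns 1-based
// index pairs and the distance; the length pre-filter is an internal
// shortcut that cannot change the result because ||a|-|b|| lower-bounds
// both metrics.
// [[Rcpp::export]]
List cross_matches_cpp(CharacterVector queries, CharacterVector targets,
                       int max_dist, int method, bool length_filter) {
  std::vector<std::string> q(queries.size()), t(targets.size());
  for (R_xlen_t i = 0; i < queries.size(); ++i) q[i] = as<std::string>(queries[i]);
  for (R_xlen_t j = 0; j < targets.size(); ++j) t[j] = as<std::string>(targets[j]);
  std::vector<int> qi, tj, dd;
  for (size_t i = 0; i < q.size(); ++i) {
    const int la = q[i].size();
    for (size_t j = 0; j < t.size(); ++j) {
      if (length_filter) {
        int diff = la - (int)t[j].size();
        if (diff > max_dist || -diff > max_dist) continue;
      }
      int d = (method == 1) ? osa_one(q[i], t[j]) : lev_one(q[i], t[j]);
      if (d <= max_dist) {
        qi.push_back(i + 1);
        tj.push_back(j + 1);
        dd.push_back(d);
      }
    }
  }
  return List::create(_["query_idx"] = wrap(qi), _["target_idx"] = wrap(tj),
                      _["distance"] = wrap(dd));
}
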