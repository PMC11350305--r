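#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Jaro similarity on [0, 1]. Convention: two empty strings are identical
// (1); an empty string against a non-empty one scores 0.
static double jaro_one(const std::string& a, const std::string& b) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  const int window = std::max(0, std::max(la, lb) / 2 - 1);
  std::vector<char> amatch(la, 0), bmatch(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - window);
    const int hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bmatch[j] && a[i] == b[j]) {
        amatch[i] = 1; bmatch[j] = 1; ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;
  int t = 0, k = 0;
  for (int i = 0; i < la; ++i) {
    if (!amatch[i]) continue;
    while (!bmatch[k]) ++k;
    if (a[i] != b[k]) ++t;
    ++k;
  }
  const double mm = (double)m;
  return (mm / la + mm / lb + (mm - t / 2.0) / mm) / 3.0;
}

// Unit-cost Levenshtein distance, two-row dynamic programme.
static int lev_one(const std::string& a, const std::string& b) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      const int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export]]
NumericVector jaro_sim_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    out[i] = jaro_one(as<std::string>(a[i]), as<std::string>(b[i]));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector lev_dist_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    out[i] = lev_one(as<std::string>(a[i]), as<std::string>(b[i]));
  }
  return out;
}
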