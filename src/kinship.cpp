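// Pairwise kinship on a pedigree DAG by the classical recursive definition,
// memoized on unordered pairs. Indices are 1-based rows; 0 = unknown parent.
// Recursion always ascends through the individual with the larger generation
// index (longest chain of known ancestors), which cannot be an ancestor of
// the other; ties are broken by index. This terminates on any DAG, including
// heavy implex.

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

struct KinCtx {
  const int* fa;
  const int* mo;
  const int* gen;
  std::unordered_map<uint64_t, double> memo;

  double phi(int a, int b) {
    if (a == 0 || b == 0) return 0.0;
    int x = a < b ? a : b, y = a < b ? b : a;
    uint64_t key = (static_cast<uint64_t>(x) << 32) | static_cast<uint32_t>(y);
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;
    double v;
    if (a == b) {
      v = 0.5 * (1.0 + phi(fa[a - 1], mo[a - 1]));
    } else {
      int ga = gen[a - 1], gb = gen[b - 1];
      int up, other;
      if (ga > gb || (ga == gb && a > b)) { up = a; other = b; }
      else                               { up = b; other = a; }
      v = 0.5 * (phi(fa[up - 1], other) + phi(mo[up - 1], other));
    }
    memo.emplace(key, v);
    return v;
  }
};

} // namespace

// [[Rcpp::export(name = ".kin_pairs_cpp")]]
NumericVector kin_pairs_cpp(IntegerVector fa, IntegerVector mo,
                            IntegerVector gen,
                            IntegerVector ia, IntegerVector ib) {
  KinCtx ctx{fa.begin(), mo.begin(), gen.begin(), {}};
  const int n = ia.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ctx.phi(ia[i], ib[i]);
  return out;
}

// [[Rcpp::export(name = ".kin_matrix_cpp")]]
NumericMatrix kin_matrix_cpp(IntegerVector fa, IntegerVector mo,
                             IntegerVector gen, IntegerVector rows) {
  KinCtx ctx{fa.begin(), mo.begin(), gen.begin(), {}};
  const int n = rows.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = ctx.phi(rows[i], rows[j]);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// mean kinship over all unordered pairs of `rows` (diagonal excluded)
// [[Rcpp::export(name = ".kin_mean_cpp")]]
double kin_mean_cpp(IntegerVector fa, IntegerVector mo,
                    IntegerVector gen, IntegerVector rows) {
  KinCtx ctx{fa.begin(), mo.begin(), gen.begin(), {}};
  const int n = rows.size();
  if (n < 2) return NA_REAL;
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      s += ctx.phi(rows[i], rows[j]);
  return s / (0.5 * n * (n - 1.0));
}

// inbreeding F_i = phi(father, mother); 0 when a parent is unknown
// [[Rcpp::export(name = ".inbreeding_cpp")]]
NumericVector inbreeding_cpp(IntegerVector fa, IntegerVector mo,
                             IntegerVector gen, IntegerVector rows) {
  KinCtx ctx{fa.begin(), mo.begin(), gen.begin(), {}};
  const int n = rows.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ctx.phi(fa[rows[i] - 1], mo[rows[i] - 1]);
  return out;
}
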