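#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Constrained agglomerative single-linkage clustering under a tree metric.
//
// Starting from singletons, repeatedly merge the pair of clusters with the
// minimal single-linkage distance among pairs whose linkage <= d_nn AND
// whose merged extent (maximum pairwise distance, i.e. tree-metric
// diameter) <= d_ext.  If the globally minimal-linkage pair violates d_ext
// it is skipped and the next admissible pair is merged.  Aggregation stops
// when no admissible pair remains.
//
// Tie rule (determinism): among pairs sharing the minimal linkage, the pair
// whose smallest member index is lowest wins, then the smaller of the two
// cluster-minimum indices of the other side.  Indices are the 0-based row
// order of the input distance matrix.
//
// Bookkeeping: L = pairwise single-linkage (min cross distance),
// E = pairwise max cross distance, ext = per-cluster diameter.  On merging
// a and b, L[.,a] <- min, E[.,a] <- max, ext[a] <- max(ext_a, ext_b,
// E[a][b]).  A nearest-admissible-neighbour cache keeps the scan near
// O(n^2): merging never makes a previously inadmissible untouched pair
// admissible-and-better (linkage of a merged pair is the min of old
// linkages, extent the max), so only entries pointing at the merged pair
// need recomputation.

struct Cand { int j; double link; int k1; int k2; bool ok; };

static inline bool betterPair(double l1, int a1, int b1,
                              double l2, int a2, int b2) {
  if (l1 != l2) return l1 < l2;
  if (a1 != b1 && a2 != b2) {
    int lo1 = std::min(a1, b1), hi1 = std::max(a1, b1);
    int lo2 = std::min(a2, b2), hi2 = std::max(a2, b2);
    if (lo1 != lo2) return lo1 < lo2;
    return hi1 < hi2;
  }
  return false;
}

// [[Rcpp::export(name = ".slink_constrained_cpp")]]
List slink_constrained_cpp(NumericMatrix D, double dnn, double dext) {
  const int n = D.nrow();
  List out;
  if (n == 0) {
    return List::create(_["assign"] = IntegerVector(0),
                        _["extent"] = NumericVector(0),
                        _["merge_linkage"] = NumericVector(0),
                        _["merge_extent"] = NumericVector(0));
  }
  std::vector<double> L(D.begin(), D.end());   // column-major n x n
  std::vector<double> E(D.begin(), D.end());
  std::vector<double> ext(n, 0.0);
  std::vector<int> minId(n), rep(n);
  std::vector<bool> active(n, true);
  for (int i = 0; i < n; ++i) { minId[i] = i; rep[i] = i; }

  std::vector<int> nnIdx(n, -1);
  std::vector<double> nnLink(n, 0.0);

  auto admissible = [&](int i, int j) -> bool {
    double l = L[i + (size_t)n * j];
    if (l > dnn) return false;
    double e = std::max(std::max(ext[i], ext[j]), E[i + (size_t)n * j]);
    return e <= dext;
  };

  auto recomputeNN = [&](int i) {
    int best = -1; double bl = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i || !active[j]) continue;
      if (!admissible(i, j)) continue;
      double l = L[i + (size_t)n * j];
      if (best < 0 ||
          betterPair(l, minId[i], minId[j], bl, minId[i], minId[best]))
        { best = j; bl = l; }
    }
    nnIdx[i] = best; nnLink[i] = bl;
  };

  for (int i = 0; i < n; ++i) recomputeNN(i);

  std::vector<double> mlink, mext;
  mlink.reserve(n); mext.reserve(n);

  while (true) {
    int bi = -1, bj = -1; double bl = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!active[i] || nnIdx[i] < 0) continue;
      int j = nnIdx[i];
      if (bi < 0 || betterPair(nnLink[i], minId[i], minId[j],
                               bl, minId[bi], minId[bj]))
        { bi = i; bj = j; bl = nnLink[i]; }
    }
    if (bi < 0) break;
    int a = bi, b = bj;
    if (minId[b] < minId[a]) std::swap(a, b);   // keep lower min index
    double newExt = std::max(std::max(ext[a], ext[b]), E[a + (size_t)n * b]);
    mlink.push_back(L[a + (size_t)n * b]);
    mext.push_back(newExt);
    ext[a] = newExt;
    // minId[a] already the smaller
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == a || k == b) continue;
      double lmin = std::min(L[a + (size_t)n * k], L[b + (size_t)n * k]);
      double emax = std::max(E[a + (size_t)n * k], E[b + (size_t)n * k]);
      L[a + (size_t)n * k] = L[k + (size_t)n * a] = lmin;
      E[a + (size_t)n * k] = E[k + (size_t)n * a] = emax;
    }
    active[b] = false;
    for (int v = 0; v < n; ++v) if (rep[v] == b) rep[v] = a;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      if (i == a || nnIdx[i] == a || nnIdx[i] == b) { recomputeNN(i); continue; }
      // the merged cluster may now beat the cached pair (lower linkage by
      // the min rule, or a better tie key since its minimum index dropped)
      if (admissible(i, a)) {
        double l = L[i + (size_t)n * a];
        if (nnIdx[i] < 0 ||
            betterPair(l, minId[i], minId[a],
                       nnLink[i], minId[i], minId[nnIdx[i]]))
          { nnIdx[i] = a; nnLink[i] = l; }
      }
    }
  }

  // deterministic cluster labels: order of cluster minimum index
  std::vector<int> reps;
  for (int i = 0; i < n; ++i) if (active[i]) reps.push_back(i);
  std::sort(reps.begin(), reps.end(),
            [&](int x, int y) { return minId[x] < minId[y]; });
  std::vector<int> lab(n, -1);
  for (size_t k = 0; k < reps.size(); ++k) lab[reps[k]] = (int)k;
  IntegerVector assign(n);
  for (int v = 0; v < n; ++v) assign[v] = lab[rep[v]] + 1;
  NumericVector extents(reps.size());
  for (size_t k = 0; k < reps.size(); ++k) extents[k] = ext[reps[k]];

  return List::create(_["assign"] = assign,
                      _["extent"] = extents,
                      _["merge_linkage"] = NumericVector(mlink.begin(), mlink.end()),
                      _["merge_extent"] = NumericVector(mext.begin(), mext.end()));
}
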