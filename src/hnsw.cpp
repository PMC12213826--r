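// Hierarchical Navigable Small World graph index and exact flat scan.
// Distances: L2 (Euclidean) and Canberra. Row-major copies of the input
// matrix are kept inside the index so queries never touch R memory layout.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

static inline double dist_l2(const double *a, const double *b, int d) {
  double s = 0.0;
  for (int i = 0; i < d; ++i) {
    const double t = a[i] - b[i];
    s += t * t;
  }
  return std::sqrt(s);
}

// Canberra: terms with |a|+|b| = 0 contribute 0 (0/0 convention).
static inline double dist_canberra(const double *a, const double *b, int d) {
  double s = 0.0;
  for (int i = 0; i < d; ++i) {
    const double num = std::fabs(a[i] - b[i]);
    const double den = std::fabs(a[i]) + std::fabs(b[i]);
    if (den > 0.0) s += num / den;
  }
  return s;
}

struct PairCmpFar {
  // max-heap on distance (furthest on top)
  bool operator()(const std::pair<double, int> &a,
                  const std::pair<double, int> &b) const {
    return a.first < b.first;
  }
};
struct PairCmpNear {
  // min-heap on distance (nearest on top)
  bool operator()(const std::pair<double, int> &a,
                  const std::pair<double, int> &b) const {
    return a.first > b.first;
  }
};

class HnswIndex {
public:
  int n, dim, M, Mmax0, efC, metric;
  double mL;
  std::vector<double> data;                         // row-major n x dim
  std::vector<std::vector<std::vector<int>>> links; // [node][layer][nbr]
  std::vector<int> levels;
  int entry;
  int maxLevel;
  std::mt19937 rng;
  mutable std::vector<unsigned> visited_;
  mutable unsigned stamp_;

  HnswIndex(const NumericMatrix &X, int M_, int efC_, int metric_,
            unsigned seed)
      : n(X.nrow()), dim(X.ncol()), M(M_), Mmax0(2 * M_), efC(efC_),
        metric(metric_), mL(1.0 / std::log(std::max(2, M_))), entry(-1),
        maxLevel(-1), rng(seed), visited_(X.nrow(), 0u), stamp_(0u) {
    data.resize(static_cast<size_t>(n) * dim);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < dim; ++j)
        data[static_cast<size_t>(i) * dim + j] = X(i, j);
    links.resize(n);
    levels.resize(n);
    for (int i = 0; i < n; ++i) insert(i);
  }

  inline const double *row(int i) const {
    return data.data() + static_cast<size_t>(i) * dim;
  }
  inline double dist(const double *q, int j) const {
    return metric == 0 ? dist_l2(q, row(j), dim) : dist_canberra(q, row(j), dim);
  }

  // Best-first search at one layer; returns up to ef (dist, id) pairs.
  std::vector<std::pair<double, int>>
  searchLayer(const double *q, const std::vector<std::pair<double, int>> &entries,
              int ef, int layer) const {
    ++stamp_;
    std::priority_queue<std::pair<double, int>, std::vector<std::pair<double, int>>,
                        PairCmpNear> cand;
    std::priority_queue<std::pair<double, int>, std::vector<std::pair<double, int>>,
                        PairCmpFar> result;
    for (const auto &e : entries) {
      if (visited_[e.second] == stamp_) continue;
      visited_[e.second] = stamp_;
      cand.push(e);
      result.push(e);
    }
    while (static_cast<int>(result.size()) > ef) result.pop();
    while (!cand.empty()) {
      const auto c = cand.top();
      if (!result.empty() && c.first > result.top().first &&
          static_cast<int>(result.size()) >= ef)
        break;
      cand.pop();
      if (layer < static_cast<int>(links[c.second].size())) {
        for (int e : links[c.second][layer]) {
          if (visited_[e] == stamp_) continue;
          visited_[e] = stamp_;
          const double d = dist(q, e);
          if (static_cast<int>(result.size()) < ef || d < result.top().first) {
            cand.push({d, e});
            result.push({d, e});
            if (static_cast<int>(result.size()) > ef) result.pop();
          }
        }
      }
    }
    std::vector<std::pair<double, int>> out;
    out.reserve(result.size());
    while (!result.empty()) {
      out.push_back(result.top());
      result.pop();
    }
    std::sort(out.begin(), out.end());
    return out;
  }

  void insert(int i) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    double u = unif(rng);
    if (u <= 0.0) u = 1e-12;
    const int l = static_cast<int>(std::floor(-std::log(u) * mL));
    levels[i] = l;
    links[i].assign(l + 1, {});
    if (entry < 0) {
      entry = i;
      maxLevel = l;
      return;
    }
    const double *q = row(i);
    std::vector<std::pair<double, int>> eps = {{dist(q, entry), entry}};
    for (int layer = maxLevel; layer > l; --layer)
      eps = searchLayer(q, eps, 1, layer);
    for (int layer = std::min(l, maxLevel); layer >= 0; --layer) {
      auto W = searchLayer(q, eps, efC, layer);
      const int Mmax = layer == 0 ? Mmax0 : M;
      const int nsel = std::min<int>(M, W.size());
      for (int s = 0; s < nsel; ++s) {
        const int nb = W[s].second;
        links[i][layer].push_back(nb);
        links[nb][layer].push_back(i);
        if (static_cast<int>(links[nb][layer].size()) > Mmax)
          shrink(nb, layer, Mmax);
      }
      eps = W;
    }
    if (l > maxLevel) {
      maxLevel = l;
      entry = i;
    }
  }

  void shrink(int node, int layer, int Mmax) {
    const double *q = row(node);
    auto &lst = links[node][layer];
    std::vector<std::pair<double, int>> scored;
    scored.reserve(lst.size());
    for (int e : lst) scored.push_back({dist(q, e), e});
    std::sort(scored.begin(), scored.end());
    lst.clear();
    for (int s = 0; s < Mmax; ++s) lst.push_back(scored[s].second);
  }

  // k nearest neighbours of an external query vector.
  std::vector<std::pair<double, int>> query(const double *q, int k, int ef) const {
    std::vector<std::pair<double, int>> eps = {{dist(q, entry), entry}};
    for (int layer = maxLevel; layer >= 1; --layer)
      eps = searchLayer(q, eps, 1, layer);
    auto W = searchLayer(q, eps, std::max(ef, k), 0);
    if (static_cast<int>(W.size()) > k) W.resize(k);
    return W;
  }
};

// [[Rcpp::export(name = ".hnsw_build")]]
SEXP hnsw_build(NumericMatrix X, int M, int ef_construction, int metric,
                int seed) {
  HnswIndex *idx =
      new HnswIndex(X, M, ef_construction, metric, static_cast<unsigned>(seed));
  XPtr<HnswIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".hnsw_query")]]
List hnsw_query(SEXP ptr_, NumericMatrix Q, int k, int ef) {
  XPtr<HnswIndex> ptr(ptr_);
  const int nq = Q.nrow(), dim = Q.ncol();
  if (dim != ptr->dim) stop("query dimensionality does not match index");
  IntegerMatrix ids(nq, k);
  NumericMatrix dists(nq, k);
  std::vector<double> q(dim);
  for (int r = 0; r < nq; ++r) {
    for (int j = 0; j < dim; ++j) q[j] = Q(r, j);
    auto res = ptr->query(q.data(), k, ef);
    for (int s = 0; s < k; ++s) {
      if (s < static_cast<int>(res.size())) {
        ids(r, s) = res[s].second + 1;
        dists(r, s) = res[s].first;
      } else {
        ids(r, s) = NA_INTEGER;
        dists(r, s) = NA_REAL;
      }
    }
  }
  return List::create(_["ids"] = ids, _["distances"] = dists);
}

// A deserialized external pointer has a NULL address; report it so the R
// layer can rebuild the graph from the stored matrix and seed.
// [[Rcpp::export(name = ".hnsw_valid")]]
bool hnsw_valid(SEXP ptr_) {
  if (TYPEOF(ptr_) != EXTPTRSXP) return false;
  return R_ExternalPtrAddr(ptr_) != nullptr;
}

// Exact scan: partial sort of all database distances per query.
// Ties broken by database row index for a stable, reproducible ordering.
// [[Rcpp::export(name = ".flat_query")]]
List flat_query(NumericMatrix X, NumericMatrix Q, int k, int metric) {
  const int n = X.nrow(), dim = X.ncol(), nq = Q.nrow();
  if (Q.ncol() != dim) stop("query dimensionality does not match database");
  if (k > n) stop("k exceeds database size");
  IntegerMatrix ids(nq, k);
  NumericMatrix dists(nq, k);
  std::vector<double> xr(static_cast<size_t>(n) * dim), q(dim);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < dim; ++j)
      xr[static_cast<size_t>(i) * dim + j] = X(i, j);
  std::vector<std::pair<double, int>> scored(n);
  for (int r = 0; r < nq; ++r) {
    for (int j = 0; j < dim; ++j) q[j] = Q(r, j);
    for (int i = 0; i < n; ++i) {
      const double *xi = xr.data() + static_cast<size_t>(i) * dim;
      scored[i] = {metric == 0 ? dist_l2(q.data(), xi, dim)
                               : dist_canberra(q.data(), xi, dim),
                   i};
    }
    std::partial_sort(scored.begin(), scored.begin() + k, scored.end());
    for (int s = 0; s < k; ++s) {
      ids(r, s) = scored[s].second + 1;
      dists(r, s) = scored[s].first;
    }
  }
  return List::create(_["ids"] = ids, _["distances"] = dists);
}
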