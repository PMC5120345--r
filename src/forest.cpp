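#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// A compact random forest for the gill-raker trait classifier: bagged CART
// trees, Gini splits over threshold rules on a numeric (one-hot encoded)
// design matrix, per-node column subsampling (mtry), out-of-bag voting and
// out-of-bag permutation importance aggregated over column groups (one
// group per parent trait, so dummy columns of a categorical trait are
// permuted jointly). Deterministic for a fixed seed.

namespace {

struct Tree {
  std::vector<int> col, left, right, leaf; // leaf = class id or -1
  std::vector<double> thr;
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, mtry, p;
  std::mt19937_64& rng;
  Tree tree;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int K_, int mtry_,
          std::mt19937_64& rng_)
      : X(X_), y(y_), K(K_), mtry(mtry_), p(X_.ncol()), rng(rng_) {}

  int draw(int n) { return (int)(rng() % (uint64_t)n); }

  static double gini(const std::vector<int>& cnt, int n) {
    if (n == 0) return 0.0;
    double s = 0;
    for (int c : cnt) s += (double)c * c;
    return 1.0 - s / ((double)n * n);
  }

  int build(std::vector<int>& idx) {
    const int n = (int)idx.size();
    std::vector<int> cnt(K, 0);
    for (int i : idx) ++cnt[y[i]];
    int maj = 0;
    for (int c = 1; c < K; ++c) if (cnt[c] > cnt[maj]) maj = c;
    const double g0 = gini(cnt, n);
    int node = (int)tree.col.size();
    tree.col.push_back(-1); tree.thr.push_back(0);
    tree.left.push_back(-1); tree.right.push_back(-1); tree.leaf.push_back(maj);
    if (g0 <= 0.0 || n < 2) return node;

    // sample mtry distinct columns (partial Fisher-Yates)
    std::vector<int> cols(p);
    for (int j = 0; j < p; ++j) cols[j] = j;
    const int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) std::swap(cols[j], cols[j + draw(p - j)]);

    double best = g0 - 1e-12, bthr = 0;
    int bcol = -1;
    std::vector<std::pair<double, int>> vals(n);
    std::vector<int> lc(K);
    for (int jj = 0; jj < m; ++jj) {
      const int col = cols[jj];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], col), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[n - 1].first) continue;
      std::fill(lc.begin(), lc.end(), 0);
      for (int i = 0; i < n - 1; ++i) {
        ++lc[vals[i].second];
        if (vals[i].first == vals[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        double sl = 0, sr = 0;
        for (int c = 0; c < K; ++c) {
          sl += (double)lc[c] * lc[c];
          const int rcnt = cnt[c] - lc[c];
          sr += (double)rcnt * rcnt;
        }
        const double gw =
            ((double)nl - sl / nl + (double)nr - sr / nr) / (double)n;
        if (gw < best) {
          best = gw;
          bcol = col;
          bthr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (bcol < 0) return node;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx)
      (X(i, bcol) <= bthr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return node; // numeric-tie guard
    tree.col[node] = bcol;
    tree.thr[node] = bthr;
    tree.leaf[node] = -1;
    const int l = build(li);
    tree.left[node] = l;
    const int r = build(ri);
    tree.right[node] = r;
    return node;
  }
};

// predict row `i`, optionally reading columns of group `g` from row `donor`
int predict(const Tree& t, const NumericMatrix& X, const IntegerVector& grp,
            int i, int g, int donor) {
  int node = 0;
  while (t.leaf[node] < 0) {
    const int col = t.col[node];
    const int src = (g >= 0 && grp[col] == g) ? donor : i;
    node = (X(src, col) <= t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.leaf[node];
}

} // namespace

// [[Rcpp::export(name = ".forest_cpp")]]
List forest_cpp(NumericMatrix X, IntegerVector y, IntegerVector group,
                int n_class, int n_group, int n_trees, int mtry,
                double seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("X / y size mismatch");
  if (n_trees < 1) stop("n_trees must be >= 1");
  std::mt19937_64 rng((uint64_t)seed);

  IntegerMatrix votes(n, n_class);
  IntegerVector oob_times(n);
  NumericVector imp(n_group), imp_trees(n_group);

  std::vector<int> inbag(n), oob;
  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> bag(n);
    for (int i = 0; i < n; ++i) {
      const int r = (int)(rng() % (uint64_t)n);
      bag[i] = r;
      ++inbag[r];
    }
    Builder b(X, y, n_class, mtry, rng);
    b.build(bag);

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob.push_back(i);
    if (oob.empty()) continue;

    int correct = 0;
    std::vector<int> pred(oob.size());
    for (size_t k = 0; k < oob.size(); ++k) {
      pred[k] = predict(b.tree, X, group, oob[k], -1, -1);
      ++votes(oob[k], pred[k]);
      ++oob_times[oob[k]];
      if (pred[k] == y[oob[k]]) ++correct;
    }
    const int no = (int)oob.size();
    std::vector<int> perm(no);
    for (int k = 0; k < no; ++k) perm[k] = k;
    for (int g = 0; g < n_group; ++g) {
      for (int k = 0; k < no; ++k)
        std::swap(perm[k], perm[k + (int)(rng() % (uint64_t)(no - k))]);
      int cg = 0;
      for (int k = 0; k < no; ++k)
        if (predict(b.tree, X, group, oob[k], g, oob[perm[k]]) == y[oob[k]])
          ++cg;
      imp[g] += (double)(correct - cg) / no;
      imp_trees[g] += 1.0;
    }
  }
  for (int g = 0; g < n_group; ++g)
    if (imp_trees[g] > 0) imp[g] /= imp_trees[g];
  return List::create(_["votes"] = votes, _["oob_times"] = oob_times,
                      _["importance"] = imp);
}
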