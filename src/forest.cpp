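// Compact Breiman-style random forest for small trait tables:
// CART with Gini splits, bootstrap aggregation, out-of-bag accuracy and
// OOB permutation importance (mean decrease in accuracy). Uses R's RNG so
// results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int pred = 0;
};

int rand_int(int n) {  // uniform on 0..n-1 via R RNG
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

int majority(const std::vector<int>& counts) {
  int best = 0;
  for (size_t c = 1; c < counts.size(); ++c)
    if (counts[c] > counts[best]) best = static_cast<int>(c);
  return best;
}

double gini(const std::vector<int>& counts, int total) {
  if (total == 0) return 0.0;
  double g = 1.0;
  for (int c : counts) {
    double p = static_cast<double>(c) / total;
    g -= p * p;
  }
  return g;
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, const IntegerVector& y, int k,
              int mtry, int min_node)
    : X_(X), y_(y), k_(k), mtry_(mtry), min_node_(min_node) {}

  std::vector<Node> build(std::vector<int>& idx) {
    nodes_.clear();
    grow(idx, 0, static_cast<int>(idx.size()));
    return nodes_;
  }

  static int predict(const std::vector<Node>& nodes, const NumericMatrix& X,
                     int row, double perm_value, int perm_feature) {
    int cur = 0;
    while (nodes[cur].feature >= 0) {
      double v = (nodes[cur].feature == perm_feature)
        ? perm_value : X(row, nodes[cur].feature);
      cur = (v <= nodes[cur].threshold) ? nodes[cur].left : nodes[cur].right;
    }
    return nodes[cur].pred;
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int k_, mtry_, min_node_;
  std::vector<Node> nodes_;

  // grows the subtree on idx[lo, hi) and returns its node index
  int grow(std::vector<int>& idx, int lo, int hi) {
    int me = static_cast<int>(nodes_.size());
    nodes_.push_back(Node());
    int n = hi - lo;

    std::vector<int> counts(k_, 0);
    for (int i = lo; i < hi; ++i) counts[y_[idx[i]]]++;
    int maj = majority(counts);
    bool pure = counts[maj] == n;
    if (pure || n < min_node_) {
      nodes_[me].pred = maj;
      return me;
    }

    double node_imp = gini(counts, n) * n;
    int p = X_.ncol();
    // sample mtry features without replacement (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry_, p);
    for (int j = 0; j < m; ++j)
      std::swap(feats[j], feats[j + rand_int(p - j)]);

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int> > vals(n);
    for (int fj = 0; fj < m; ++fj) {
      int f = feats[fj];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X_(idx[lo + i], f), y_[idx[lo + i]]);
      std::sort(vals.begin(), vals.end());
      std::vector<int> left(k_, 0), right(counts);
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        left[vals[i].second]++; right[vals[i].second]--; nl++;
        if (vals[i + 1].first <= vals[i].first) continue;  // no split between ties
        double gain = node_imp - gini(left, nl) * nl -
                      gini(right, n - nl) * (n - nl);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) {
      nodes_[me].pred = maj;
      return me;
    }

    // partition idx[lo,hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X_(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) {  // degenerate split (shouldn't happen)
      nodes_[me].pred = maj;
      return me;
    }
    nodes_[me].feature = best_f;
    nodes_[me].threshold = best_thr;
    nodes_[me].left = grow(idx, lo, mid);
    nodes_[me].right = grow(idx, mid, hi);
    return me;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_importance_cpp")]]
List rf_importance_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                       int n_trees, int mtry, int min_node) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  std::vector<int> imp_trees(p, 0);
  // votes for the ensemble OOB prediction
  std::vector<std::vector<int> > votes(n, std::vector<int>(n_classes, 0));

  std::vector<int> inbag(n);
  std::vector<int> oob;
  std::vector<int> boot;
  std::vector<int> pred_oob;

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    boot.resize(n);
    for (int i = 0; i < n; ++i) {
      int r = rand_int(n);
      boot[i] = r;
      inbag[r]++;
    }
    oob.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);

    TreeBuilder tb(X, y, n_classes, mtry, min_node);
    std::vector<Node> tree = tb.build(boot);

    if (oob.empty()) continue;
    int n_oob = static_cast<int>(oob.size());
    pred_oob.resize(n_oob);
    int correct = 0;
    for (int i = 0; i < n_oob; ++i) {
      pred_oob[i] = TreeBuilder::predict(tree, X, oob[i], 0.0, -1);
      votes[oob[i]][pred_oob[i]]++;
      if (pred_oob[i] == y[oob[i]]) correct++;
    }
    double acc0 = static_cast<double>(correct) / n_oob;

    // permutation importance: shuffle one feature among the OOB samples
    std::vector<double> pv(n_oob);
    for (int f = 0; f < p; ++f) {
      for (int i = 0; i < n_oob; ++i) pv[i] = X(oob[i], f);
      for (int i = n_oob - 1; i > 0; --i)
        std::swap(pv[i], pv[rand_int(i + 1)]);
      int corr_p = 0;
      for (int i = 0; i < n_oob; ++i) {
        int pr = TreeBuilder::predict(tree, X, oob[i], pv[i], f);
        if (pr == y[oob[i]]) corr_p++;
      }
      importance[f] += acc0 - static_cast<double>(corr_p) / n_oob;
      imp_trees[f]++;
    }
  }

  NumericVector imp(p);
  for (int f = 0; f < p; ++f)
    imp[f] = imp_trees[f] ? importance[f] / imp_trees[f] : 0.0;

  int n_scored = 0, n_correct = 0;
  IntegerVector ens_pred(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int tot = 0;
    for (int c = 0; c < n_classes; ++c) tot += votes[i][c];
    if (!tot) continue;
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes[i][c] > votes[i][best]) best = c;
    ens_pred[i] = best;
    n_scored++;
    if (best == y[i]) n_correct++;
  }
  double oob_acc = n_scored ? static_cast<double>(n_correct) / n_scored
                            : NA_REAL;
  return List::create(_["importance"] = imp,
                      _["oob_accuracy"] = oob_acc,
                      _["oob_prediction"] = ens_pred);
}
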