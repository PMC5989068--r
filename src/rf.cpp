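// Random Forest binary classifier: bagged CART trees with Gini splits,
// mtry random candidate features per node, class-probability predictions,
// and permutation-based mean-decrease-in-accuracy importance on the
// out-of-bag samples. Uses R's RNG so results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  // node arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> prob;  // class-1 fraction of training samples in node
};

inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Grow one node over idx[lo, hi); returns node id.
int grow(const NumericMatrix& X, const IntegerVector& y, Tree& tree,
         std::vector<int>& idx, int lo, int hi, int mtry, int min_node,
         std::vector<int>& feat_pool,
         std::vector<std::pair<double, int> >& buf) {
  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  int node = static_cast<int>(tree.feature.size());
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.prob.push_back(static_cast<double>(n1) / n);
  if (n1 == 0 || n1 == n || n <= min_node) return node;

  int p = X.ncol();
  // partial Fisher-Yates: first mtry entries of feat_pool are the candidates
  for (int m = 0; m < mtry; ++m) {
    int j = m + runif_int(p - m);
    std::swap(feat_pool[m], feat_pool[j]);
  }
  double best_score = -1.0;
  int best_feat = -1;
  double best_thr = 0.0;
  double parent = static_cast<double>(n1) * n1 / n +
                  static_cast<double>(n - n1) * (n - n1) / n;
  for (int m = 0; m < mtry; ++m) {
    int f = feat_pool[m];
    buf.resize(n);
    for (int i = 0; i < n; ++i) {
      int s = idx[lo + i];
      buf[i] = std::make_pair(X(s, f), y[s]);
    }
    std::sort(buf.begin(), buf.end());
    if (buf.front().first == buf.back().first) continue;
    int l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += buf[i].second;
      if (buf[i].first == buf[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      int r1 = n1 - l1;
      double score = static_cast<double>(l1) * l1 / nl +
                     static_cast<double>(nl - l1) * (nl - l1) / nl +
                     static_cast<double>(r1) * r1 / nr +
                     static_cast<double>(nr - r1) * (nr - r1) / nr;
      if (score > best_score) {
        best_score = score;
        best_feat = f;
        best_thr = (buf[i].first + buf[i + 1].first) / 2.0;
      }
    }
  }
  if (best_feat < 0 || best_score <= parent + 1e-12) return node;

  // partition idx[lo, hi) around the split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // numerically degenerate split

  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  int l = grow(X, y, tree, idx, lo, mid, mtry, min_node, feat_pool, buf);
  int r = grow(X, y, tree, idx, mid, hi, mtry, min_node, feat_pool, buf);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

inline double predict_one(const Tree& tree, const NumericMatrix& X, int row,
                          int swap_feat = -1, int swap_row = -1) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    int f = tree.feature[node];
    double v = (f == swap_feat && swap_row >= 0) ? X(swap_row, f) : X(row, f);
    node = (v <= tree.threshold[node]) ? tree.left[node] : tree.right[node];
  }
  return tree.prob[node];
}

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["prob"] = wrap(t.prob));
}

Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int> >(l["feature"]);
  t.threshold = as<std::vector<double> >(l["threshold"]);
  t.left = as<std::vector<int> >(l["left"]);
  t.right = as<std::vector<int> >(l["right"]);
  t.prob = as<std::vector<double> >(l["prob"]);
  return t;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, bool importance) {
  int n = X.nrow(), p = X.ncol();
  std::vector<Tree> forest;
  forest.reserve(ntree);
  NumericVector oob_prob(n, 0.0);
  IntegerVector oob_n(n, 0);
  NumericVector imp(p, 0.0);
  IntegerVector imp_trees(p, 0);
  std::vector<int> idx(n), inbag(n), feat_pool(p);
  std::vector<std::pair<double, int> > buf;
  std::vector<int> oob_rows;
  std::vector<int> perm;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int s = runif_int(n);
      idx[i] = s;
      inbag[s]++;
    }
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    Tree tree;
    grow(X, y, tree, idx, 0, n, mtry, min_node, feat_pool, buf);

    oob_rows.clear();
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob_rows.push_back(i);
    int n_oob = static_cast<int>(oob_rows.size());
    if (n_oob > 0) {
      int correct = 0;
      for (int k = 0; k < n_oob; ++k) {
        int i = oob_rows[k];
        double pr = predict_one(tree, X, i);
        oob_prob[i] += pr;
        oob_n[i]++;
        if ((pr >= 0.5 ? 1 : 0) == y[i]) correct++;
      }
      if (importance) {
        // features actually used by this tree
        std::vector<bool> used(p, false);
        for (size_t k = 0; k < tree.feature.size(); ++k)
          if (tree.feature[k] >= 0) used[tree.feature[k]] = true;
        perm.assign(oob_rows.begin(), oob_rows.end());
        for (int f = 0; f < p; ++f) {
          if (!used[f]) continue;
          // permute feature f's values among the OOB rows
          for (int k = n_oob - 1; k > 0; --k)
            std::swap(perm[k], perm[runif_int(k + 1)]);
          int correct_perm = 0;
          for (int k = 0; k < n_oob; ++k) {
            int i = oob_rows[k];
            double pr = predict_one(tree, X, i, f, perm[k]);
            if ((pr >= 0.5 ? 1 : 0) == y[i]) correct_perm++;
          }
          imp[f] += static_cast<double>(correct - correct_perm) / n_oob;
          imp_trees[f]++;
        }
      }
    }
    forest.push_back(tree);
  }
  // importance: mean decrease in accuracy over all trees (trees not using a
  // feature contribute zero decrease), as in the standard formulation
  if (importance)
    for (int f = 0; f < p; ++f) imp[f] /= ntree;

  List trees(ntree);
  for (int t = 0; t < ntree; ++t) trees[t] = tree_to_list(forest[t]);
  for (int i = 0; i < n; ++i)
    oob_prob[i] = oob_n[i] > 0 ? oob_prob[i] / oob_n[i] : NA_REAL;
  return List::create(_["trees"] = trees, _["oob_prob"] = oob_prob,
                      _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow();
  int ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    Tree tree = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
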