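// Exact greedy tree construction for second-order gradient boosting.
// The split gain and leaf weights follow the regularized objective
//   Obj = -1/2 * sum_j G_j^2 / (H_j + lambda) + gamma * T
// so a split is kept only when
//   1/2 [G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda)] - gamma > 0.
// Ties are broken toward the lowest feature index, then the lowest
// threshold (features are scanned in order, values ascending, and only a
// strictly larger gain replaces the incumbent).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double GAIN_EPS = 1e-10;

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;  // -1 for leaf
  std::vector<double> weight;    // defined for leaves
  std::vector<double> G, H;
  std::vector<int> count;
  int add_node(double g, double h, int n) {
    feature.push_back(-1); threshold.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1); weight.push_back(0.0);
    G.push_back(g); H.push_back(h); count.push_back(n);
    return (int)feature.size() - 1;
  }
};

// [[Rcpp::export(name = ".cpp_build_tree")]]
List cpp_build_tree(NumericMatrix X, NumericVector g, NumericVector h,
                    IntegerMatrix sorted_idx, IntegerVector cols,
                    double lambda, double gamma, int max_depth,
                    double min_child_weight, double learning_rate) {
  const int n = X.nrow();
  TreeBuf tree;
  double G0 = 0.0, H0 = 0.0;
  for (int i = 0; i < n; ++i) { G0 += g[i]; H0 += h[i]; }
  int root = tree.add_node(G0, H0, n);
  std::vector<int> node_of(n, root);
  std::vector<int> active(1, root);

  for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
    int n_nodes = (int)tree.feature.size();
    std::vector<char> is_active(n_nodes, 0);
    for (int nd : active) is_active[nd] = 1;

    std::vector<double> best_gain(n_nodes, GAIN_EPS);
    std::vector<int> best_feat(n_nodes, -1);
    std::vector<double> best_thr(n_nodes, 0.0);

    std::vector<double> GL(n_nodes), HL(n_nodes), prevv(n_nodes);
    std::vector<int> seen(n_nodes);

    for (int jj = 0; jj < cols.size(); ++jj) {
      int j = cols[jj];
      for (int nd : active) { GL[nd] = HL[nd] = 0.0; seen[nd] = 0; }
      for (int r = 0; r < n; ++r) {
        int i = sorted_idx(r, j);
        int nd = node_of[i];
        if (!is_active[nd]) continue;
        double v = X(i, j);
        if (seen[nd] > 0 && v > prevv[nd]) {
          double gl = GL[nd], hl = HL[nd];
          double gr = tree.G[nd] - gl, hr = tree.H[nd] - hl;
          if (hl >= min_child_weight && hr >= min_child_weight) {
            double gain = 0.5 * (gl * gl / (hl + lambda) +
                                 gr * gr / (hr + lambda) -
                                 tree.G[nd] * tree.G[nd] /
                                 (tree.H[nd] + lambda)) - gamma;
            // strictly-better with a tolerance so exact ties (up to
            // float noise) resolve to the lowest feature index, then the
            // lowest threshold
            double slack = 1e-12 * std::max(1.0, std::fabs(best_gain[nd]));
            if (gain > best_gain[nd] + slack) {
              best_gain[nd] = gain;
              best_feat[nd] = j;
              best_thr[nd] = 0.5 * (prevv[nd] + v);
            }
          }
        }
        GL[nd] += g[i]; HL[nd] += h[i];
        prevv[nd] = v; seen[nd]++;
      }
    }

    // materialize the accepted splits
    std::vector<int> next_active;
    for (int nd : active) {
      if (best_feat[nd] < 0) continue;
      tree.feature[nd] = best_feat[nd];
      tree.threshold[nd] = best_thr[nd];
      int l = tree.add_node(0.0, 0.0, 0);
      int r = tree.add_node(0.0, 0.0, 0);
      tree.left[nd] = l; tree.right[nd] = r;
      next_active.push_back(l); next_active.push_back(r);
    }
    if (next_active.empty()) break;
    for (int i = 0; i < n; ++i) {
      int nd = node_of[i];
      if (nd < (int)tree.feature.size() && tree.feature[nd] >= 0) {
        int child = (X(i, tree.feature[nd]) <= tree.threshold[nd])
                        ? tree.left[nd] : tree.right[nd];
        node_of[i] = child;
        tree.G[child] += g[i]; tree.H[child] += h[i]; tree.count[child]++;
      }
    }
    active.clear();
    for (int nd : next_active) {
      if (tree.count[nd] > 0) active.push_back(nd);
    }
  }

  int n_nodes = (int)tree.feature.size();
  int n_leaves = 0;
  for (int nd = 0; nd < n_nodes; ++nd) {
    if (tree.feature[nd] < 0) {
      tree.weight[nd] =
          -tree.G[nd] / (tree.H[nd] + lambda) * learning_rate;
      ++n_leaves;
    }
  }
  NumericVector fitted(n);
  for (int i = 0; i < n; ++i) fitted[i] = tree.weight[node_of[i]];

  return List::create(
      _["feature"] = wrap(tree.feature), _["threshold"] = wrap(tree.threshold),
      _["left"] = wrap(tree.left), _["right"] = wrap(tree.right),
      _["weight"] = wrap(tree.weight), _["G"] = wrap(tree.G),
      _["H"] = wrap(tree.H), _["count"] = wrap(tree.count),
      _["n_leaves"] = n_leaves, _["fitted"] = fitted);
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
NumericVector cpp_predict_tree(NumericMatrix X, IntegerVector feature,
                               NumericVector threshold, IntegerVector left,
                               IntegerVector right, NumericVector weight) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int nd = 0;
    while (feature[nd] >= 0) {
      nd = (X(i, feature[nd]) <= threshold[nd]) ? left[nd] : right[nd];
    }
    out[i] = weight[nd];
  }
  return out;
}
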