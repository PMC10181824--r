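// Gradient-boosted regression trees with squared-error loss, plus exact
// path-dependent tree-Shapley attributions.  Written here because no boosted
// tree library is available in the target R stack; the interface mirrors the
// usual XGBoost-style regularisation (L1 alpha, L2 lambda, gamma min-gain,
// row/column subsampling).
//
// Trees are stored as flat matrices (one row per node) so fitted models are
// plain R lists and serialise without any external dependency.
//
// Node matrix columns: 0 feature (0-based, -1 for leaf), 1 threshold,
// 2 left child, 3 right child, 4 value (leaf weight, already eta-scaled),
// 5 cover (number of full-training rows reaching the node).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeNode {
  int feature;      // -1 == leaf
  double threshold;
  int left, right;
  double value;
  double cover;
};

inline double soft_threshold(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

inline double split_score(double g, double h, double alpha, double lambda) {
  const double t = soft_threshold(g, alpha);
  return t * t / (h + lambda);
}

// traversal: x < threshold goes left
inline int descend(const std::vector<TreeNode>& tree, const double* xrow,
                   int nrow_stride, int node) {
  while (tree[node].feature >= 0) {
    const double v = xrow[(size_t)tree[node].feature * nrow_stride];
    node = (v < tree[node].threshold) ? tree[node].left : tree[node].right;
  }
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int nrounds, int max_depth,
                 double eta, double reg_alpha, double reg_lambda, double gamma,
                 double min_child_weight, IntegerMatrix row_samples,
                 List col_samples) {
  const int n = X.nrow(), p = X.ncol();
  const int n_sub = row_samples.nrow();
  if (n < 2) stop("need at least two rows");

  // base score and running predictions on the full training set
  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;
  std::vector<double> pred(n, base);

  // global per-feature sort orders (row indices ascending by feature value)
  std::vector<std::vector<int> > order(p, std::vector<int>(n));
  for (int f = 0; f < p; ++f) {
    std::vector<int>& o = order[f];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, f);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  List trees(nrounds);
  std::vector<int> in_sample(n);        // 0/1 membership, per tree
  std::vector<int> node_of_row(n, -1);  // tree-node id for sampled rows

  for (int t = 0; t < nrounds; ++t) {
    // gradients (squared error: g = pred - y, h = 1)
    std::fill(in_sample.begin(), in_sample.end(), 0);
    for (int k = 0; k < n_sub; ++k) in_sample[row_samples(k, t)] = 1;
    IntegerVector cols = col_samples[t];

    std::vector<TreeNode> tree;
    tree.push_back(TreeNode{-1, 0.0, -1, -1, 0.0, 0.0});
    for (int i = 0; i < n; ++i) node_of_row[i] = in_sample[i] ? 0 : -1;

    std::vector<int> level_nodes(1, 0);
    for (int depth = 0; depth < max_depth && !level_nodes.empty(); ++depth) {
      const int nl = (int)level_nodes.size();
      // map global node id -> position in this level
      std::vector<int> pos(tree.size(), -1);
      for (int j = 0; j < nl; ++j) pos[level_nodes[j]] = j;

      std::vector<double> G(nl, 0.0), H(nl, 0.0);
      for (int i = 0; i < n; ++i) {
        const int nd = node_of_row[i];
        if (nd < 0 || pos[nd] < 0) continue;
        G[pos[nd]] += pred[i] - y[i];
        H[pos[nd]] += 1.0;
      }

      std::vector<double> best_gain(nl, 0.0), best_thr(nl, 0.0);
      std::vector<int> best_feat(nl, -1);

      // per-node scan state, reset per feature
      std::vector<double> GL(nl), HL(nl), lastv(nl);
      std::vector<char> seen(nl);
      for (int ci = 0; ci < cols.size(); ++ci) {
        const int f = cols[ci];
        std::fill(GL.begin(), GL.end(), 0.0);
        std::fill(HL.begin(), HL.end(), 0.0);
        std::fill(seen.begin(), seen.end(), 0);
        const std::vector<int>& o = order[f];
        for (int k = 0; k < n; ++k) {
          const int i = o[k];
          const int nd = node_of_row[i];
          if (nd < 0) continue;
          const int j = pos[nd];
          if (j < 0) continue;
          const double v = X(i, f);
          if (seen[j] && v > lastv[j]) {
            const double HR = H[j] - HL[j];
            if (HL[j] >= min_child_weight && HR >= min_child_weight) {
              const double gain =
                  0.5 * (split_score(GL[j], HL[j], reg_alpha, reg_lambda) +
                         split_score(G[j] - GL[j], HR, reg_alpha, reg_lambda) -
                         split_score(G[j], H[j], reg_alpha, reg_lambda)) -
                  gamma;
              if (gain > best_gain[j] + 1e-12) {
                best_gain[j] = gain;
                best_feat[j] = f;
                best_thr[j] = 0.5 * (lastv[j] + v);
              }
            }
          }
          GL[j] += pred[i] - y[i];
          HL[j] += 1.0;
          lastv[j] = v;
          seen[j] = 1;
        }
      }

      // apply splits, create children
      std::vector<int> next_level;
      for (int j = 0; j < nl; ++j) {
        const int nd = level_nodes[j];
        if (best_feat[j] >= 0) {
          const int l = (int)tree.size(), r = l + 1;
          tree[nd].feature = best_feat[j];
          tree[nd].threshold = best_thr[j];
          tree[nd].left = l;
          tree[nd].right = r;
          tree.push_back(TreeNode{-1, 0.0, -1, -1, 0.0, 0.0});
          tree.push_back(TreeNode{-1, 0.0, -1, -1, 0.0, 0.0});
          next_level.push_back(l);
          next_level.push_back(r);
        }
      }
      if (!next_level.empty()) {
        for (int i = 0; i < n; ++i) {
          const int nd = node_of_row[i];
          if (nd < 0 || tree[nd].feature < 0) continue;
          node_of_row[i] = (X(i, tree[nd].feature) < tree[nd].threshold)
                               ? tree[nd].left
                               : tree[nd].right;
        }
      }
      level_nodes.swap(next_level);
    }

    // leaf weights from the sampled rows
    {
      const int nn = (int)tree.size();
      std::vector<double> Gn(nn, 0.0), Hn(nn, 0.0);
      for (int i = 0; i < n; ++i) {
        const int nd = node_of_row[i];
        if (nd < 0) continue;
        Gn[nd] += pred[i] - y[i];
        Hn[nd] += 1.0;
      }
      for (int nd = 0; nd < nn; ++nd)
        if (tree[nd].feature < 0)
          tree[nd].value =
              -eta * soft_threshold(Gn[nd], reg_alpha) / (Hn[nd] + reg_lambda);
    }

    // cover over the FULL training set (used by the Shapley value function)
    // and prediction update
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      tree[nd].cover += 1.0;
      while (tree[nd].feature >= 0) {
        nd = (X(i, tree[nd].feature) < tree[nd].threshold) ? tree[nd].left
                                                           : tree[nd].right;
        tree[nd].cover += 1.0;
      }
      pred[i] += tree[nd].value;
    }

    NumericMatrix m((int)tree.size(), 6);
    for (int nd = 0; nd < (int)tree.size(); ++nd) {
      m(nd, 0) = tree[nd].feature;
      m(nd, 1) = tree[nd].threshold;
      m(nd, 2) = tree[nd].left;
      m(nd, 3) = tree[nd].right;
      m(nd, 4) = tree[nd].value;
      m(nd, 5) = tree[nd].cover;
    }
    trees[t] = m;
  }

  return List::create(_["trees"] = trees, _["base_score"] = base);
}

static std::vector<TreeNode> unpack_tree(NumericMatrix m) {
  std::vector<TreeNode> tree(m.nrow());
  for (int nd = 0; nd < m.nrow(); ++nd) {
    tree[nd].feature = (int)m(nd, 0);
    tree[nd].threshold = m(nd, 1);
    tree[nd].left = (int)m(nd, 2);
    tree[nd].right = (int)m(nd, 3);
    tree[nd].value = m(nd, 4);
    tree[nd].cover = m(nd, 5);
  }
  return tree;
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List trees, double base_score, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  for (int t = 0; t < trees.size(); ++t) {
    std::vector<TreeNode> tree = unpack_tree(trees[t]);
    for (int i = 0; i < n; ++i) {
      const int leaf = descend(tree, &X(i, 0), n, 0);
      out[i] += tree[leaf].value;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Path-dependent tree-Shapley (polynomial-time recursion over decision paths
// with the conditional-expectation value function defined by node covers).

namespace {

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

void extend_path(PathElement* path, int unique_depth, double zero_fraction,
                 double one_fraction, int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight +=
        one_fraction * path[i].pweight * (i + 1) / (double)(unique_depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight * (unique_depth - i) /
                      (double)(unique_depth + 1);
  }
}

void unwind_path(PathElement* path, int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight =
          next_one_portion * (unique_depth + 1) / (double)((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                                   (unique_depth - i) / (double)(unique_depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1)) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement* path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp =
          next_one_portion * (unique_depth + 1) / (double)((i + 1) * one_fraction);
      total += tmp;
      next_one_portion =
          path[i].pweight -
          tmp * zero_fraction * ((unique_depth - i) / (double)(unique_depth + 1));
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((unique_depth - i) / (double)(unique_depth + 1));
    }
  }
  return total;
}

void tree_shap_recursive(const std::vector<TreeNode>& tree, const double* xrow,
                         int nrow_stride, double* phi, int node,
                         int unique_depth, PathElement* parent_path,
                         double parent_zero_fraction,
                         double parent_one_fraction, int parent_feature_index) {
  // phi points at row i of a column-major n x p matrix: entry for feature f
  // lives at phi[f * nrow_stride]
  PathElement* path = parent_path + unique_depth + 1;
  std::copy(parent_path, parent_path + unique_depth + 1, path);
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  const TreeNode& nd = tree[node];
  if (nd.feature < 0) {
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      phi[(size_t)path[i].feature_index * nrow_stride] +=
          w * (path[i].one_fraction - path[i].zero_fraction) * nd.value;
    }
    return;
  }

  const double xval = xrow[(size_t)nd.feature * nrow_stride];
  const int hot = (xval < nd.threshold) ? nd.left : nd.right;
  const int cold = (hot == nd.left) ? nd.right : nd.left;
  const double hot_zero_fraction = tree[hot].cover / nd.cover;
  const double cold_zero_fraction = tree[cold].cover / nd.cover;
  double incoming_zero_fraction = 1.0, incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (path[path_index].feature_index == nd.feature) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, xrow, nrow_stride, phi, hot, unique_depth + 1, path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, nd.feature);
  tree_shap_recursive(tree, xrow, nrow_stride, phi, cold, unique_depth + 1,
                      path, cold_zero_fraction * incoming_zero_fraction, 0.0,
                      nd.feature);
}

int tree_depth(const std::vector<TreeNode>& tree, int node) {
  if (tree[node].feature < 0) return 1;
  return 1 + std::max(tree_depth(tree, tree[node].left),
                      tree_depth(tree, tree[node].right));
}

}  // namespace

// [[Rcpp::export(name = ".gbt_shap_cpp")]]
List gbt_shap_cpp(List trees, double base_score, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  double expected = base_score;

  for (int t = 0; t < trees.size(); ++t) {
    std::vector<TreeNode> tree = unpack_tree(trees[t]);
    // tree mean (cover-weighted leaf values) contributes to the base value
    double tree_mean = 0.0;
    for (size_t nd = 0; nd < tree.size(); ++nd)
      if (tree[nd].feature < 0)
        tree_mean += tree[nd].value * tree[nd].cover / tree[0].cover;
    expected += tree_mean;

    const int d = tree_depth(tree, 0) + 2;
    std::vector<PathElement> buffer((d * (d + 1)) / 2 + 2 * d + 4);
    for (int i = 0; i < n; ++i) {
      tree_shap_recursive(tree, &X(i, 0), n, &phi(i, 0), 0, 0, buffer.data(),
                          1.0, 1.0, -1);
    }
  }
  return List::create(_["phi"] = phi, _["expected_value"] = expected);
}
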