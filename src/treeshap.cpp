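// Path-dependent TreeSHAP in double precision for binary tree ensembles.
// Computes, for each row, the exact Shapley attribution of every feature
// under the tree-path-dependent feature perturbation, plus the ensemble
// margin (sum of leaf values) recomputed in double. Attributions satisfy
// base + sum(phi) == margin to double rounding error.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> yes, no, miss;
  std::vector<double> value;  // leaf value (0 for internal)
  std::vector<double> cover;
  int max_depth;
};

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *unique_path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1) / double(unique_depth + 1);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) / double(unique_depth + 1);
  }
}

static void unwind_path(PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               double((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                               (unique_depth - i) / double(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
                               (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *unique_path,
                               int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         double((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight - tmp * zero_fraction *
                         ((unique_depth - i) / double(unique_depth + 1));
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / double(unique_depth + 1));
    }
  }
  return total;
}

static void tree_shap_recursive(const Tree &tr, const double *x, double *phi,
                                int node, int unique_depth,
                                PathElement *parent_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *unique_path = parent_path + unique_depth + 1;
  for (int i = 0; i <= unique_depth; ++i) unique_path[i] = parent_path[i];
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (tr.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * tr.value[node];
    }
    return;
  }

  const int split = tr.feature[node];
  const double xv = x[split];
  int hot;
  // xgboost evaluates splits in float32; mirror that exactly
  if (ISNAN(xv)) hot = tr.miss[node];
  else hot = ((float)xv < (float)tr.threshold[node]) ? tr.yes[node] : tr.no[node];
  const int cold = (hot == tr.yes[node]) ? tr.no[node] : tr.yes[node];
  const double w = tr.cover[node];
  const double hot_zero_fraction = tr.cover[hot] / w;
  const double cold_zero_fraction = tr.cover[cold] / w;
  double incoming_zero_fraction = 1.0, incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (unique_path[path_index].feature_index == split) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tr, x, phi, hot, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split);
  tree_shap_recursive(tr, x, phi, cold, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0, split);
}

static int node_depth(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return 1;
  return 1 + std::max(node_depth(tr, tr.yes[node]), node_depth(tr, tr.no[node]));
}

static double tree_expectation(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  const int l = tr.yes[node], r = tr.no[node];
  return (tr.cover[l] * tree_expectation(tr, l) +
          tr.cover[r] * tree_expectation(tr, r)) / tr.cover[node];
}

static double tree_predict(const Tree &tr, const double *x) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    const double xv = x[tr.feature[node]];
    if (ISNAN(xv)) node = tr.miss[node];
    else node = ((float)xv < (float)tr.threshold[node]) ? tr.yes[node] : tr.no[node];
  }
  return tr.value[node];
}

// trees: list of lists with integer vectors feature (0-based, -1 leaf),
// yes/no/miss (0-based node ids) and numeric threshold/value/cover.
// X: rows to explain (features in model column order, NA = missing).
// [[Rcpp::export]]
List cpp_treeshap(List trees, NumericMatrix X) {
  const int ntree = trees.size();
  const int n = X.nrow(), p = X.ncol();
  std::vector<Tree> forest(ntree);
  int max_depth = 0;
  double base = 0.0;
  for (int t = 0; t < ntree; ++t) {
    List tl = trees[t];
    Tree &tr = forest[t];
    tr.feature = as<std::vector<int>>(tl["feature"]);
    tr.threshold = as<std::vector<double>>(tl["threshold"]);
    tr.yes = as<std::vector<int>>(tl["yes"]);
    tr.no = as<std::vector<int>>(tl["no"]);
    tr.miss = as<std::vector<int>>(tl["miss"]);
    tr.value = as<std::vector<double>>(tl["value"]);
    tr.cover = as<std::vector<double>>(tl["cover"]);
    tr.max_depth = node_depth(tr, 0);
    if (tr.max_depth > max_depth) max_depth = tr.max_depth;
    base += tree_expectation(tr, 0);
  }

  NumericMatrix phi(n, p);
  NumericVector margin(n);
  const int path_len = (max_depth + 2) * (max_depth + 3) / 2 + 2;
  std::vector<PathElement> path(path_len);
  std::vector<double> row(p), phirow(p);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    std::fill(phirow.begin(), phirow.end(), 0.0);
    double m = 0.0;
    for (int t = 0; t < ntree; ++t) {
      const Tree &tr = forest[t];
      m += tree_predict(tr, row.data());
      if (tr.feature[0] < 0) continue;  // single-leaf tree: only base
      tree_shap_recursive(tr, row.data(), phirow.data(), 0, 0, path.data(),
                          1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = phirow[j];
    margin[i] = m;
  }
  return List::create(_["phi"] = phi, _["base"] = base,
                      _["margin"] = margin);
}
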