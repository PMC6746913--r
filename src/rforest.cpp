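// Deterministic random forest for binary classification, plus the greedy
// identity-filter kernel. The forest uses its own mt19937 stream (seeded
// from R) so that fits are bit-reproducible across platforms independently
// of R's RNG state: CART trees, Gini splits, bootstrap bagging, per-node
// uniform feature subsampling without replacement.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;    // -1 for a leaf
  double threshold;
  int left, right;
  double prob;    // P(class 1) among training samples in the node
};

struct Tree {
  std::vector<Node> nodes;
};

// bounded draw from the raw mt19937 stream; modulo bias is irrelevant here
inline int rand_below(std::mt19937 &rng, int n) {
  return static_cast<int>(rng() % static_cast<std::uint32_t>(n));
}

struct BuildCtx {
  const NumericMatrix &X;
  const IntegerVector &y;
  int mtry, min_node, max_depth;
  std::mt19937 &rng;
  std::vector<int> feat_pool;
};

int build_node(BuildCtx &ctx, Tree &tree, std::vector<int> &idx, int depth) {
  const int n = static_cast<int>(idx.size());
  int pos = 0;
  for (int i : idx) pos += ctx.y[i];

  Node node;
  node.feature = -1;
  node.threshold = 0.0;
  node.left = node.right = -1;
  node.prob = static_cast<double>(pos) / n;

  bool stop = (pos == 0 || pos == n || n < 2 * ctx.min_node ||
               depth >= ctx.max_depth);
  if (!stop) {
    // choose mtry distinct candidate features (partial Fisher-Yates)
    const int p = ctx.X.ncol();
    std::vector<int> &pool = ctx.feat_pool;
    for (int j = 0; j < ctx.mtry; ++j) {
      int k = j + rand_below(ctx.rng, p - j);
      std::swap(pool[j], pool[k]);
    }

    double best_score = -1.0;
    int best_feat = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < ctx.mtry; ++j) {
      const int f = pool[j];
      for (int i = 0; i < n; ++i)
        vals[i] = {ctx.X(idx[i], f), ctx.y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;

      // scan split points between distinct values; maximize
      // sum over children of (pos^2 + neg^2) / size  (Gini gain up to const)
      int lp = 0;
      for (int i = 0; i < n - 1; ++i) {
        lp += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        const int ln = i + 1, rn = n - ln;
        const int rp = pos - lp;
        const double score =
            (static_cast<double>(lp) * lp +
             static_cast<double>(ln - lp) * (ln - lp)) / ln +
            (static_cast<double>(rp) * rp +
             static_cast<double>(rn - rp) * (rn - rp)) / rn;
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_feat >= 0) {
      std::vector<int> left_idx, right_idx;
      left_idx.reserve(n);
      right_idx.reserve(n);
      for (int i : idx) {
        if (ctx.X(i, best_feat) <= best_thr) left_idx.push_back(i);
        else right_idx.push_back(i);
      }
      if (!left_idx.empty() && !right_idx.empty()) {
        node.feature = best_feat;
        node.threshold = best_thr;
        const int self = static_cast<int>(tree.nodes.size());
        tree.nodes.push_back(node);
        idx.clear();
        idx.shrink_to_fit();
        tree.nodes[self].left = build_node(ctx, tree, left_idx, depth + 1);
        tree.nodes[self].right = build_node(ctx, tree, right_idx, depth + 1);
        return self;
      }
    }
  }
  tree.nodes.push_back(node);
  return static_cast<int>(tree.nodes.size() - 1);
}

double tree_score(const Tree &t, const NumericMatrix &X, int row, bool vote) {
  int cur = 0;
  while (t.nodes[cur].feature >= 0) {
    cur = (X(row, t.nodes[cur].feature) <= t.nodes[cur].threshold)
              ? t.nodes[cur].left
              : t.nodes[cur].right;
  }
  const double p = t.nodes[cur].prob;
  return vote ? (p >= 0.5 ? 1.0 : 0.0) : p;
}

std::vector<Tree> unpack_forest(const List &forest) {
  std::vector<Tree> trees(forest.size());
  for (int t = 0; t < forest.size(); ++t) {
    List tl = forest[t];
    IntegerVector feature = tl["feature"];
    NumericVector threshold = tl["threshold"];
    IntegerVector left = tl["left"];
    IntegerVector right = tl["right"];
    NumericVector prob = tl["prob"];
    Tree &tr = trees[t];
    tr.nodes.resize(feature.size());
    for (int i = 0; i < feature.size(); ++i) {
      tr.nodes[i] = {feature[i], threshold[i], left[i], right[i], prob[i]};
    }
  }
  return trees;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, int max_depth, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (mtry < 1 || mtry > p) stop("mtry out of range");

  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  List forest(ntree);

  BuildCtx ctx{X, y, mtry, min_node, max_depth, rng, {}};
  ctx.feat_pool.resize(p);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = rand_below(rng, n);
    for (int j = 0; j < p; ++j) ctx.feat_pool[j] = j;

    Tree tree;
    tree.nodes.reserve(64);
    build_node(ctx, tree, boot, 0);

    const int m = static_cast<int>(tree.nodes.size());
    IntegerVector feature(m), left(m), right(m);
    NumericVector threshold(m), prob(m);
    for (int i = 0; i < m; ++i) {
      feature[i] = tree.nodes[i].feature;
      threshold[i] = tree.nodes[i].threshold;
      left[i] = tree.nodes[i].left;
      right[i] = tree.nodes[i].right;
      prob[i] = tree.nodes[i].prob;
    }
    forest[t] = List::create(Named("feature") = feature,
                             Named("threshold") = threshold,
                             Named("left") = left, Named("right") = right,
                             Named("prob") = prob);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X, bool vote) {
  const std::vector<Tree> trees = unpack_forest(forest);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (const Tree &t : trees) acc += tree_score(t, X, i, vote);
    out[i] = acc / trees.size();
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector identity_filter_cpp(IntegerMatrix m, double threshold) {
  const int n = m.nrow(), L = m.ncol();
  const int max_match = static_cast<int>(std::floor(threshold * L + 1e-9));
  std::vector<int> kept;
  LogicalVector keep(n, false);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (int kidx : kept) {
      int match = 0;
      for (int j = 0; j < L; ++j)
        if (m(i, j) == m(kidx, j)) ++match;
      // identity above the threshold, or an exact duplicate, is redundant
      if (match > max_match || match == L) {
        ok = false;
        break;
      }
    }
    if (ok) {
      keep[i] = true;
      kept.push_back(i);
    }
  }
  return keep;
}
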