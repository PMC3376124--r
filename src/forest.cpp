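// Decision-tree growth and traversal for the bagged ensemble classifier.
// Trees are fully grown (no pruning): a node becomes a leaf only when it
// is class-pure or no candidate split on its random feature subset can
// separate its samples (all sampled features constant). Impure nodes are
// split on the maximum impurity decrease even when that decrease is zero
// (necessary for parity-style interactions such as XOR, where the first
// split gains nothing but enables pure grandchildren). Candidate
// thresholds are midpoints between consecutive distinct sorted values.
// The feature subset drawn at each node has fixed size m; randomness
// comes from a per-tree mt19937 seed so growth is bit-reproducible.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// impurity of a (pos, neg) count pair, times the node size
static double nodeImpurity(double npos, double nneg, int criterion) {
  double n = npos + nneg;
  if (n <= 0.0) return 0.0;
  if (criterion == 1) {  // gini
    double p = npos / n;
    return n * 2.0 * p * (1.0 - p);
  }
  double h = 0.0;        // entropy (nats)
  if (npos > 0.0) h -= npos * std::log(npos / n);
  if (nneg > 0.0) h -= nneg * std::log(nneg / n);
  return h;
}

struct TreeBuf {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // -1 for leaf
  std::vector<int> pred;        // leaf class (0 neg / 1 pos), -1 internal
  std::vector<int> n_node;      // samples reaching the node

  int addNode() {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(-1);
    n_node.push_back(0);
    return (int)feature.size() - 1;
  }
};

// [[Rcpp::export(name = ".cppGrowTree")]]
List cppGrowTree(NumericMatrix X, IntegerVector y, IntegerVector rows,
                 int m, int seed, int criterion) {
  const int M = X.ncol();
  if (m < 1 || m > M) stop("m must be between 1 and the feature count");
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> featPool(M);
  for (int j = 0; j < M; ++j) featPool[j] = j;

  TreeBuf tree;
  struct Work { int node; std::vector<int> samples; };
  std::vector<Work> stack;
  {
    std::vector<int> root(rows.begin(), rows.end());
    int id = tree.addNode();
    stack.push_back(Work{id, std::move(root)});
  }

  std::vector<std::pair<double, int>> vals;   // (value, label) sort buffer

  while (!stack.empty()) {
    Work wk = std::move(stack.back());
    stack.pop_back();
    std::vector<int>& s = wk.samples;
    const int n = (int)s.size();
    tree.n_node[wk.node] = n;

    int npos = 0;
    for (int i = 0; i < n; ++i) npos += y[s[i]];
    int nneg = n - npos;
    if (npos == 0 || nneg == 0 || n < 2) {
      // pure (or single sample): leaf; majority with ties to negative
      tree.pred[wk.node] = (npos > nneg) ? 1 : 0;
      continue;
    }

    // draw m distinct features (partial Fisher-Yates)
    for (int k = 0; k < m; ++k) {
      std::uniform_int_distribution<int> pickDist(k, M - 1);
      int pick = pickDist(rng);
      std::swap(featPool[k], featPool[pick]);
    }

    double parentImp = nodeImpurity((double)npos, (double)nneg, criterion);
    bool haveSplit = false;
    double bestGain = 0.0;
    int bestFeat = -1;
    double bestThr = 0.0;

    for (int k = 0; k < m; ++k) {
      const int f = featPool[k];
      vals.clear();
      for (int i = 0; i < n; ++i)
        vals.push_back(std::make_pair(X(s[i], f), y[s[i]]));
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      double lpos = 0.0, lneg = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        if (vals[i].second == 1) lpos += 1.0; else lneg += 1.0;
        if (vals[i].first == vals[i + 1].first) continue;
        double childImp =
          nodeImpurity(lpos, lneg, criterion) +
          nodeImpurity((double)npos - lpos, (double)nneg - lneg, criterion);
        double gain = parentImp - childImp;
        if (!haveSplit || gain > bestGain) {
          haveSplit = true;
          bestGain = gain;
          bestFeat = f;
          bestThr = vals[i].first + (vals[i + 1].first - vals[i].first) / 2.0;
        }
      }
    }

    if (bestFeat < 0) {
      tree.pred[wk.node] = (npos > nneg) ? 1 : 0;
      continue;
    }

    std::vector<int> ls, rs;
    for (int i = 0; i < n; ++i) {
      if (X(s[i], bestFeat) <= bestThr) ls.push_back(s[i]);
      else rs.push_back(s[i]);
    }
    // a midpoint threshold always separates at least one sample each way
    int lid = tree.addNode();
    int rid = tree.addNode();
    tree.feature[wk.node] = bestFeat;
    tree.threshold[wk.node] = bestThr;
    tree.left[wk.node] = lid;
    tree.right[wk.node] = rid;
    stack.push_back(Work{rid, std::move(rs)});
    stack.push_back(Work{lid, std::move(ls)});
  }

  return List::create(
    _["feature"] = wrap(tree.feature),
    _["threshold"] = wrap(tree.threshold),
    _["left"] = wrap(tree.left),
    _["right"] = wrap(tree.right),
    _["pred"] = wrap(tree.pred),
    _["n_node"] = wrap(tree.n_node));
}

// [[Rcpp::export(name = ".cppPredictTree")]]
IntegerVector cppPredictTree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  IntegerVector pred = tree["pred"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    out[i] = pred[node];
  }
  return out;
}
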