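#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// XGBoost-style boosted trees: second-order logistic objective, exact greedy
// level-wise split search, gamma (min split gain) / lambda (L2) regularization,
// shrinkage eta. Deterministic: no row/column subsampling, ties broken by the
// lowest feature index.

namespace {

struct Node {
  int feat = -1;          // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double value = 0.0;     // leaf weight * eta
  double G = 0.0, H = 0.0;
  int level = 0;
  bool open = false;      // still splittable at its level
};

inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

}  // namespace

// [[Rcpp::export]]
List gbm_train_cpp(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
                   double eta, double gamma, double lambda,
                   double min_child_weight, double base_margin) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least two rows");

  // presort each feature once
  std::vector<std::vector<int> > order(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int>& o = order[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<double> margin(n, base_margin), g(n), h(n);
  NumericVector importance(p);
  List trees(n_trees);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      double pr = sigmoid(margin[i]);
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }

    std::vector<Node> nodes(1);
    nodes[0].open = true;
    std::vector<int> nid(n, 0);

    for (int depth = 0; depth < max_depth; ++depth) {
      // per-node totals for open nodes at this level
      int nn = (int)nodes.size();
      std::vector<char> active(nn, 0);
      bool any = false;
      for (int k = 0; k < nn; ++k)
        if (nodes[k].open && nodes[k].level == depth) { active[k] = 1; any = true; }
      if (!any) break;
      for (int k = 0; k < nn; ++k) { nodes[k].G = 0; nodes[k].H = 0; }
      for (int i = 0; i < n; ++i) {
        int k = nid[i];
        if (active[k]) { nodes[k].G += g[i]; nodes[k].H += h[i]; }
      }

      std::vector<double> best_gain(nn, 0.0), best_thr(nn, 0.0);
      std::vector<int> best_feat(nn, -1);
      std::vector<double> GL(nn), HL(nn), lastv(nn);
      std::vector<char> has(nn);

      for (int j = 0; j < p; ++j) {
        std::fill(GL.begin(), GL.end(), 0.0);
        std::fill(HL.begin(), HL.end(), 0.0);
        std::fill(has.begin(), has.end(), 0);
        const std::vector<int>& o = order[j];
        for (int ii = 0; ii < n; ++ii) {
          int s = o[ii];
          int k = nid[s];
          if (!active[k]) continue;
          double v = X(s, j);
          if (has[k] && v > lastv[k] + 1e-12) {
            double HR = nodes[k].H - HL[k];
            if (HL[k] >= min_child_weight && HR >= min_child_weight) {
              double GR = nodes[k].G - GL[k];
              double gain = 0.5 * (GL[k] * GL[k] / (HL[k] + lambda) +
                                   GR * GR / (HR + lambda) -
                                   nodes[k].G * nodes[k].G / (nodes[k].H + lambda)) -
                            gamma;
              if (gain > best_gain[k] + 1e-12) {
                best_gain[k] = gain;
                best_feat[k] = j;
                best_thr[k] = 0.5 * (lastv[k] + v);
              }
            }
          }
          GL[k] += g[s];
          HL[k] += h[s];
          lastv[k] = v;
          has[k] = 1;
        }
      }

      // apply splits / close leaves
      for (int k = 0; k < nn; ++k) {
        if (!active[k]) continue;
        if (best_feat[k] >= 0 && best_gain[k] > 0.0) {
          int l = (int)nodes.size(), r = l + 1;
          nodes.push_back(Node());
          nodes.push_back(Node());
          nodes[l].open = nodes[r].open = true;
          nodes[l].level = nodes[r].level = depth + 1;
          nodes[k].feat = best_feat[k];
          nodes[k].thr = best_thr[k];
          nodes[k].left = l;
          nodes[k].right = r;
          nodes[k].open = false;
          importance[best_feat[k]] += best_gain[k];
        } else {
          nodes[k].open = false;
          nodes[k].value = -eta * nodes[k].G / (nodes[k].H + lambda);
        }
      }
      // reassign samples of split nodes
      for (int i = 0; i < n; ++i) {
        int k = nid[i];
        if (k < nn && nodes[k].feat >= 0 && nodes[k].level == depth)
          nid[i] = (X(i, nodes[k].feat) < nodes[k].thr) ? nodes[k].left : nodes[k].right;
      }
    }
    // any node still open hit max depth: make it a leaf
    for (size_t k = 0; k < nodes.size(); ++k) {
      if (nodes[k].open) {
        nodes[k].G = 0; nodes[k].H = 0;
        nodes[k].open = false;
        nodes[k].feat = -1;
      }
    }
    // recompute G/H for depth-capped leaves and update margins
    {
      std::vector<double> Gs(nodes.size(), 0.0), Hs(nodes.size(), 0.0);
      for (int i = 0; i < n; ++i) { Gs[nid[i]] += g[i]; Hs[nid[i]] += h[i]; }
      for (size_t k = 0; k < nodes.size(); ++k)
        if (nodes[k].feat < 0 && nodes[k].value == 0.0 && Hs[k] > 0)
          nodes[k].value = -eta * Gs[k] / (Hs[k] + lambda);
      for (int i = 0; i < n; ++i) margin[i] += nodes[nid[i]].value;
    }

    NumericMatrix tm((int)nodes.size(), 5);
    for (size_t k = 0; k < nodes.size(); ++k) {
      tm(k, 0) = nodes[k].feat;   // -1 for leaf, else 0-based feature
      tm(k, 1) = nodes[k].thr;
      tm(k, 2) = nodes[k].left;
      tm(k, 3) = nodes[k].right;
      tm(k, 4) = nodes[k].value;
    }
    trees[t] = tm;
  }

  return List::create(_["trees"] = trees, _["base_margin"] = base_margin,
                      _["importance"] = importance);
}

// [[Rcpp::export]]
NumericVector gbm_margin_cpp(List trees, double base_margin, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while ((int)tm(k, 0) >= 0) {
        int j = (int)tm(k, 0);
        k = (X(i, j) < tm(k, 1)) ? (int)tm(k, 2) : (int)tm(k, 3);
      }
      out[i] += tm(k, 4);
    }
  }
  return out;
}
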