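// Deterministic histogram-based gradient-boosted regression trees.
//
// Features arrive pre-binned (integer codes 0..max_bins-1 per column, see
// R/gbdt.R). The binned matrix is copied once into a row-major uint8
// buffer so that building all feature histograms of a node is a single
// cache-friendly pass over its rows. Trees are grown depth-first with
// exact greedy variance-reduction splits; ties break toward the lowest
// feature index and lowest bin, and there is no row or column
// subsampling, so refitting with identical inputs is bit-reproducible.
// Squared-error loss: each tree fits the current residuals and the
// ensemble adds shrinkage times the leaf means.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

struct Node {
  int feature;   // -1 for a leaf
  int split;     // go left if bin <= split
  int left, right;
  double value;  // leaf mean residual
};

struct Workspace {
  const std::vector<uint8_t>& X;  // row-major n x p
  int n, p, max_bins, max_depth, min_leaf;
  const std::vector<double>* resid;
  std::vector<double> hsum;
  std::vector<int> hcnt;
  std::vector<int> rows;
  std::vector<Node> nodes;
  Workspace(const std::vector<uint8_t>& Xrm, int n_, int p_, int mb,
            int md, int ml)
      : X(Xrm), n(n_), p(p_), max_bins(mb), max_depth(md), min_leaf(ml),
        hsum((size_t)p_ * mb), hcnt((size_t)p_ * mb), rows(n_) {}
};

static void grow(Workspace& w, int lo, int hi, int depth, int node_id) {
  const int n = hi - lo;
  const std::vector<double>& r = *w.resid;
  double sum = 0.0;
  for (int k = lo; k < hi; ++k) sum += r[w.rows[k]];
  w.nodes[node_id].feature = -1;
  w.nodes[node_id].value = sum / n;
  if (depth >= w.max_depth || n < 2 * w.min_leaf) return;

  const int mb = w.max_bins;
  std::fill(w.hsum.begin(), w.hsum.end(), 0.0);
  std::fill(w.hcnt.begin(), w.hcnt.end(), 0);
  for (int k = lo; k < hi; ++k) {
    const int i = w.rows[k];
    const uint8_t* xi = &w.X[(size_t)i * w.p];
    const double ri = r[i];
    for (int j = 0; j < w.p; ++j) {
      const size_t h = (size_t)j * mb + xi[j];
      w.hsum[h] += ri;
      w.hcnt[h] += 1;
    }
  }
  const double parent = sum * sum / n;
  double best_gain = 1e-12;  // require a strictly positive gain
  int best_f = -1, best_b = -1;
  for (int j = 0; j < w.p; ++j) {
    const double* hs = &w.hsum[(size_t)j * mb];
    const int* hc = &w.hcnt[(size_t)j * mb];
    double sL = 0.0; int nL = 0;
    for (int b = 0; b < mb - 1; ++b) {  // split after bin b
      sL += hs[b]; nL += hc[b];
      if (nL == 0) continue;
      const int nR = n - nL;
      if (nR == 0) break;
      if (nL < w.min_leaf || nR < w.min_leaf) continue;
      const double sR = sum - sL;
      const double gain = sL * sL / nL + sR * sR / nR - parent;
      if (gain > best_gain) {
        best_gain = gain; best_f = j; best_b = b;
      }
    }
  }
  if (best_f < 0) return;

  // partition rows[lo,hi) stably: left block first
  std::vector<int> left_rows, right_rows;
  left_rows.reserve(n);
  for (int k = lo; k < hi; ++k) {
    const int i = w.rows[k];
    if (w.X[(size_t)i * w.p + best_f] <= best_b) left_rows.push_back(i);
    else right_rows.push_back(i);
  }
  std::copy(left_rows.begin(), left_rows.end(), w.rows.begin() + lo);
  std::copy(right_rows.begin(), right_rows.end(),
            w.rows.begin() + lo + left_rows.size());
  const int mid = lo + (int)left_rows.size();

  const int li = (int)w.nodes.size(); w.nodes.push_back(Node());
  const int ri = (int)w.nodes.size(); w.nodes.push_back(Node());
  w.nodes[node_id].feature = best_f;
  w.nodes[node_id].split = best_b;
  w.nodes[node_id].left = li;
  w.nodes[node_id].right = ri;
  grow(w, lo, mid, depth + 1, li);
  grow(w, mid, hi, depth + 1, ri);
}

static double tree_predict(const std::vector<Node>& nodes,
                           const uint8_t* xi) {
  int id = 0;
  while (nodes[id].feature >= 0) {
    id = (xi[nodes[id].feature] <= nodes[id].split)
         ? nodes[id].left : nodes[id].right;
  }
  return nodes[id].value;
}

static std::vector<uint8_t> row_major(const IntegerMatrix& X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<uint8_t> out((size_t)n * p);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      out[(size_t)i * p + j] = (uint8_t)X(i, j);
    }
  }
  return out;
}

static List pack(const std::vector<Node>& nodes) {
  const int m = (int)nodes.size();
  IntegerVector f(m), s(m), l(m), r(m);
  NumericVector v(m);
  for (int i = 0; i < m; ++i) {
    f[i] = nodes[i].feature; s[i] = nodes[i].split;
    l[i] = nodes[i].left; r[i] = nodes[i].right; v[i] = nodes[i].value;
  }
  return List::create(_["feature"] = f, _["split"] = s, _["left"] = l,
                      _["right"] = r, _["value"] = v);
}

static std::vector<Node> unpack(const List& tree) {
  IntegerVector f = tree["feature"], s = tree["split"],
                l = tree["left"], r = tree["right"];
  NumericVector v = tree["value"];
  std::vector<Node> nodes(f.size());
  for (int i = 0; i < f.size(); ++i) {
    nodes[i].feature = f[i]; nodes[i].split = s[i];
    nodes[i].left = l[i]; nodes[i].right = r[i]; nodes[i].value = v[i];
  }
  return nodes;
}

// [[Rcpp::export(name = ".gbdt_fit_cpp")]]
List gbdt_fit_cpp(IntegerMatrix X, NumericVector y, int n_trees,
                  int max_depth, double learning_rate, int min_leaf,
                  int max_bins) {
  const int n = X.nrow(), p = X.ncol();
  if (max_bins > 256) stop("max_bins must be <= 256");
  std::vector<uint8_t> Xrm = row_major(X);
  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;
  std::vector<double> pred(n, base), resid(n);
  Workspace w(Xrm, n, p, max_bins, max_depth, min_leaf);
  w.resid = &resid;
  List trees(n_trees);
  for (int m = 0; m < n_trees; ++m) {
    for (int i = 0; i < n; ++i) {
      resid[i] = y[i] - pred[i];
      w.rows[i] = i;
    }
    w.nodes.assign(1, Node());
    grow(w, 0, n, 0, 0);
    for (int i = 0; i < n; ++i) {
      pred[i] += learning_rate * tree_predict(w.nodes, &Xrm[(size_t)i * p]);
    }
    trees[m] = pack(w.nodes);
  }
  return List::create(_["base"] = base, _["trees"] = trees,
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export(name = ".gbdt_predict_cpp")]]
NumericVector gbdt_predict_cpp(List model, IntegerMatrix X, int n_trees) {
  List trees = model["trees"];
  const double base = model["base"];
  const double lr = model["learning_rate"];
  const int use = std::min((int)trees.size(), n_trees);
  const int n = X.nrow(), p = X.ncol();
  std::vector<uint8_t> Xrm = row_major(X);
  NumericVector out(n, base);
  for (int m = 0; m < use; ++m) {
    std::vector<Node> nodes = unpack(trees[m]);
    for (int i = 0; i < n; ++i) {
      out[i] += lr * tree_predict(nodes, &Xrm[(size_t)i * p]);
    }
  }
  return out;
}
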