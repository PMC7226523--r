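#include <Rcpp.h>
using namespace Rcpp;

// Gradient-boosted ensembles with depth-limited regression trees as base
// learners. Two losses: negative Cox partial log-likelihood (Breslow form)
// for censored survival, and binomial deviance for binary labels. Tree
// structure is found by least-squares fitting of the current negative
// gradient; leaf values are one Newton step (sum g / sum h), shrunk by the
// learning rate. The procedure is deterministic (no row/column subsampling).

struct Node { int feature; double threshold; int left, right; double value; };

static void grow(const NumericMatrix &X, const std::vector<int> &rows,
                 const std::vector<double> &g, const std::vector<double> &h,
                 int depth, int min_leaf, std::vector<Node> &nodes) {
  int me = nodes.size();
  nodes.push_back(Node());
  double G = 0, H = 0;
  for (size_t r = 0; r < rows.size(); ++r) { G += g[rows[r]]; H += h[rows[r]]; }
  nodes[me].feature = -1;
  nodes[me].left = nodes[me].right = -1;
  nodes[me].value = H > 1e-12 ? G / H : 0.0;

  int n = rows.size();
  if (depth <= 0 || n < 2 * min_leaf) return;

  int p = X.ncol();
  double best_gain = 1e-12;
  int best_f = -1, best_cut = -1;
  std::vector<int> idx(rows), best_order;
  double base = G * G / n;

  for (int f = 0; f < p; ++f) {
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return X(a, f) < X(b, f); });
    double GL = 0;
    for (int k = 0; k < n - 1; ++k) {
      GL += g[idx[k]];
      if (X(idx[k], f) == X(idx[k + 1], f)) continue;
      int nl = k + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double GR = G - GL;
      double gain = GL * GL / nl + GR * GR / nr - base;
      if (gain > best_gain) {
        best_gain = gain; best_f = f; best_cut = k;
        best_order = idx;
      }
    }
  }
  if (best_f < 0) return;

  nodes[me].feature = best_f;
  nodes[me].threshold = (X(best_order[best_cut], best_f) +
                         X(best_order[best_cut + 1], best_f)) / 2.0;
  std::vector<int> lrows(best_order.begin(), best_order.begin() + best_cut + 1);
  std::vector<int> rrows(best_order.begin() + best_cut + 1, best_order.end());
  nodes[me].left = nodes.size();
  grow(X, lrows, g, h, depth - 1, min_leaf, nodes);
  nodes[me].right = nodes.size();
  grow(X, rrows, g, h, depth - 1, min_leaf, nodes);
}

static double tree_predict(const std::vector<Node> &nodes, const NumericMatrix &X, int row) {
  int cur = 0;
  while (nodes[cur].feature >= 0)
    cur = X(row, nodes[cur].feature) <= nodes[cur].threshold ? nodes[cur].left : nodes[cur].right;
  return nodes[cur].value;
}

// Breslow gradient/hessian of the negative Cox partial log-likelihood and the
// loss itself, at linear predictor f. ord: rows sorted by increasing time.
static double cox_grad(const NumericVector &time, const IntegerVector &status,
                       const std::vector<int> &ord, const std::vector<double> &f,
                       std::vector<double> &g, std::vector<double> &h) {
  int n = ord.size();
  std::vector<double> ef(n);
  for (int i = 0; i < n; ++i) ef[i] = std::exp(f[i]);
  // risk-set sums walking from latest to earliest unique time
  double S0 = 0, loss = 0;
  double cum1 = 0, cum2 = 0;  // sum over event times <= t of d/R and d/R^2
  std::vector<double> c1(n), c2(n);
  int i = n - 1;
  // first pass: compute R at each unique time
  std::vector<double> Rj(n);  // risk-set mass keyed by position of first-at-time
  while (i >= 0) {
    double t = time[ord[i]];
    int j = i;
    while (j >= 0 && time[ord[j]] == t) { S0 += ef[ord[j]]; --j; }
    for (int k = j + 1; k <= i; ++k) Rj[k] = S0;
    i = j;
  }
  // cumulative event-time sums from earliest to latest
  int k = 0;
  while (k < n) {
    double t = time[ord[k]];
    int j = k, d = 0;
    double fl = 0;
    while (j < n && time[ord[j]] == t) { if (status[ord[j]]) { ++d; fl += f[ord[j]]; } ++j; }
    if (d > 0) {
      cum1 += d / Rj[k];
      cum2 += d / (Rj[k] * Rj[k]);
      loss -= fl - d * std::log(Rj[k]);
    }
    for (int m = k; m < j; ++m) { c1[m] = cum1; c2[m] = cum2; }
    k = j;
  }
  for (int m = 0; m < n; ++m) {
    int row = ord[m];
    g[row] = status[row] - ef[row] * c1[m];           // descent direction = +g
    h[row] = ef[row] * c1[m] - ef[row] * ef[row] * c2[m];
    if (h[row] < 1e-9) h[row] = 1e-9;
  }
  return loss;
}

// [[Rcpp::export]]
List cpp_boost_fit(NumericMatrix X, NumericVector time, IntegerVector status,
                   std::string loss, int n_stages, double learning_rate,
                   int max_depth, int min_leaf) {
  int n = X.nrow();
  std::vector<double> f(n, 0.0), g(n), h(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  double f0 = 0.0;

  bool cox = loss == "cox";
  if (cox) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return time[a] < time[b]; });
  } else {
    double ybar = 0;
    for (int i = 0; i < n; ++i) ybar += status[i];
    ybar /= n;
    ybar = std::min(std::max(ybar, 1e-6), 1 - 1e-6);
    f0 = std::log(ybar / (1 - ybar));
    for (int i = 0; i < n; ++i) f[i] = f0;
  }

  List trees(n_stages);
  NumericVector train_loss(n_stages);

  for (int s = 0; s < n_stages; ++s) {
    double cur;
    if (cox) {
      cur = cox_grad(time, status, ord, f, g, h);
    } else {
      cur = 0;
      for (int i = 0; i < n; ++i) {
        double p = 1.0 / (1.0 + std::exp(-f[i]));
        g[i] = status[i] - p;
        h[i] = std::max(p * (1 - p), 1e-9);
        cur -= status[i] ? std::log(std::max(p, 1e-12)) : std::log(std::max(1 - p, 1e-12));
      }
    }
    std::vector<Node> nodes;
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    grow(X, all, g, h, max_depth, min_leaf, nodes);
    NumericMatrix tm(nodes.size(), 5);
    for (size_t q = 0; q < nodes.size(); ++q) {
      tm(q, 0) = nodes[q].feature + 1;  // 0 = leaf in R encoding
      tm(q, 1) = nodes[q].feature >= 0 ? nodes[q].threshold : NA_REAL;
      tm(q, 2) = nodes[q].left + 1;
      tm(q, 3) = nodes[q].right + 1;
      tm(q, 4) = learning_rate * nodes[q].value;
    }
    trees[s] = tm;
    for (int i = 0; i < n; ++i) f[i] += learning_rate * tree_predict(nodes, X, i);
    train_loss[s] = cur;  // loss before this stage's update
  }

  NumericVector fhat(f.begin(), f.end());
  return List::create(_["f0"] = f0, _["trees"] = trees,
                      _["train_loss"] = train_loss, _["fitted"] = fhat);
}

// [[Rcpp::export]]
NumericVector cpp_boost_predict(List trees, double f0, NumericMatrix X, int n_stages) {
  int n = X.nrow();
  NumericVector out(n, f0);
  int S = std::min((int)trees.size(), n_stages);
  for (int s = 0; s < S; ++s) {
    NumericMatrix tm = trees[s];
    for (int i = 0; i < n; ++i) {
      int cur = 0;
      while ((int)tm(cur, 0) > 0) {
        int feat = (int)tm(cur, 0) - 1;
        cur = X(i, feat) <= tm(cur, 1) ? (int)tm(cur, 2) - 1 : (int)tm(cur, 3) - 1;
      }
      out[i] += tm(cur, 4);
    }
  }
  return out;
}
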