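// Compact binary-classification random forest with out-of-bag permutation
// variable importance (mean decrease in OOB accuracy).  Self-contained
// because no forest package is available at build time; gini splits,
// bootstrap per tree, mtry random candidate variables per node.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var, left, right, pred;  // pred used at leaves
  std::vector<double> thr;
  int new_node() {
    var.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1); pred.push_back(0);
    return static_cast<int>(var.size()) - 1;
  }
  // predict sample i, optionally overriding column `swap_var` with
  // `swap_val` (used for permutation importance)
  int predict(const NumericMatrix& x, int i, int swap_var,
              double swap_val) const {
    int node = 0;
    while (var[node] >= 0) {
      double v = (var[node] == swap_var) ? swap_val : x(i, var[node]);
      node = (v <= thr[node]) ? left[node] : right[node];
    }
    return pred[node];
  }
};

struct Job {
  int id, depth;
  std::vector<int> idx;
};

}  // namespace

// [[Rcpp::export]]
List rf_forest_cpp(NumericMatrix x, IntegerVector y, int ntree, int mtry,
                   int min_node, int max_depth, int seed) {
  const int n = x.nrow(), p = x.ncol();
  if (ntree < 1) stop("n_trees must be >= 1");
  if (mtry < 1 || mtry > p) stop("invalid mtry");
  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::uniform_int_distribution<int> unif_n(0, n - 1);

  std::vector<double> importance(p, 0.0);
  std::vector<double> oob_votes1(n, 0.0);
  std::vector<int> oob_times(n, 0);

  std::vector<int> perm(p);
  std::vector<double> vals;
  std::vector<int> ord;

  for (int t = 0; t < ntree; ++t) {
    // bootstrap
    std::vector<int> inbag(n, 0);
    for (int i = 0; i < n; ++i) inbag[unif_n(rng)]++;
    std::vector<int> root;
    root.reserve(n);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < inbag[i]; ++k) root.push_back(i);
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);

    Tree tree;
    std::vector<bool> used(p, false);
    std::vector<Job> stack;
    int root_id = tree.new_node();
    stack.push_back(Job{root_id, 0, std::move(root)});

    while (!stack.empty()) {
      Job job = std::move(stack.back());
      stack.pop_back();
      std::vector<int>& idx = job.idx;
      const int m = static_cast<int>(idx.size());
      int c1 = 0;
      for (int i : idx) c1 += y[i];
      tree.pred[job.id] =
          (2 * c1 > m) ? 1 : (2 * c1 < m ? 0 : static_cast<int>(rng() & 1u));
      if (c1 == 0 || c1 == m || m < 2 * min_node || job.depth >= max_depth)
        continue;

      // choose mtry candidate variables (partial Fisher-Yates)
      for (int j = 0; j < p; ++j) perm[j] = j;
      int best_var = -1;
      double best_thr = 0.0, best_score = 1e300;
      for (int k = 0; k < mtry; ++k) {
        std::uniform_int_distribution<int> pick(k, p - 1);
        std::swap(perm[k], perm[pick(rng)]);
        const int v = perm[k];
        vals.resize(m);
        ord.resize(m);
        for (int i = 0; i < m; ++i) {
          vals[i] = x(idx[i], v);
          ord[i] = i;
        }
        std::sort(ord.begin(), ord.end(),
                  [&](int a, int b) { return vals[a] < vals[b]; });
        int l1 = 0;
        for (int i = 0; i < m - 1; ++i) {
          l1 += y[idx[ord[i]]];
          const double xa = vals[ord[i]], xb = vals[ord[i + 1]];
          if (xa == xb) continue;
          const int nl = i + 1, nr = m - nl;
          const int r1 = c1 - l1;
          const double gl =
              1.0 - (static_cast<double>(l1) * l1 +
                     static_cast<double>(nl - l1) * (nl - l1)) /
                        (static_cast<double>(nl) * nl);
          const double gr =
              1.0 - (static_cast<double>(r1) * r1 +
                     static_cast<double>(nr - r1) * (nr - r1)) /
                        (static_cast<double>(nr) * nr);
          const double score = (nl * gl + nr * gr) / m;
          if (score < best_score) {
            best_score = score;
            best_var = v;
            best_thr = xa + (xb - xa) / 2.0;
          }
        }
      }
      if (best_var < 0) continue;  // no valid split among candidates

      std::vector<int> left_idx, right_idx;
      left_idx.reserve(m);
      right_idx.reserve(m);
      for (int i : idx) {
        if (x(i, best_var) <= best_thr) left_idx.push_back(i);
        else right_idx.push_back(i);
      }
      if (left_idx.empty() || right_idx.empty()) continue;
      used[best_var] = true;
      tree.var[job.id] = best_var;
      tree.thr[job.id] = best_thr;
      const int lid = tree.new_node(), rid = tree.new_node();
      tree.left[job.id] = lid;
      tree.right[job.id] = rid;
      stack.push_back(Job{lid, job.depth + 1, std::move(left_idx)});
      stack.push_back(Job{rid, job.depth + 1, std::move(right_idx)});
    }

    // OOB accuracy and permutation importance for this tree
    const int no = static_cast<int>(oob.size());
    if (no == 0) continue;
    int correct = 0;
    for (int i : oob) {
      const int pr = tree.predict(x, i, -1, 0.0);
      oob_votes1[i] += pr;
      oob_times[i]++;
      if (pr == y[i]) correct++;
    }
    const double acc = static_cast<double>(correct) / no;
    std::vector<double> shuffled(no);
    std::vector<int> pi(no);
    for (int v = 0; v < p; ++v) {
      if (!used[v]) continue;
      for (int i = 0; i < no; ++i) pi[i] = i;
      for (int i = no - 1; i > 0; --i) {
        std::uniform_int_distribution<int> pick(0, i);
        std::swap(pi[i], pi[pick(rng)]);
      }
      for (int i = 0; i < no; ++i) shuffled[i] = x(oob[pi[i]], v);
      int corr_perm = 0;
      for (int i = 0; i < no; ++i)
        if (tree.predict(x, oob[i], v, shuffled[i]) == y[oob[i]]) corr_perm++;
      importance[v] += acc - static_cast<double>(corr_perm) / no;
    }
  }

  NumericVector imp(p);
  for (int v = 0; v < p; ++v) imp[v] = importance[v] / ntree;
  IntegerVector oob_pred(n, NA_INTEGER);
  int oob_correct = 0, oob_n = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_times[i] == 0) continue;
    oob_pred[i] = (2.0 * oob_votes1[i] >= oob_times[i]) ? 1 : 0;
    oob_n++;
    if (oob_pred[i] == y[i]) oob_correct++;
  }
  return List::create(
      _["importance"] = imp, _["oob_prediction"] = oob_pred,
      _["oob_accuracy"] =
          oob_n ? static_cast<double>(oob_correct) / oob_n : NA_REAL);
}
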