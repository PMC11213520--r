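// Hierarchical density-based clustering (HDBSCAN).
//
// Pipeline: core distances (k-NN, counting the point itself) -> mutual
// reachability distances -> minimum spanning tree (Prim, distances computed on
// the fly so no n x n matrix is materialized) -> single-linkage dendrogram ->
// condensed tree at min_cluster_size -> stability-based excess-of-mass cluster
// extraction. Per-point lambda values (1 / departure distance) are returned so
// callers can rank members by density centrality (exemplars).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <limits>
#include <vector>
using namespace Rcpp;

static const double LAMBDA_CAP = 1e12;

struct Merge {
  int left, right;   // dendrogram node ids (0..n-1 leaves, n.. internal)
  double weight;
  int size;
};

static inline double sq_euclid(const double* x, int n, int d, int i, int j) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    const double diff = x[i + (size_t)n * k] - x[j + (size_t)n * k];
    s += diff * diff;
  }
  return s;
}

// [[Rcpp::export]]
List hdbscan_cpp(NumericMatrix X, int min_samples, int min_cluster_size,
                 bool allow_single_cluster) {
  const int n = X.nrow(), d = X.ncol();
  const double* x = REAL(X);
  if (min_samples < 1) stop("min_samples must be >= 1");
  if (min_samples > n) stop("min_samples larger than the number of points");

  // core distance: distance to the min_samples-th nearest neighbour,
  // counting the point itself
  std::vector<double> core(n);
  {
    std::vector<double> row(n);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) row[j] = sq_euclid(x, n, d, i, j);
      std::nth_element(row.begin(), row.begin() + (min_samples - 1), row.end());
      core[i] = std::sqrt(row[min_samples - 1]);
    }
  }

  // Prim's MST on the mutual reachability graph
  std::vector<double> best(n, std::numeric_limits<double>::infinity());
  std::vector<int> from(n, -1);
  std::vector<bool> in_tree(n, false);
  std::vector<int> edge_a(n - 1), edge_b(n - 1);
  std::vector<double> edge_w(n - 1);
  int cur = 0;
  in_tree[0] = true;
  for (int e = 0; e < n - 1; ++e) {
    double bw = std::numeric_limits<double>::infinity();
    int bi = -1;
    for (int j = 0; j < n; ++j) {
      if (in_tree[j]) continue;
      double mrd = std::sqrt(sq_euclid(x, n, d, cur, j));
      mrd = std::max(mrd, std::max(core[cur], core[j]));
      if (mrd < best[j]) { best[j] = mrd; from[j] = cur; }
      if (best[j] < bw) { bw = best[j]; bi = j; }
    }
    edge_a[e] = from[bi]; edge_b[e] = bi; edge_w[e] = bw;
    in_tree[bi] = true;
    cur = bi;
  }

  // single-linkage dendrogram via union-find over weight-sorted edges
  std::vector<int> order(n - 1);
  for (int i = 0; i < n - 1; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return edge_w[a] < edge_w[b]; });
  const int n_nodes = 2 * n - 1;
  std::vector<int> uf_parent(n_nodes), node_size(n_nodes, 1);
  for (int i = 0; i < n_nodes; ++i) uf_parent[i] = i;
  std::function<int(int)> find = [&](int v) {
    while (uf_parent[v] != v) { uf_parent[v] = uf_parent[uf_parent[v]]; v = uf_parent[v]; }
    return v;
  };
  std::vector<Merge> merges(n - 1);
  int next_node = n;
  for (int e = 0; e < n - 1; ++e) {
    const int idx = order[e];
    const int ra = find(edge_a[idx]), rb = find(edge_b[idx]);
    merges[next_node - n] = {ra, rb, edge_w[idx], node_size[ra] + node_size[rb]};
    node_size[next_node] = node_size[ra] + node_size[rb];
    uf_parent[ra] = next_node;
    uf_parent[rb] = next_node;
    ++next_node;
  }

  // condense the dendrogram: clusters must hold >= min_cluster_size points
  const int root_node = n_nodes - 1;
  std::vector<int> node_cluster(n_nodes, -1);
  std::vector<int> cl_parent;        // condensed cluster tree
  std::vector<double> cl_birth;      // lambda at which the cluster appears
  std::vector<int> point_cluster(n, -1);
  std::vector<double> point_lambda(n, 0.0);
  cl_parent.push_back(-1);
  cl_birth.push_back(0.0);
  node_cluster[root_node] = 0;

  // collect all leaf points under a dendrogram node
  std::vector<int> stack;
  auto emit_points = [&](int node, double lambda, int cluster) {
    stack.clear();
    stack.push_back(node);
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      if (v < n) {
        point_cluster[v] = cluster;
        point_lambda[v] = lambda;
      } else {
        node_cluster[v] = -2;  // consumed
        stack.push_back(merges[v - n].left);
        stack.push_back(merges[v - n].right);
      }
    }
  };

  for (int node = root_node; node >= n; --node) {
    const int cluster = node_cluster[node];
    if (cluster < 0) continue;  // inside an already-emitted small subtree
    const Merge& m = merges[node - n];
    const double w = m.weight;
    const double lambda = w > 1.0 / LAMBDA_CAP ? 1.0 / w : LAMBDA_CAP;
    const int sl = m.left < n ? 1 : merges[m.left - n].size;
    const int sr = m.right < n ? 1 : merges[m.right - n].size;
    const bool big_l = sl >= min_cluster_size, big_r = sr >= min_cluster_size;
    if (big_l && big_r) {
      node_cluster[m.left] = (int)cl_parent.size();
      cl_parent.push_back(cluster);
      cl_birth.push_back(lambda);
      node_cluster[m.right] = (int)cl_parent.size();
      cl_parent.push_back(cluster);
      cl_birth.push_back(lambda);
    } else if (big_l) {
      node_cluster[m.left] = cluster;
      emit_points(m.right, lambda, cluster);
    } else if (big_r) {
      node_cluster[m.right] = cluster;
      emit_points(m.left, lambda, cluster);
    } else {
      emit_points(m.left, lambda, cluster);
      emit_points(m.right, lambda, cluster);
    }
  }
  // points still attached directly (n == 1 edge cases)
  for (int i = 0; i < n; ++i)
    if (point_cluster[i] < 0 && node_cluster.size() && n == 1) point_cluster[i] = 0;

  const int n_cl = cl_parent.size();
  // subtree sizes and stabilities
  std::vector<int> cl_npts(n_cl, 0);
  std::vector<double> stab(n_cl, 0.0);
  for (int i = 0; i < n; ++i) {
    const int c = point_cluster[i];
    if (c >= 0) {
      cl_npts[c] += 1;
      stab[c] += std::min(point_lambda[i], LAMBDA_CAP) - cl_birth[c];
    }
  }
  std::vector<int> cl_size(cl_npts);
  std::vector<bool> has_child(n_cl, false);
  for (int c = n_cl - 1; c >= 1; --c) {
    cl_size[cl_parent[c]] += cl_size[c];
    has_child[cl_parent[c]] = true;
  }
  for (int c = n_cl - 1; c >= 1; --c)
    stab[cl_parent[c]] += (cl_birth[c] - cl_birth[cl_parent[c]]) * cl_size[c];

  // excess-of-mass selection, children before parents
  std::vector<bool> selected(n_cl, false);
  std::vector<double> child_sum(n_cl, 0.0);
  for (int c = n_cl - 1; c >= 0; --c) {
    const bool is_root = (c == 0);
    if (!has_child[c]) {
      selected[c] = !(is_root && !allow_single_cluster);
    } else if (is_root && !allow_single_cluster) {
      selected[c] = false;
      stab[c] = child_sum[c];
    } else if (stab[c] < child_sum[c]) {
      selected[c] = false;
      stab[c] = child_sum[c];
    } else {
      selected[c] = true;
    }
    if (c > 0) child_sum[cl_parent[c]] += stab[c];
  }
  // deselect descendants of selected clusters (top-down; parent id < child id)
  std::vector<bool> covered(n_cl, false);
  covered[0] = selected[0];
  for (int c = 1; c < n_cl; ++c) {
    if (covered[cl_parent[c]]) selected[c] = false;
    covered[c] = selected[c] || covered[cl_parent[c]];
  }

  // final labels: walk up from the departure cluster to the first selected one
  std::vector<int> sel_id(n_cl, -1);
  int k = 0;
  for (int c = 0; c < n_cl; ++c)
    if (selected[c]) sel_id[c] = k++;
  IntegerVector labels(n);
  NumericVector lambdas(n);
  for (int i = 0; i < n; ++i) {
    int c = point_cluster[i];
    int lab = -1;
    while (c >= 0) {
      if (selected[c]) { lab = sel_id[c]; break; }
      c = cl_parent[c];
    }
    labels[i] = lab;
    lambdas[i] = point_lambda[i];
  }
  return List::create(_["labels"] = labels, _["lambda"] = lambdas,
                      _["n_clusters"] = k, _["core_distance"] = NumericVector(core.begin(), core.end()));
}
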