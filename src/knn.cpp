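#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// k-th nearest-neighbour distances among a point cloud, self excluded.
// Two metrics: plain Euclidean via a median-split kd-tree (scales to 1e5+
// samples), and minimum-image periodic via a direct pairwise scan with
// early termination (used for periodic particle clouds).

namespace {

const double INF = std::numeric_limits<double>::infinity();

// k smallest squared distances, sorted ascending; cheap for small k
struct NBest {
  int k;
  std::vector<double> d;
  explicit NBest(int kk) : k(kk) { d.reserve(kk); }
  double worst() const { return (int)d.size() == k ? d.back() : INF; }
  void add(double s) {
    if ((int)d.size() == k) {
      if (s >= d.back()) return;
      d.pop_back();
    }
    d.insert(std::upper_bound(d.begin(), d.end(), s), s);
  }
};

struct KDTree {
  const double *pts;   // column-major M x d
  int M, d;
  std::vector<int> idx;
  struct Node { int lo, hi, axis, left, right; double split; };
  std::vector<Node> nodes;
  static const int LEAF = 16;

  double coord(int i, int j) const { return pts[(size_t)j * M + i]; }

  int build(int lo, int hi) {
    Node nd; nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
    nd.axis = 0; nd.split = 0.0;
    int cur = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo <= LEAF) return cur;
    int axis = 0; double best = -1.0;
    for (int j = 0; j < d; ++j) {
      double mn = coord(idx[lo], j), mx = mn;
      for (int t = lo + 1; t < hi; ++t) {
        double x = coord(idx[t], j);
        if (x < mn) mn = x;
        if (x > mx) mx = x;
      }
      if (mx - mn > best) { best = mx - mn; axis = j; }
    }
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, axis) < coord(b, axis); });
    nodes[cur].axis = axis;
    nodes[cur].split = coord(idx[mid], axis);
    int l = build(lo, mid);
    int r = build(mid, hi);
    nodes[cur].left = l;
    nodes[cur].right = r;
    return cur;
  }

  void init(const double *p, int m, int dd) {
    pts = p; M = m; d = dd;
    idx.resize(M);
    for (int i = 0; i < M; ++i) idx[i] = i;
    nodes.reserve(2 * M / LEAF + 4);
    build(0, M);
  }

  void search(int node, int q, NBest &best) const {
    const Node &nd = nodes[node];
    if (nd.left < 0) {
      for (int t = nd.lo; t < nd.hi; ++t) {
        int i = idx[t];
        if (i == q) continue;
        double s = 0.0, w = best.worst();
        for (int j = 0; j < d; ++j) {
          double dx = coord(i, j) - coord(q, j);
          s += dx * dx;
          if (s >= w) break;
        }
        if (s < w) best.add(s);
      }
      return;
    }
    double diff = coord(q, nd.axis) - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far  = diff <= 0 ? nd.right : nd.left;
    search(near, q, best);
    if (diff * diff < best.worst()) search(far, q, best);
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector knn_dist_cpp(NumericMatrix pts, int k) {
  int M = pts.nrow();
  if (k < 1 || k >= M) stop("need 1 <= k < number of samples");
  KDTree tree;
  tree.init(REAL(pts), M, pts.ncol());
  NumericVector out(M);
  for (int q = 0; q < M; ++q) {
    NBest best(k);
    tree.search(0, q, best);
    out[q] = std::sqrt(best.d.back());
  }
  return out;
}

// [[Rcpp::export]]
NumericVector knn_dist_periodic_cpp(NumericMatrix pts, int k, NumericVector box) {
  int M = pts.nrow(), d = pts.ncol();
  if (k < 1 || k >= M) stop("need 1 <= k < number of samples");
  if (box.size() != d) stop("box must have one period per dimension");
  NumericVector out(M);
  const double *P = REAL(pts);
  std::vector<double> half(d);
  for (int j = 0; j < d; ++j) half[j] = 0.5 * box[j];
  for (int q = 0; q < M; ++q) {
    NBest best(k);
    for (int i = 0; i < M; ++i) {
      if (i == q) continue;
      double s = 0.0, w = best.worst();
      for (int j = 0; j < d; ++j) {
        double dx = std::fabs(P[(size_t)j * M + i] - P[(size_t)j * M + q]);
        if (dx > half[j]) dx = box[j] - dx;
        s += dx * dx;
        if (s >= w) break;
      }
      if (s < w) best.add(s);
    }
    out[q] = std::sqrt(best.d.back());
  }
  return out;
}

// Mean minimum-image distance between two particle clouds sampled frame by
// frame (used for the triple-selection cutoff of the continuous MIE).
// [[Rcpp::export]]
double mean_pair_distance_cpp(NumericMatrix a, NumericMatrix b, NumericVector box) {
  int M = a.nrow(), d = a.ncol();
  double acc = 0.0;
  for (int i = 0; i < M; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      double dx = std::fabs(a(i, j) - b(i, j));
      double L = box[j];
      if (dx > 0.5 * L) dx = L - dx;
      s += dx * dx;
    }
    acc += std::sqrt(s);
  }
  return acc / M;
}

// Minimum-image squared-displacement cost matrix between a frame and a
// reference frame (permutation reduction).
// [[Rcpp::export]]
NumericMatrix assignment_cost_cpp(NumericMatrix frame, NumericMatrix ref,
                                  NumericVector box) {
  int n = frame.nrow();
  if (ref.nrow() != n) stop("frame and reference particle counts differ");
  NumericMatrix cost(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int m = 0; m < 3; ++m) {
        double dx = std::fabs(frame(i, m) - ref(j, m));
        double L = box[m];
        if (dx > 0.5 * L) dx = L - dx;
        s += dx * dx;
      }
      cost(i, j) = s;
    }
  }
  return cost;
}
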