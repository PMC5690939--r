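#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact nearest-neighbour search via a kd-tree over the secondary cloud.
// Approximate search is deliberately not offered: oracle equivalence with
// the all-pairs reference is a tested property of the distance engine.

namespace {

struct Node {
  int pt, left, right, axis;
};

class KDTree {
public:
  std::vector<Node> nodes;
  std::vector<double> coords; // 3 * n, point-major
  int root;

  KDTree(const NumericMatrix& P) {
    int n = P.nrow();
    coords.resize(3 * static_cast<size_t>(n));
    for (int i = 0; i < n; ++i) {
      coords[3 * i] = P(i, 0);
      coords[3 * i + 1] = P(i, 1);
      coords[3 * i + 2] = P(i, 2);
    }
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.reserve(n);
    root = build(idx, 0, n, 0);
  }

  int build(std::vector<int>& idx, int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int ax = depth % 3;
    int mid = (lo + hi) / 2;
    const std::vector<double>& c = coords;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&c, ax](int a, int b) {
                       return c[3 * a + ax] < c[3 * b + ax];
                     });
    Node nd;
    nd.pt = idx[mid];
    nd.axis = ax;
    nd.left = nd.right = -1;
    int me = static_cast<int>(nodes.size());
    nodes.push_back(nd);
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid + 1, hi, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  void query(const double* q, int node, double& best2) const {
    if (node < 0) return;
    const Node& nd = nodes[node];
    const double* p = &coords[3 * nd.pt];
    double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best2) best2 = d2;
    double diff = q[nd.axis] - p[nd.axis];
    int nearer = diff < 0 ? nd.left : nd.right;
    int farther = diff < 0 ? nd.right : nd.left;
    query(q, nearer, best2);
    if (diff * diff < best2) query(q, farther, best2);
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_nn_min_distances")]]
NumericVector cpp_nn_min_distances(NumericMatrix primary,
                                   NumericMatrix secondary) {
  if (secondary.nrow() < 1) stop("secondary cloud is empty");
  KDTree tree(secondary);
  int n = primary.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = {primary(i, 0), primary(i, 1), primary(i, 2)};
    double best2 = R_PosInf;
    tree.query(q, tree.root, best2);
    out[i] = std::sqrt(best2);
  }
  return out;
}

namespace {

inline double cross2(double ox, double oy, double ax, double ay,
                     double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

inline bool on_segment(double px, double py, double qx, double qy,
                       double rx, double ry, double eps) {
  return std::min(px, qx) - eps <= rx && rx <= std::max(px, qx) + eps &&
         std::min(py, qy) - eps <= ry && ry <= std::max(py, qy) + eps;
}

bool segments_intersect(double p1x, double p1y, double p2x, double p2y,
                        double q1x, double q1y, double q2x, double q2y,
                        double eps) {
  double d1 = cross2(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = cross2(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = cross2(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = cross2(p1x, p1y, p2x, p2y, q2x, q2y);
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps)))
    return true;
  if (std::abs(d1) <= eps && on_segment(q1x, q1y, q2x, q2y, p1x, p1y, eps))
    return true;
  if (std::abs(d2) <= eps && on_segment(q1x, q1y, q2x, q2y, p2x, p2y, eps))
    return true;
  if (std::abs(d3) <= eps && on_segment(p1x, p1y, p2x, p2y, q1x, q1y, eps))
    return true;
  if (std::abs(d4) <= eps && on_segment(p1x, p1y, p2x, p2y, q2x, q2y, eps))
    return true;
  return false;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_polygon_is_simple")]]
bool cpp_polygon_is_simple(NumericMatrix xy, double eps = 1e-9) {
  int n = xy.nrow();
  if (n < 3) return false;
  // edge i runs from vertex i to vertex (i+1) mod n (implicit closure)
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      // skip adjacent edges (shared endpoint), incl. the wrap-around pair
      if (j == i + 1 || (i == 0 && j == n - 1)) continue;
      if (segments_intersect(xy(i, 0), xy(i, 1), xy(i2, 0), xy(i2, 1),
                             xy(j, 0), xy(j, 1), xy(j2, 0), xy(j2, 1), eps))
        return false;
    }
  }
  return true;
}
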