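#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact closest-point queries from points to a triangle mesh through an
// axis-aligned bounding-box tree (median split on centroids). Pruning uses
// the lower bound distance to a node's box, with non-strict comparison so
// exactly tied candidates are never discarded; among exact ties the lowest
// triangle index wins (determinism contract).

namespace {

struct Tri { double a[3], b[3], c[3]; };

struct Node {
  double lo[3], hi[3];
  int left, right;      // children, or -1
  int start, count;     // leaf triangle range into `order`
};

struct BVH {
  std::vector<Tri> tris;
  std::vector<int> order;
  std::vector<Node> nodes;
  static const int LEAF = 8;

  void bounds(int start, int count, double *lo, double *hi) {
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int t = start; t < start + count; ++t) {
      const Tri &T = tris[order[t]];
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], std::min(T.a[d], std::min(T.b[d], T.c[d])));
        hi[d] = std::max(hi[d], std::max(T.a[d], std::max(T.b[d], T.c[d])));
      }
    }
  }

  int build(int start, int count) {
    Node nd;
    bounds(start, count, nd.lo, nd.hi);
    nd.start = start; nd.count = count; nd.left = nd.right = -1;
    int self = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= LEAF) return self;
    // split on widest centroid axis
    double clo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double chi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int t = start; t < start + count; ++t) {
      const Tri &T = tris[order[t]];
      for (int d = 0; d < 3; ++d) {
        double c = (T.a[d] + T.b[d] + T.c[d]) / 3.0;
        clo[d] = std::min(clo[d], c); chi[d] = std::max(chi[d], c);
      }
    }
    int axis = 0; double w = chi[0] - clo[0];
    for (int d = 1; d < 3; ++d)
      if (chi[d] - clo[d] > w) { w = chi[d] - clo[d]; axis = d; }
    if (!(w > 0)) return self;  // all centroids coincide: stay a leaf
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int u, int v) {
                       const Tri &U = tris[u], &V = tris[v];
                       double cu = U.a[axis] + U.b[axis] + U.c[axis];
                       double cv = V.a[axis] + V.b[axis] + V.c[axis];
                       if (cu != cv) return cu < cv;
                       return u < v;
                     });
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[self].left = l; nodes[self].right = r;
    return self;
  }

  static double box_dist2(const Node &nd, const double *p) {
    double s = 0;
    for (int d = 0; d < 3; ++d) {
      double v = 0;
      if (p[d] < nd.lo[d]) v = nd.lo[d] - p[d];
      else if (p[d] > nd.hi[d]) v = p[d] - nd.hi[d];
      s += v * v;
    }
    return s;
  }
};

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
inline void closest_pt_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d]; ac[d] = c[d] - a[d]; ap[d] = p[d] - a[d];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int d = 0; d < 3; ++d) out[d] = a[d]; return; }
  double bp[3];
  for (int d = 0; d < 3; ++d) bp[d] = p[d] - b[d];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int d = 0; d < 3; ++d) out[d] = b[d]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = (d1 - d3 != 0) ? d1 / (d1 - d3) : 0;
    for (int d = 0; d < 3; ++d) out[d] = a[d] + v * ab[d];
    return;
  }
  double cp[3];
  for (int d = 0; d < 3; ++d) cp[d] = p[d] - c[d];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int d = 0; d < 3; ++d) out[d] = c[d]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = (d2 - d6 != 0) ? d2 / (d2 - d6) : 0;
    for (int d = 0; d < 3; ++d) out[d] = a[d] + w * ac[d];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double den = (d4 - d3) + (d5 - d6);
    double w = den != 0 ? (d4 - d3) / den : 0;
    for (int d = 0; d < 3; ++d) out[d] = b[d] + w * (c[d] - b[d]);
    return;
  }
  double denom = va + vb + vc;
  double v = denom != 0 ? vb / denom : 0;
  double w = denom != 0 ? vc / denom : 0;
  for (int d = 0; d < 3; ++d) out[d] = a[d] + ab[d] * v + ac[d] * w;
}

} // namespace

// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix V, IntegerMatrix Fc, NumericMatrix Q) {
  int nf = Fc.nrow(), nq = Q.nrow();
  if (nf < 1) stop("mesh has no triangles");
  BVH bvh;
  bvh.tris.resize(nf);
  bvh.order.resize(nf);
  for (int t = 0; t < nf; ++t) {
    bvh.order[t] = t;
    for (int d = 0; d < 3; ++d) {
      bvh.tris[t].a[d] = V(Fc(t, 0) - 1, d);
      bvh.tris[t].b[d] = V(Fc(t, 1) - 1, d);
      bvh.tris[t].c[d] = V(Fc(t, 2) - 1, d);
    }
  }
  bvh.nodes.reserve(2 * nf / BVH::LEAF + 4);
  bvh.build(0, nf);

  NumericVector dist(nq);
  NumericMatrix cp(nq, 3);
  IntegerVector tri(nq);
  std::vector<int> stack;
  stack.reserve(64);
  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q, 0), Q(q, 1), Q(q, 2)};
    double best2 = R_PosInf, bestp[3] = {0, 0, 0};
    int besti = -1;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back(); stack.pop_back();
      const Node &nd = bvh.nodes[ni];
      if (BVH::box_dist2(nd, p) > best2) continue;
      if (nd.left < 0) {
        for (int t = nd.start; t < nd.start + nd.count; ++t) {
          int ti = bvh.order[t];
          const Tri &T = bvh.tris[ti];
          double c[3];
          closest_pt_tri(p, T.a, T.b, T.c, c);
          double dx = p[0]-c[0], dy = p[1]-c[1], dz = p[2]-c[2];
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 < best2 || (d2 == best2 && ti < besti)) {
            best2 = d2; besti = ti;
            bestp[0] = c[0]; bestp[1] = c[1]; bestp[2] = c[2];
          }
        }
      } else {
        // visit nearer child first (push farther first)
        double dl = BVH::box_dist2(bvh.nodes[nd.left], p);
        double dr = BVH::box_dist2(bvh.nodes[nd.right], p);
        if (dl <= dr) { stack.push_back(nd.right); stack.push_back(nd.left); }
        else          { stack.push_back(nd.left); stack.push_back(nd.right); }
      }
    }
    dist[q] = std::sqrt(best2);
    cp(q, 0) = bestp[0]; cp(q, 1) = bestp[1]; cp(q, 2) = bestp[2];
    tri[q] = besti + 1;  // 1-based
  }
  return List::create(_["distance"] = dist, _["point"] = cp,
                      _["triangle"] = tri);
}
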