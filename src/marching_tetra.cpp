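#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on the Kuhn 6-tetrahedron
// cube decomposition. The decomposition is translation-invariant (every
// cube is split around the same main diagonal), so tetrahedron faces on
// shared cube boundaries coincide and the resulting surface is watertight.
// Crossing vertices are welded through an (edge endpoint pair) -> vertex
// hash so the mesh is indexed, not a triangle soup.
//
// Triangle winding is fixed locally: the outward normal of each emitted
// triangle must point away from the "inside" (value > iso) corners of its
// tetrahedron.

namespace {

const int CO[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
// Kuhn: six tets around the 0-6 main diagonal
const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

struct Mesher {
  const double *field;
  int nx, ny, nz;
  double sx, sy, sz, ox, oy, oz;
  double iso;
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts;   // x,y,z triplets
  std::vector<int> faces;      // 0-based triplets

  inline size_t lin(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
  }
  inline void world(size_t id, double *p) const {
    size_t i = id % nx, rest = id / nx;
    size_t j = rest % ny, k = rest / ny;
    p[0] = ox + i * sx; p[1] = oy + j * sy; p[2] = oz + k * sz;
  }
  // welded crossing vertex on lattice edge (a, b); a, b linear voxel ids
  int crossing(size_t a, size_t b) {
    if (a > b) std::swap(a, b);
    uint64_t key = ((uint64_t)a << 32) | (uint64_t)b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = field[a], vb = field[b];
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double pa[3], pb[3];
    world(a, pa); world(b, pb);
    int idx = (int)(verts.size() / 3);
    verts.push_back(pa[0] + t * (pb[0] - pa[0]));
    verts.push_back(pa[1] + t * (pb[1] - pa[1]));
    verts.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex.emplace(key, idx);
    return idx;
  }
  inline void vpos(int v, double *p) const {
    p[0] = verts[3 * v]; p[1] = verts[3 * v + 1]; p[2] = verts[3 * v + 2];
  }
  // emit triangle (v1,v2,v3); flip so normal points away from `inref`
  // (a point on the inside of the surface)
  void emit(int v1, int v2, int v3, const double *inref) {
    double p1[3], p2[3], p3[3];
    vpos(v1, p1); vpos(v2, p2); vpos(v3, p3);
    double e1[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
    double e2[3] = {p3[0]-p1[0], p3[1]-p1[1], p3[2]-p1[2]};
    double nrm[3] = {e1[1]*e2[2]-e1[2]*e2[1],
                     e1[2]*e2[0]-e1[0]*e2[2],
                     e1[0]*e2[1]-e1[1]*e2[0]};
    double c[3] = {(p1[0]+p2[0]+p3[0])/3 - inref[0],
                   (p1[1]+p2[1]+p3[1])/3 - inref[1],
                   (p1[2]+p2[2]+p3[2])/3 - inref[2]};
    double dp = nrm[0]*c[0] + nrm[1]*c[1] + nrm[2]*c[2];
    if (dp >= 0) { faces.push_back(v1); faces.push_back(v2); faces.push_back(v3); }
    else         { faces.push_back(v1); faces.push_back(v3); faces.push_back(v2); }
  }

  void tetra(const size_t *cid, const double *cval, const int *tet) {
    size_t id[4]; double val[4]; bool in[4]; int nin = 0;
    for (int m = 0; m < 4; ++m) {
      id[m] = cid[tet[m]]; val[m] = cval[tet[m]];
      in[m] = val[m] > iso; nin += in[m];
    }
    if (nin == 0 || nin == 4) return;
    if (nin == 1 || nin == 3) {
      bool want = (nin == 1);          // the minority side
      int solo = 0;
      for (int m = 0; m < 4; ++m) if (in[m] == want) { solo = m; break; }
      int o[3], t = 0;
      for (int m = 0; m < 4; ++m) if (m != solo) o[t++] = m;
      int v1 = crossing(id[solo], id[o[0]]);
      int v2 = crossing(id[solo], id[o[1]]);
      int v3 = crossing(id[solo], id[o[2]]);
      double ref[3];
      if (nin == 1) {                  // solo corner is inside
        world(id[solo], ref);
        emit(v1, v2, v3, ref);
      } else {                         // solo corner is outside; inside ref =
        double c[3] = {0, 0, 0};       // centroid of the three inside corners
        for (int m = 0; m < 3; ++m) {
          double p[3]; world(id[o[m]], p);
          c[0] += p[0] / 3; c[1] += p[1] / 3; c[2] += p[2] / 3;
        }
        emit(v1, v2, v3, c);
      }
    } else {                           // 2 in / 2 out: quad
      int A = -1, B = -1, C = -1, D = -1;
      for (int m = 0; m < 4; ++m) {
        if (in[m]) { if (A < 0) A = m; else B = m; }
        else       { if (C < 0) C = m; else D = m; }
      }
      int q1 = crossing(id[A], id[C]);
      int q2 = crossing(id[A], id[D]);
      int q3 = crossing(id[B], id[D]);
      int q4 = crossing(id[B], id[C]);
      double pa[3], pb[3];
      world(id[A], pa); world(id[B], pb);
      double ref[3] = {(pa[0]+pb[0])/2, (pa[1]+pb[1])/2, (pa[2]+pb[2])/2};
      emit(q1, q2, q3, ref);
      emit(q1, q3, q4, ref);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             double iso) {
  Mesher M;
  M.field = field.begin();
  M.nx = dim[0]; M.ny = dim[1]; M.nz = dim[2];
  M.sx = spacing[0]; M.sy = spacing[1]; M.sz = spacing[2];
  M.ox = origin[0]; M.oy = origin[1]; M.oz = origin[2];
  M.iso = iso;
  const double *f = M.field;
  for (int k = 0; k < M.nz - 1; ++k) {
    for (int j = 0; j < M.ny - 1; ++j) {
      for (int i = 0; i < M.nx - 1; ++i) {
        size_t cid[8]; double cval[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cid[c] = M.lin(i + CO[c][0], j + CO[c][1], k + CO[c][2]);
          cval[c] = f[cid[c]];
          if (cval[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) M.tetra(cid, cval, TETS[t]);
      }
    }
  }
  int nv = (int)(M.verts.size() / 3);
  int nf = (int)(M.faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = M.verts[3 * v];
    V(v, 1) = M.verts[3 * v + 1];
    V(v, 2) = M.verts[3 * v + 2];
  }
  IntegerMatrix Fc(nf, 3);
  for (int t = 0; t < nf; ++t) {
    Fc(t, 0) = M.faces[3 * t] + 1;       // 1-based for R
    Fc(t, 1) = M.faces[3 * t + 1] + 1;
    Fc(t, 2) = M.faces[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}
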