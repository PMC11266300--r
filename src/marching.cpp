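#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Iso-surface extraction on a regular scalar grid by marching tetrahedra.
// Each grid cube is split into six tetrahedra around the main diagonal;
// crossings are linearly interpolated, deduplicated by the (sorted) pair of
// grid-node ids spanning the crossed edge, so the result is watertight by
// construction.  "Inside" is value >= iso; triangles are oriented outward
// (normals point away from the inside corners of the tetrahedron).

namespace {

struct MCState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

inline uint64_t edge_key(uint64_t a, uint64_t b) {
  if (a > b) std::swap(a, b);
  return a * 0x100000000ULL + b;  // node ids < 2^32
}

// crossing on grid edge between nodes na, nb (world coords pa/pb, values va/vb)
inline int crossing_vertex(MCState &st, uint64_t na, uint64_t nb,
                           const double *pa, const double *pb,
                           double va, double vb, double iso) {
  uint64_t key = edge_key(na, nb);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double denom = vb - va;
  double t = (std::abs(denom) < 1e-300) ? 0.5 : (iso - va) / denom;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = (int)st.vx.size();
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  st.edge_vertex[key] = id;
  return id;
}

inline void emit_triangle(MCState &st, int a, int b, int c,
                          const double inside_centroid[3]) {
  // orient so the normal points away from the inside of the tetrahedron
  double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
  double nx = uy * wz - uz * wy;
  double ny = uz * wx - ux * wz;
  double nz = ux * wy - uy * wx;
  double cx = (ax + st.vx[b] + st.vx[c]) / 3.0;
  double cy = (ay + st.vy[b] + st.vy[c]) / 3.0;
  double cz = (az + st.vz[b] + st.vz[c]) / 3.0;
  double d = nx * (inside_centroid[0] - cx) + ny * (inside_centroid[1] - cy) +
             nz * (inside_centroid[2] - cz);
  if (d > 0) std::swap(b, c);
  st.f0.push_back(a);
  st.f1.push_back(b);
  st.f2.push_back(c);
}

}  // namespace

// [[Rcpp::export(name = ".mtSurface")]]
List mtSurface(NumericVector values, IntegerVector dims, NumericVector spacing,
               NumericVector origin, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double *v = REAL(values);

  // cube corner offsets (standard ordering)
  static const int CO[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // six tetrahedra around the main diagonal c0-c6
  static const int TETS[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};

  MCState st;
  double pos[8][3];
  double val[8];
  uint64_t nid[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CO[c][0], jj = j + CO[c][1], kk = k + CO[c][2];
          uint64_t idx = (uint64_t)ii + (uint64_t)nx * ((uint64_t)jj + (uint64_t)ny * kk);
          nid[c] = idx;
          val[c] = v[idx];
          pos[c][0] = ox + ii * sx;
          pos[c][1] = oy + jj * sy;
          pos[c][2] = oz + kk * sz;
          if (val[c] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int in_idx[4], out_idx[4];
          int nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[T[c]] >= iso) in_idx[nin++] = T[c];
            else out_idx[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          double ic[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) ic[d] += pos[in_idx[c]][d] / nin;
          if (nin == 1) {
            int a = in_idx[0];
            int e0 = crossing_vertex(st, nid[a], nid[out_idx[0]], pos[a], pos[out_idx[0]], val[a], val[out_idx[0]], iso);
            int e1 = crossing_vertex(st, nid[a], nid[out_idx[1]], pos[a], pos[out_idx[1]], val[a], val[out_idx[1]], iso);
            int e2 = crossing_vertex(st, nid[a], nid[out_idx[2]], pos[a], pos[out_idx[2]], val[a], val[out_idx[2]], iso);
            emit_triangle(st, e0, e1, e2, ic);
          } else if (nin == 3) {
            int a = out_idx[0];
            int e0 = crossing_vertex(st, nid[a], nid[in_idx[0]], pos[a], pos[in_idx[0]], val[a], val[in_idx[0]], iso);
            int e1 = crossing_vertex(st, nid[a], nid[in_idx[1]], pos[a], pos[in_idx[1]], val[a], val[in_idx[1]], iso);
            int e2 = crossing_vertex(st, nid[a], nid[in_idx[2]], pos[a], pos[in_idx[2]], val[a], val[in_idx[2]], iso);
            emit_triangle(st, e0, e1, e2, ic);
          } else {  // nin == 2: quad, split into two triangles
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int eAC = crossing_vertex(st, nid[A], nid[C], pos[A], pos[C], val[A], val[C], iso);
            int eAD = crossing_vertex(st, nid[A], nid[D], pos[A], pos[D], val[A], val[D], iso);
            int eBD = crossing_vertex(st, nid[B], nid[D], pos[B], pos[D], val[B], val[D], iso);
            int eBC = crossing_vertex(st, nid[B], nid[C], pos[B], pos[C], val[B], val[C], iso);
            emit_triangle(st, eAC, eAD, eBD, ic);
            emit_triangle(st, eAC, eBD, eBC, ic);
          }
        }
      }
    }
  }

  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i];
    V(i, 1) = st.vy[i];
    V(i, 2) = st.vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.f0[i] + 1;  // 1-based for R
    F(i, 1) = st.f1[i] + 1;
    F(i, 2) = st.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
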