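#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Iterative isotropic remeshing (split long edges, collapse short edges,
// flip for valence regularity, tangential relaxation with projection back
// onto the input surface).  Operates on closed orientable manifold meshes.

namespace remeshns {

typedef std::array<double, 3> Vec3;
typedef std::array<int, 3> Tri;

inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return {a[0]-b[0], a[1]-b[1], a[2]-b[2]}; }
inline Vec3 add(const Vec3 &a, const Vec3 &b) { return {a[0]+b[0], a[1]+b[1], a[2]+b[2]}; }
inline Vec3 mul(const Vec3 &a, double s) { return {a[0]*s, a[1]*s, a[2]*s}; }
inline double dot(const Vec3 &a, const Vec3 &b) { return a[0]*b[0]+a[1]*b[1]+a[2]*b[2]; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a[1]*b[2]-a[2]*b[1], a[2]*b[0]-a[0]*b[2], a[0]*b[1]-a[1]*b[0]};
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }
inline double dist(const Vec3 &a, const Vec3 &b) { return norm(sub(a, b)); }

inline uint64_t ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (uint64_t)a * 0x100000000ULL + (uint64_t)b;
}

// ---- closest point on triangle (for surface projection) ----
inline void closest_on_tri(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                           const Vec3 &c, Vec3 &out) {
  Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { out = a; return; }
  Vec3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { out = b; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) { out = add(a, mul(ab, d1/(d1-d3))); return; }
  Vec3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { out = c; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) { out = add(a, mul(ac, d2/(d2-d6))); return; }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0) {
    double w = (d4-d3)/((d4-d3)+(d5-d6));
    out = add(b, mul(sub(c, b), w));
    return;
  }
  double denom = 1.0/(va+vb+vc);
  out = add(a, add(mul(ab, vb*denom), mul(ac, vc*denom)));
}

struct SurfaceLocator {
  std::vector<Vec3> V;
  std::vector<Tri> F;
  std::vector<Vec3> C;  // centroids
  double minb[3], cell, max_spread;
  int dims[3];
  std::vector<std::vector<int>> buckets;

  void build(const NumericMatrix &Vm, const IntegerMatrix &Fm) {
    int nv = Vm.nrow(), nf = Fm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = {Vm(i,0), Vm(i,1), Vm(i,2)};
    F.resize(nf);
    C.resize(nf);
    double mean_edge = 0;
    for (int f = 0; f < nf; ++f) {
      F[f] = {Fm(f,0)-1, Fm(f,1)-1, Fm(f,2)-1};
      C[f] = mul(add(add(V[F[f][0]], V[F[f][1]]), V[F[f][2]]), 1.0/3.0);
      mean_edge += dist(V[F[f][0]], V[F[f][1]]);
    }
    mean_edge /= std::max(1, nf);
    cell = std::max(mean_edge * 2.0, 1e-9);
    double mx[3];
    for (int d = 0; d < 3; ++d) { minb[d] = R_PosInf; mx[d] = R_NegInf; }
    for (int f = 0; f < nf; ++f)
      for (int d = 0; d < 3; ++d) {
        minb[d] = std::min(minb[d], C[f][d]);
        mx[d] = std::max(mx[d], C[f][d]);
      }
    for (int d = 0; d < 3; ++d) {
      minb[d] -= 1e-9;
      dims[d] = std::max(1, (int)std::floor((mx[d]-minb[d])/cell) + 1);
    }
    buckets.assign((size_t)dims[0]*dims[1]*dims[2], {});
    max_spread = 0;
    for (int f = 0; f < nf; ++f) {
      int c[3];
      for (int d = 0; d < 3; ++d)
        c[d] = std::min(dims[d]-1, std::max(0, (int)std::floor((C[f][d]-minb[d])/cell)));
      buckets[c[0] + dims[0]*(c[1] + dims[1]*c[2])].push_back(f);
      for (int v = 0; v < 3; ++v)
        max_spread = std::max(max_spread, dist(V[F[f][v]], C[f]));
    }
  }

  Vec3 project(const Vec3 &p) const {
    int c[3];
    for (int d = 0; d < 3; ++d)
      c[d] = std::min(dims[d]-1, std::max(0, (int)std::floor((p[d]-minb[d])/cell)));
    double best = std::numeric_limits<double>::infinity();
    Vec3 best_pt = p;
    int maxdim = std::max({dims[0], dims[1], dims[2]}) + 2;
    for (int r = 0; r <= maxdim; ++r) {
      for (int dk = -r; dk <= r; ++dk) {
        int k = c[2]+dk;
        if (k < 0 || k >= dims[2]) continue;
        for (int dj = -r; dj <= r; ++dj) {
          int j = c[1]+dj;
          if (j < 0 || j >= dims[1]) continue;
          for (int di = -r; di <= r; ++di) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != r) continue;
            int i = c[0]+di;
            if (i < 0 || i >= dims[0]) continue;
            const std::vector<int> &bkt = buckets[i + dims[0]*(j + dims[1]*k)];
            for (int f : bkt) {
              Vec3 pt;
              closest_on_tri(p, V[F[f][0]], V[F[f][1]], V[F[f][2]], pt);
              double d2 = dot(sub(pt, p), sub(pt, p));
              if (d2 < best) { best = d2; best_pt = pt; }
            }
          }
        }
      }
      double ring_min = (double)r * cell - max_spread;
      if (best < std::numeric_limits<double>::infinity() && ring_min > 0 &&
          ring_min*ring_min > best)
        break;
    }
    return best_pt;
  }
};

struct Mesh {
  std::vector<Vec3> V;
  std::vector<Tri> F;            // F[i][0] == -1 means dead
  std::vector<std::vector<int>> vf;  // vertex -> incident alive faces

  void init(const NumericMatrix &Vm, const IntegerMatrix &Fm) {
    int nv = Vm.nrow(), nf = Fm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = {Vm(i,0), Vm(i,1), Vm(i,2)};
    F.resize(nf);
    vf.assign(nv, {});
    for (int f = 0; f < nf; ++f) {
      F[f] = {Fm(f,0)-1, Fm(f,1)-1, Fm(f,2)-1};
      for (int v = 0; v < 3; ++v) vf[F[f][v]].push_back(f);
    }
  }

  bool alive(int f) const { return F[f][0] >= 0; }

  void kill_face(int f) {
    for (int v = 0; v < 3; ++v) {
      std::vector<int> &l = vf[F[f][v]];
      l.erase(std::remove(l.begin(), l.end(), f), l.end());
    }
    F[f] = {-1, -1, -1};
  }

  int add_face(int a, int b, int c) {
    int id = (int)F.size();
    F.push_back({a, b, c});
    vf[a].push_back(id);
    vf[b].push_back(id);
    vf[c].push_back(id);
    return id;
  }

  int add_vertex(const Vec3 &p) {
    V.push_back(p);
    vf.push_back({});
    return (int)V.size() - 1;
  }

  // faces containing both a and b
  void edge_faces(int a, int b, std::vector<int> &out) const {
    out.clear();
    for (int f : vf[a]) {
      const Tri &t = F[f];
      if (t[0] == b || t[1] == b || t[2] == b) out.push_back(f);
    }
  }

  void neighbors(int v, std::unordered_set<int> &out) const {
    out.clear();
    for (int f : vf[v]) {
      for (int k = 0; k < 3; ++k)
        if (F[f][k] != v) out.insert(F[f][k]);
    }
  }

  Vec3 face_normal(int f) const {
    const Tri &t = F[f];
    return cross(sub(V[t[1]], V[t[0]]), sub(V[t[2]], V[t[0]]));
  }

  int valence(int v) const { return (int)vf[v].size(); }
};

void collect_edges(const Mesh &m, std::vector<std::pair<int,int>> &edges) {
  edges.clear();
  std::unordered_set<uint64_t> seen;
  seen.reserve(m.F.size() * 2);
  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.alive((int)f)) continue;
    const Tri &t = m.F[f];
    for (int k = 0; k < 3; ++k) {
      int a = t[k], b = t[(k+1)%3];
      uint64_t key = ekey(a, b);
      if (seen.insert(key).second) edges.push_back({std::min(a,b), std::max(a,b)});
    }
  }
}

void split_pass(Mesh &m, double high) {
  for (int sweep = 0; sweep < 10; ++sweep) {
    std::vector<std::pair<int,int>> edges;
    collect_edges(m, edges);
    std::vector<std::pair<double, size_t>> longe;
    for (size_t e = 0; e < edges.size(); ++e) {
      double L = dist(m.V[edges[e].first], m.V[edges[e].second]);
      if (L > high) longe.push_back({-L, e});
    }
    if (longe.empty()) return;
    std::sort(longe.begin(), longe.end());
    for (auto &pr : longe) {
      int a = edges[pr.second].first, b = edges[pr.second].second;
      if (dist(m.V[a], m.V[b]) <= high) continue;  // geometry changed
      std::vector<int> fs;
      m.edge_faces(a, b, fs);
      if (fs.empty()) continue;
      int mid = m.add_vertex(mul(add(m.V[a], m.V[b]), 0.5));
      for (int f : fs) {
        Tri t = m.F[f];
        m.kill_face(f);
        // preserve cyclic orientation: find position of a then b
        int ia = (t[0]==a) ? 0 : (t[1]==a ? 1 : 2);
        int c;
        if (t[(ia+1)%3] == b) {  // order a -> b -> c
          c = t[(ia+2)%3];
          m.add_face(a, mid, c);
          m.add_face(mid, b, c);
        } else {                  // order b -> a -> c (i.e. a -> c -> b)
          c = t[(ia+1)%3];
          m.add_face(b, mid, c);
          m.add_face(mid, a, c);
        }
      }
    }
  }
}

void collapse_pass(Mesh &m, double low, double high) {
  std::vector<std::pair<int,int>> edges;
  collect_edges(m, edges);
  std::vector<std::pair<double, size_t>> shorte;
  for (size_t e = 0; e < edges.size(); ++e) {
    double L = dist(m.V[edges[e].first], m.V[edges[e].second]);
    if (L < low) shorte.push_back({L, e});
  }
  std::sort(shorte.begin(), shorte.end());
  std::unordered_set<int> touched;
  for (auto &pr : shorte) {
    int a = edges[pr.second].first, b = edges[pr.second].second;
    if (touched.count(a) || touched.count(b)) continue;
    if (m.vf[a].empty() || m.vf[b].empty()) continue;
    double L = dist(m.V[a], m.V[b]);
    if (L >= low) continue;
    std::vector<int> fs;
    m.edge_faces(a, b, fs);
    if (fs.size() != 2) continue;  // boundary or non-manifold: leave alone
    // link condition: common neighborhood must be exactly the two opposite verts
    std::unordered_set<int> na, nb;
    m.neighbors(a, na);
    m.neighbors(b, nb);
    int common = 0;
    for (int v : na) if (nb.count(v)) ++common;
    if (common != 2) continue;
    Vec3 mid = mul(add(m.V[a], m.V[b]), 0.5);
    // don't create overlong edges
    bool bad = false;
    for (int v : na) if (v != b && dist(mid, m.V[v]) > high) { bad = true; break; }
    if (!bad) for (int v : nb) if (v != a && dist(mid, m.V[v]) > high) { bad = true; break; }
    if (bad) continue;
    // don't flip any surviving face
    Vec3 olda = m.V[a], oldb = m.V[b];
    for (int v : {a, b}) {
      for (int f : m.vf[v]) {
        if (f == fs[0] || f == fs[1]) continue;
        Vec3 n0 = m.face_normal(f);
        Tri t = m.F[f];
        Vec3 p[3];
        for (int k = 0; k < 3; ++k)
          p[k] = (t[k] == a || t[k] == b) ? mid : m.V[t[k]];
        Vec3 n1 = cross(sub(p[1], p[0]), sub(p[2], p[0]));
        if (dot(n0, n1) <= 1e-12 * norm(n0) * norm(n1)) { bad = true; break; }
      }
      if (bad) break;
    }
    if (bad) continue;
    // execute: merge b into a at midpoint
    m.V[a] = mid;
    m.kill_face(fs[0]);
    m.kill_face(fs[1]);
    std::vector<int> bfaces = m.vf[b];
    for (int f : bfaces) {
      Tri &t = m.F[f];
      for (int k = 0; k < 3; ++k)
        if (t[k] == b) t[k] = a;
      m.vf[a].push_back(f);
    }
    m.vf[b].clear();
    touched.insert(a);
    touched.insert(b);
    (void)olda; (void)oldb;
  }
}

void flip_pass(Mesh &m) {
  std::vector<std::pair<int,int>> edges;
  collect_edges(m, edges);
  for (auto &e : edges) {
    int a = e.first, b = e.second;
    std::vector<int> fs;
    m.edge_faces(a, b, fs);
    if (fs.size() != 2) continue;
    // opposite vertices
    int c = -1, d = -1, f1 = -1, f2 = -1;
    for (int f : fs) {
      const Tri &t = m.F[f];
      int other = t[0] + t[1] + t[2] - a - b;
      // orientation: does f traverse a->b or b->a?
      bool ab = false;
      for (int k = 0; k < 3; ++k)
        if (t[k] == a && t[(k+1)%3] == b) ab = true;
      if (ab) { c = other; f1 = f; } else { d = other; f2 = f; }
    }
    if (c < 0 || d < 0 || c == d) continue;
    // would the flipped edge already exist?
    std::unordered_set<int> nc;
    m.neighbors(c, nc);
    if (nc.count(d)) continue;
    int va = m.valence(a), vb = m.valence(b), vc = m.valence(c), vd = m.valence(d);
    auto dev = [](int v) { return (v - 6) * (v - 6); };
    int before = dev(va) + dev(vb) + dev(vc) + dev(vd);
    int after = dev(va-1) + dev(vb-1) + dev(vc+1) + dev(vd+1);
    if (after >= before) continue;
    if (va <= 3 || vb <= 3) continue;
    // geometric sanity: new faces must roughly agree with old normals
    Vec3 n_old = add(m.face_normal(f1), m.face_normal(f2));
    Vec3 nA = cross(sub(m.V[d], m.V[a]), sub(m.V[c], m.V[a]));
    Vec3 nB = cross(sub(m.V[b], m.V[d]), sub(m.V[c], m.V[d]));
    double s = norm(n_old);
    if (dot(n_old, nA) <= 1e-10 * s * norm(nA) || dot(n_old, nB) <= 1e-10 * s * norm(nB))
      continue;
    m.kill_face(f1);
    m.kill_face(f2);
    m.add_face(a, d, c);
    m.add_face(d, b, c);
  }
}

void relax_pass(Mesh &m, const SurfaceLocator &loc, double lambda) {
  int nv = (int)m.V.size();
  std::vector<Vec3> normals(nv, {0, 0, 0});
  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.alive((int)f)) continue;
    Vec3 n = m.face_normal((int)f);
    for (int k = 0; k < 3; ++k) normals[m.F[f][k]] = add(normals[m.F[f][k]], n);
  }
  std::vector<Vec3> newV = m.V;
  std::unordered_set<int> nb;
  for (int v = 0; v < nv; ++v) {
    if (m.vf[v].empty()) continue;
    m.neighbors(v, nb);
    if (nb.empty()) continue;
    Vec3 cen = {0, 0, 0};
    for (int u : nb) cen = add(cen, m.V[u]);
    cen = mul(cen, 1.0 / nb.size());
    Vec3 n = normals[v];
    double nn = norm(n);
    Vec3 disp = sub(cen, m.V[v]);
    if (nn > 1e-300) {
      n = mul(n, 1.0 / nn);
      disp = sub(disp, mul(n, dot(disp, n)));  // tangential component only
    }
    Vec3 moved = add(m.V[v], mul(disp, lambda));
    newV[v] = loc.project(moved);
  }
  m.V = newV;
}

}  // namespace remeshns

// [[Rcpp::export(name = ".isotropicRemesh")]]
List isotropicRemesh(NumericMatrix Vm, IntegerMatrix Fm, double target_edge,
                     int iterations, double lambda) {
  using namespace remeshns;
  SurfaceLocator loc;
  loc.build(Vm, Fm);
  Mesh m;
  m.init(Vm, Fm);
  double high = 4.0 / 3.0 * target_edge;
  double low = 4.0 / 5.0 * target_edge;
  for (int it = 0; it < iterations; ++it) {
    split_pass(m, high);
    collapse_pass(m, low, high);
    flip_pass(m);
    relax_pass(m, loc, lambda);
  }
  // compact
  int nv = (int)m.V.size();
  std::vector<int> vmap(nv, -1);
  std::vector<int> keepf;
  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.alive((int)f)) continue;
    keepf.push_back((int)f);
    for (int k = 0; k < 3; ++k) vmap[m.F[f][k]] = 0;
  }
  int nn = 0;
  for (int v = 0; v < nv; ++v)
    if (vmap[v] == 0) vmap[v] = nn++;
  NumericMatrix Vout(nn, 3);
  for (int v = 0; v < nv; ++v)
    if (vmap[v] >= 0)
      for (int d = 0; d < 3; ++d) Vout(vmap[v], d) = m.V[v][d];
  IntegerMatrix Fout((int)keepf.size(), 3);
  for (size_t i = 0; i < keepf.size(); ++i)
    for (int k = 0; k < 3; ++k) Fout((int)i, k) = vmap[m.F[keepf[i]][k]] + 1;
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
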