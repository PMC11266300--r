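#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Uniform-grid spatial queries: exact nearest vertex (ties broken by lowest
// index, matching a brute-force scan) and closest point on a triangle soup.

namespace {

struct UniformGrid {
  double minb[3], cell;
  int dims[3];
  std::vector<std::vector<int>> buckets;

  int clampi(int v, int lo, int hi) const { return v < lo ? lo : (v > hi ? hi : v); }

  int cell_index(double x, double y, double z, int *c) const {
    c[0] = clampi((int)std::floor((x - minb[0]) / cell), 0, dims[0] - 1);
    c[1] = clampi((int)std::floor((y - minb[1]) / cell), 0, dims[1] - 1);
    c[2] = clampi((int)std::floor((z - minb[2]) / cell), 0, dims[2] - 1);
    return c[0] + dims[0] * (c[1] + dims[1] * c[2]);
  }

  // minimal squared distance from point p to cell (i,j,k)'s box
  double box_dist2(const double *p, int i, int j, int k) const {
    double d2 = 0;
    const int c[3] = {i, j, k};
    for (int d = 0; d < 3; ++d) {
      double lo = minb[d] + c[d] * cell, hi = lo + cell;
      double v = p[d] < lo ? lo - p[d] : (p[d] > hi ? p[d] - hi : 0.0);
      d2 += v * v;
    }
    return d2;
  }
};

void build_grid(UniformGrid &g, const NumericMatrix &P, double cell) {
  int n = P.nrow();
  double maxb[3];
  for (int d = 0; d < 3; ++d) { g.minb[d] = R_PosInf; maxb[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      g.minb[d] = std::min(g.minb[d], P(i, d));
      maxb[d] = std::max(maxb[d], P(i, d));
    }
  g.cell = cell;
  for (int d = 0; d < 3; ++d) {
    g.minb[d] -= 1e-9;
    g.dims[d] = std::max(1, (int)std::floor((maxb[d] - g.minb[d]) / cell) + 1);
  }
  g.buckets.assign((size_t)g.dims[0] * g.dims[1] * g.dims[2], {});
  int c[3];
  for (int i = 0; i < n; ++i)
    g.buckets[g.cell_index(P(i, 0), P(i, 1), P(i, 2), c)].push_back(i);
}

// closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
void closest_on_triangle(const double *p, const double *a, const double *b,
                         const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) { ab[d] = b[d] - a[d]; ac[d] = c[d] - a[d]; ap[d] = p[d] - a[d]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int d=0;d<3;++d) out[d]=a[d]; return; }
  double bp[3]; for (int d=0;d<3;++d) bp[d]=p[d]-b[d];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int d=0;d<3;++d) out[d]=b[d]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int d=0;d<3;++d) out[d]=a[d]+v*ab[d];
    return;
  }
  double cp[3]; for (int d=0;d<3;++d) cp[d]=p[d]-c[d];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int d=0;d<3;++d) out[d]=c[d]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int d=0;d<3;++d) out[d]=a[d]+w*ac[d];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int d=0;d<3;++d) out[d]=b[d]+w*(c[d]-b[d]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int d=0;d<3;++d) out[d]=a[d]+v*ab[d]+w*ac[d];
}

}  // namespace

// [[Rcpp::export(name = ".nearestVertex")]]
IntegerVector nearestVertex(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector out(nq);
  if (nr == 0) stop("reference point set is empty");
  // cell size: aim for a handful of points per cell
  double span = 0;
  {
    double mn[3] = {R_PosInf, R_PosInf, R_PosInf}, mx[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < nr; ++i)
      for (int d = 0; d < 3; ++d) {
        mn[d] = std::min(mn[d], ref(i, d));
        mx[d] = std::max(mx[d], ref(i, d));
      }
    span = std::max({mx[0] - mn[0], mx[1] - mn[1], mx[2] - mn[2], 1e-9});
  }
  double cell = std::max(span / std::max(4.0, std::cbrt((double)nr)), span * 1e-6);
  UniformGrid g;
  build_grid(g, ref, cell);

  int maxdim = std::max({g.dims[0], g.dims[1], g.dims[2]});
  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    int c[3];
    g.cell_index(p[0], p[1], p[2], c);
    double best = std::numeric_limits<double>::infinity();
    int best_idx = -1;
    for (int r = 0; r <= maxdim; ++r) {
      // cells at Chebyshev distance exactly r from c
      bool any_cell = false;
      for (int dk = -r; dk <= r; ++dk) {
        int k = c[2] + dk;
        if (k < 0 || k >= g.dims[2]) continue;
        for (int dj = -r; dj <= r; ++dj) {
          int j = c[1] + dj;
          if (j < 0 || j >= g.dims[1]) continue;
          for (int di = -r; di <= r; ++di) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != r) continue;
            int i = c[0] + di;
            if (i < 0 || i >= g.dims[0]) continue;
            any_cell = true;
            if (g.box_dist2(p, i, j, k) > best) continue;
            const std::vector<int> &b = g.buckets[i + g.dims[0] * (j + g.dims[1] * k)];
            for (int idx : b) {
              double dx = ref(idx, 0) - p[0], dy = ref(idx, 1) - p[1], dz = ref(idx, 2) - p[2];
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best || (d2 == best && idx < best_idx)) {
                best = d2;
                best_idx = idx;
              }
            }
          }
        }
      }
      // cells at Chebyshev distance >= r+1 are at Euclidean distance >= r*cell
      if (best_idx >= 0 && best < (double)r * g.cell * (double)r * g.cell) break;
      if (!any_cell && r > maxdim) break;
    }
    out[q] = best_idx + 1;  // 1-based
  }
  return out;
}

// [[Rcpp::export(name = ".closestOnSurface")]]
List closestOnSurface(NumericMatrix query, NumericMatrix V, IntegerMatrix F) {
  int nq = query.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  // grid over triangle centroids; cell ~ typical triangle size
  NumericMatrix C(nf, 3);
  double mean_edge = 0;
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    for (int d = 0; d < 3; ++d) C(f, d) = (V(a, d) + V(b, d) + V(c, d)) / 3.0;
    double e = 0;
    for (int d = 0; d < 3; ++d) {
      double u = V(a, d) - V(b, d);
      e += u * u;
    }
    mean_edge += std::sqrt(e);
  }
  mean_edge /= nf;
  double cell = std::max(mean_edge * 2.0, 1e-9);
  UniformGrid g;
  build_grid(g, C, cell);
  // max distance from a triangle point to its centroid, per bucket entry,
  // bounded globally for a conservative search radius
  double max_spread = 0;
  for (int f = 0; f < nf; ++f) {
    for (int v = 0; v < 3; ++v) {
      int idx = F(f, v) - 1;
      double d2 = 0;
      for (int d = 0; d < 3; ++d) {
        double u = V(idx, d) - C(f, d);
        d2 += u * u;
      }
      max_spread = std::max(max_spread, std::sqrt(d2));
    }
  }

  NumericMatrix P(nq, 3);
  NumericVector D(nq);
  IntegerVector FI(nq);
  int maxdim = std::max({g.dims[0], g.dims[1], g.dims[2]}) + 2;

  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    int c[3];
    g.cell_index(p[0], p[1], p[2], c);
    double best = std::numeric_limits<double>::infinity();
    int best_f = -1;
    double best_pt[3] = {0, 0, 0};
    for (int r = 0; r <= maxdim; ++r) {
      for (int dk = -r; dk <= r; ++dk) {
        int k = c[2] + dk;
        if (k < 0 || k >= g.dims[2]) continue;
        for (int dj = -r; dj <= r; ++dj) {
          int j = c[1] + dj;
          if (j < 0 || j >= g.dims[1]) continue;
          for (int di = -r; di <= r; ++di) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != r) continue;
            int i = c[0] + di;
            if (i < 0 || i >= g.dims[0]) continue;
            double bd = std::sqrt(g.box_dist2(p, i, j, k)) - max_spread;
            if (best_f >= 0 && bd > 0 && bd * bd > best) continue;
            const std::vector<int> &bkt = g.buckets[i + g.dims[0] * (j + g.dims[1] * k)];
            for (int f : bkt) {
              int a = F(f, 0) - 1, b = F(f, 1) - 1, cc = F(f, 2) - 1;
              double va[3] = {V(a, 0), V(a, 1), V(a, 2)};
              double vb[3] = {V(b, 0), V(b, 1), V(b, 2)};
              double vc[3] = {V(cc, 0), V(cc, 1), V(cc, 2)};
              double pt[3];
              closest_on_triangle(p, va, vb, vc, pt);
              double d2 = 0;
              for (int d = 0; d < 3; ++d) {
                double u = pt[d] - p[d];
                d2 += u * u;
              }
              if (d2 < best || (d2 == best && f < best_f)) {
                best = d2;
                best_f = f;
                for (int d = 0; d < 3; ++d) best_pt[d] = pt[d];
              }
            }
          }
        }
      }
      double ring_min = (double)r * g.cell - max_spread;
      if (best_f >= 0 && ring_min > 0 && ring_min * ring_min > best) break;
    }
    for (int d = 0; d < 3; ++d) P(q, d) = best_pt[d];
    D[q] = std::sqrt(best);
    FI[q] = best_f + 1;
  }
  return List::create(_["points"] = P, _["distance"] = D, _["face"] = FI);
}
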