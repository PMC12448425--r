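#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Cube corner offsets: corner i at (i&1, i>>1&1, i>>2&1).
static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
};
// Edge e (0-based) -> lower corner id and axis; matches mc_edges() in R:
// x-axis edges from corners 0,2,4,6; y from 0,1,4,5; z from 0,1,2,3.
static const int EDGE_BASE[12] = {0,2,4,6, 0,1,4,5, 0,1,2,3};
static const int EDGE_AXIS[12] = {0,0,0,0, 1,1,1,1, 2,2,2,2};

// [[Rcpp::export]]
List mc_extract(NumericVector field, double iso, List table) {
  IntegerVector dims = field.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = REAL(field);

  // pre-flatten the case table
  std::vector< std::vector<int> > tab(256);
  for (int c = 0; c < 256; ++c) {
    IntegerVector tv = table[c];
    tab[c].assign(tv.begin(), tv.end());
  }

  std::unordered_map<int64_t, int> vert_id;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto val = [&](int i, int j, int k) {
    return f[(size_t)k * nx * ny + (size_t)j * nx + i];
  };

  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        int config = 0;
        for (int c = 0; c < 8; ++c) {
          if (val(i + CORNER[c][0], j + CORNER[c][1], k + CORNER[c][2]) > iso)
            config |= (1 << c);
        }
        if (config == 0 || config == 255) continue;
        const std::vector<int> &loops = tab[config];
        // resolve (or create) the shared vertex on one cube edge
        auto edge_vertex = [&](int e) {
          int bc = EDGE_BASE[e], ax = EDGE_AXIS[e];
          int bx = i + CORNER[bc][0], by = j + CORNER[bc][1], bz = k + CORNER[bc][2];
          int64_t key = (((int64_t)bz * ny + by) * nx + bx) * 3 + ax;
          auto it = vert_id.find(key);
          if (it != vert_id.end()) return it->second;
          double v0 = val(bx, by, bz);
          double v1 = val(bx + (ax == 0), by + (ax == 1), bz + (ax == 2));
          double tt = (iso - v0) / (v1 - v0);
          vx.push_back(bx + (ax == 0 ? tt : 0.0));
          vy.push_back(by + (ax == 1 ? tt : 0.0));
          vz.push_back(bz + (ax == 2 ? tt : 0.0));
          int id = (int)vx.size() - 1;
          vert_id.emplace(key, id);
          return id;
        };
        size_t pos = 0;
        while (pos < loops.size()) {
          int klen = loops[pos++];
          std::vector<int> ids(klen);
          for (int q = 0; q < klen; ++q) ids[q] = edge_vertex(loops[pos + q] - 1);
          pos += klen;
          if (klen == 3) {
            tri.push_back(ids[0] + 1); tri.push_back(ids[1] + 1); tri.push_back(ids[2] + 1);
          } else {
            // centroid fan: the centroid is strictly interior to the cube
            double cxm = 0, cym = 0, czm = 0;
            for (int q = 0; q < klen; ++q) {
              cxm += vx[ids[q]]; cym += vy[ids[q]]; czm += vz[ids[q]];
            }
            vx.push_back(cxm / klen); vy.push_back(cym / klen); vz.push_back(czm / klen);
            int cid = (int)vx.size() - 1;
            for (int q = 0; q < klen; ++q) {
              int r = (q + 1) % klen;
              tri.push_back(cid + 1); tri.push_back(ids[q] + 1); tri.push_back(ids[r] + 1);
            }
          }
        }
      }
    }
  }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  IntegerMatrix faces(nt, 3);
  for (int t = 0; t < nt; ++t) {
    faces(t, 0) = tri[3 * t]; faces(t, 1) = tri[3 * t + 1]; faces(t, 2) = tri[3 * t + 2];
  }
  return List::create(_["vertices"] = verts, _["triangles"] = faces);
}

// Separable 1D convolution along one axis with zero extension.
// [[Rcpp::export]]
NumericVector convolve_axis(NumericVector field, NumericVector kernel, int axis) {
  IntegerVector dims = field.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = ((int)kernel.size() - 1) / 2;
  NumericVector out(field.size());
  out.attr("dim") = dims;
  const double *f = REAL(field);
  const double *kk = REAL(kernel);
  double *o = REAL(out);
  const int step = (axis == 1) ? 1 : (axis == 2 ? nx : nx * ny);
  const int n_axis = (axis == 1) ? nx : (axis == 2 ? ny : nz);

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        size_t idx = (size_t)k * nx * ny + (size_t)j * nx + i;
        int pos = (axis == 1) ? i : (axis == 2 ? j : k);
        double s = 0.0;
        int tlo = std::max(-r, -pos), thi = std::min(r, n_axis - 1 - pos);
        for (int t = tlo; t <= thi; ++t) {
          s += kk[t + r] * f[idx + (ptrdiff_t)t * step];
        }
        o[idx] = s;
      }
    }
  }
  return out;
}

// Union-find over mesh vertices; returns a component label per vertex.
// [[Rcpp::export]]
IntegerVector mesh_components_cpp(IntegerMatrix faces, int nverts) {
  std::vector<int> parent(nverts);
  for (int i = 0; i < nverts; ++i) parent[i] = i;
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int x, int y) {
    x = find(x); y = find(y);
    if (x != y) parent[std::max(x, y)] = std::min(x, y);
  };
  for (int t = 0; t < faces.nrow(); ++t) {
    unite(faces(t, 0) - 1, faces(t, 1) - 1);
    unite(faces(t, 1) - 1, faces(t, 2) - 1);
  }
  IntegerVector comp(nverts);
  for (int i = 0; i < nverts; ++i) comp[i] = find(i) + 1;
  return comp;
}

// Squared distance from point p to triangle (a,b,c) - Ericson's
// closest-point construction.
static double pt_tri_dist2(const double p[3], const double a[3],
                           const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i]-a[i]; ac[i] = c[i]-a[i]; ap[i] = p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  auto dist2 = [&](double qx, double qy, double qz) {
    double dx = p[0]-qx, dy = p[1]-qy, dz = p[2]-qz;
    return dx*dx + dy*dy + dz*dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2(a[0], a[1], a[2]);
  double bp[3]; for (int i = 0; i < 3; ++i) bp[i] = p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2(b[0], b[1], b[2]);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return dist2(a[0]+v*ab[0], a[1]+v*ab[1], a[2]+v*ab[2]);
  }
  double cp[3]; for (int i = 0; i < 3; ++i) cp[i] = p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2(c[0], c[1], c[2]);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return dist2(a[0]+w*ac[0], a[1]+w*ac[1], a[2]+w*ac[2]);
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2(b[0]+w*(c[0]-b[0]), b[1]+w*(c[1]-b[1]), b[2]+w*(c[2]-b[2]));
  }
  double denom = va + vb + vc;
  double v = vb / denom, w = vc / denom;
  return dist2(a[0]+ab[0]*v+ac[0]*w, a[1]+ab[1]*v+ac[1]*w, a[2]+ab[2]*v+ac[2]*w);
}

// For each query point, is it within `tol` of the triangle mesh?
// Uniform-grid bucketing over the mesh bounding box keeps this near-linear.
// [[Rcpp::export]]
LogicalVector points_near_mesh(NumericMatrix points, NumericMatrix verts,
                               IntegerMatrix faces, double tol) {
  const int np = points.nrow(), nt = faces.nrow();
  LogicalVector out(np);
  if (nt == 0) return out;

  // mesh bbox and max triangle extent
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  double max_ext = 0.0;
  std::vector<double> tlo(3 * nt), thi(3 * nt);
  for (int t = 0; t < nt; ++t) {
    for (int d = 0; d < 3; ++d) {
      double m = R_PosInf, M = R_NegInf;
      for (int v = 0; v < 3; ++v) {
        double x = verts(faces(t, v) - 1, d);
        if (x < m) m = x;
        if (x > M) M = x;
      }
      tlo[3 * t + d] = m; thi[3 * t + d] = M;
      if (m < lo[d]) lo[d] = m;
      if (M > hi[d]) hi[d] = M;
      if (M - m > max_ext) max_ext = M - m;
    }
  }
  double h = std::max(2.0 * tol, max_ext);
  if (h <= 0) h = 1.0;
  int ncell[3];
  for (int d = 0; d < 3; ++d) {
    ncell[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
  }
  auto cell_of = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / h);
    if (c < 0) c = 0;
    if (c >= ncell[d]) c = ncell[d] - 1;
    return c;
  };
  std::unordered_map<int64_t, std::vector<int> > buckets;
  auto key_of = [&](int cx, int cy, int cz) {
    return ((int64_t)cz * ncell[1] + cy) * ncell[0] + cx;
  };
  for (int t = 0; t < nt; ++t) {
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = cell_of(tlo[3 * t + d], d);
      c1[d] = cell_of(thi[3 * t + d], d);
    }
    for (int cz = c0[2]; cz <= c1[2]; ++cz)
      for (int cy = c0[1]; cy <= c1[1]; ++cy)
        for (int cx = c0[0]; cx <= c1[0]; ++cx)
          buckets[key_of(cx, cy, cz)].push_back(t);
  }

  const double tol2 = tol * tol;
  double A[3], B[3], C[3], P[3];
  for (int p = 0; p < np; ++p) {
    P[0] = points(p, 0); P[1] = points(p, 1); P[2] = points(p, 2);
    int c0[3], c1[3];
    bool outside_far = false;
    for (int d = 0; d < 3; ++d) {
      if (P[d] < lo[d] - tol || P[d] > hi[d] + tol) { outside_far = true; break; }
      c0[d] = cell_of(P[d] - tol, d);
      c1[d] = cell_of(P[d] + tol, d);
    }
    if (outside_far) continue;
    bool hit = false;
    for (int cz = c0[2]; cz <= c1[2] && !hit; ++cz) {
      for (int cy = c0[1]; cy <= c1[1] && !hit; ++cy) {
        for (int cx = c0[0]; cx <= c1[0] && !hit; ++cx) {
          auto it = buckets.find(key_of(cx, cy, cz));
          if (it == buckets.end()) continue;
          for (int t : it->second) {
            // quick bbox rejection
            bool rej = false;
            for (int d = 0; d < 3; ++d) {
              if (P[d] < tlo[3 * t + d] - tol || P[d] > thi[3 * t + d] + tol) {
                rej = true; break;
              }
            }
            if (rej) continue;
            for (int d = 0; d < 3; ++d) {
              A[d] = verts(faces(t, 0) - 1, d);
              B[d] = verts(faces(t, 1) - 1, d);
              C[d] = verts(faces(t, 2) - 1, d);
            }
            if (pt_tri_dist2(P, A, B, C) <= tol2) { hit = true; break; }
          }
        }
      }
    }
    out[p] = hit;
  }
  return out;
}
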