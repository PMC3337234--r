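// Geometry kernels: even-odd slice rasterization, marching-tetrahedra
// iso-surfacing, and exact point-to-triangle-mesh distances.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Even-odd rasterization of one axial slice.
//
// A voxel centre is inside iff a ray cast in +x crosses the union of polygon
// edges an odd number of times. The half-open crossing rule
// ((yi > y) != (yj > y)) counts a point lying exactly on a "lower" edge as
// inside and on an "upper" edge as outside, which makes the fill
// deterministic for vertices and edges on voxel centres.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_slice(List polys, double ox, double oy,
                                  double dx, double dy, int nx, int ny) {
  LogicalVector out(static_cast<R_xlen_t>(nx) * ny, false);
  int np = polys.size();
  if (np == 0) return out;

  // bounding box over all polygons limits the scan
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  std::vector<NumericMatrix> ps;
  ps.reserve(np);
  for (int p = 0; p < np; ++p) {
    NumericMatrix m = polys[p];
    ps.push_back(m);
    for (int v = 0; v < m.nrow(); ++v) {
      xmin = std::min(xmin, m(v, 0)); xmax = std::max(xmax, m(v, 0));
      ymin = std::min(ymin, m(v, 1)); ymax = std::max(ymax, m(v, 1));
    }
  }
  int i0 = std::max(0, (int)std::ceil((xmin - ox) / dx - 1e-9));
  int i1 = std::min(nx - 1, (int)std::floor((xmax - ox) / dx + 1e-9));
  int j0 = std::max(0, (int)std::ceil((ymin - oy) / dy - 1e-9));
  int j1 = std::min(ny - 1, (int)std::floor((ymax - oy) / dy + 1e-9));

  for (int j = j0; j <= j1; ++j) {
    double y = oy + j * dy;
    for (int i = i0; i <= i1; ++i) {
      double x = ox + i * dx;
      bool inside = false;
      for (int p = 0; p < np; ++p) {
        const NumericMatrix &m = ps[p];
        int n = m.nrow();
        for (int a = 0, b = n - 1; a < n; b = a++) {
          double yi = m(a, 1), yj = m(b, 1);
          if ((yi > y) != (yj > y)) {
            double xi = m(a, 0), xj = m(b, 0);
            double xc = xi + (y - yi) / (yj - yi) * (xj - xi);
            if (x < xc) inside = !inside;
          }
        }
      }
      if (inside) out[(R_xlen_t)i + (R_xlen_t)nx * j] = true;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar field.
//
// Each grid cell is split into six tetrahedra sharing the cell's main
// diagonal; the decomposition is identical in every cell so shared cell
// faces carry the same face diagonal and the extracted surface is
// watertight. The field is virtually padded with zeros one layer outside
// the grid so that structures touching the border still close. Interior is
// strictly value > iso. Vertices are welded on lattice-edge keys.

struct MTAccum {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based triples
  std::unordered_map<uint64_t, int> edge_map;
};

static inline uint64_t corner_id(int i, int j, int k, int nx, int ny) {
  return (uint64_t)(i + 1) +
         (uint64_t)(nx + 2) * ((uint64_t)(j + 1) +
                               (uint64_t)(ny + 2) * (uint64_t)(k + 1));
}

static int edge_vertex(MTAccum &acc, uint64_t ida, uint64_t idb,
                       const double *pa, const double *pb,
                       double va, double vb, double iso, uint64_t nid) {
  uint64_t key = (ida < idb) ? ida * nid + idb : idb * nid + ida;
  auto it = acc.edge_map.find(key);
  if (it != acc.edge_map.end()) return it->second;
  double t = (vb == va) ? 0.5 : (iso - va) / (vb - va);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  acc.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  acc.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  acc.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int idx = (int)acc.vx.size() - 1;
  acc.edge_map.emplace(key, idx);
  return idx;
}

static void emit_tri(MTAccum &acc, int a, int b, int c, const double *ref) {
  // orient so the normal points away from the interior reference point
  double ax = acc.vx[a], ay = acc.vy[a], az = acc.vz[a];
  double ux = acc.vx[b] - ax, uy = acc.vy[b] - ay, uz = acc.vz[b] - az;
  double wx = acc.vx[c] - ax, wy = acc.vy[c] - ay, wz = acc.vz[c] - az;
  double nxv = uy * wz - uz * wy;
  double nyv = uz * wx - ux * wz;
  double nzv = ux * wy - uy * wx;
  double cx = (ax + acc.vx[b] + acc.vx[c]) / 3.0 - ref[0];
  double cy = (ay + acc.vy[b] + acc.vy[c]) / 3.0 - ref[1];
  double cz = (az + acc.vz[b] + acc.vz[c]) / 3.0 - ref[2];
  if (nxv * cx + nyv * cy + nzv * cz < 0.0) std::swap(b, c);
  acc.tri.push_back(a); acc.tri.push_back(b); acc.tri.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, int nx, int ny, int nz,
                        double ox, double oy, double oz,
                        double dx, double dy, double dz, double iso) {
  MTAccum acc;
  uint64_t nid = (uint64_t)(nx + 2) * (ny + 2) * (nz + 2) + 1;
  // cube corner offsets, bit order (x, y, z)
  static const int co[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                               {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // six tetrahedra around the 0-7 diagonal
  static const int tets[6][4] = {{0,1,3,7},{0,1,5,7},{0,2,3,7},
                                 {0,2,6,7},{0,4,5,7},{0,4,6,7}};
  double cv[8];
  double cp[8][3];
  uint64_t cid[8];

  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + co[c][0], cj = j + co[c][1], ck = k + co[c][2];
          double v = 0.0;
          if (ci >= 0 && ci < nx && cj >= 0 && cj < ny && ck >= 0 && ck < nz)
            v = field[(R_xlen_t)ci + (R_xlen_t)nx * (cj + (R_xlen_t)ny * ck)];
          cv[c] = v;
          cp[c][0] = ox + ci * dx;
          cp[c][1] = oy + cj * dy;
          cp[c][2] = oz + ck * dz;
          cid[c] = corner_id(ci, cj, ck, nx, ny);
          if (v > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[vi[c]] > iso) in_idx[nin++] = vi[c];
            else out_idx[nout++] = vi[c];
          }
          if (nin == 0 || nin == 4) continue;
          double ref[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c) {
            ref[0] += cp[in_idx[c]][0];
            ref[1] += cp[in_idx[c]][1];
            ref[2] += cp[in_idx[c]][2];
          }
          ref[0] /= nin; ref[1] /= nin; ref[2] /= nin;

          if (nin == 1) {
            int a = in_idx[0];
            int e0 = edge_vertex(acc, cid[a], cid[out_idx[0]], cp[a],
                                 cp[out_idx[0]], cv[a], cv[out_idx[0]], iso, nid);
            int e1 = edge_vertex(acc, cid[a], cid[out_idx[1]], cp[a],
                                 cp[out_idx[1]], cv[a], cv[out_idx[1]], iso, nid);
            int e2 = edge_vertex(acc, cid[a], cid[out_idx[2]], cp[a],
                                 cp[out_idx[2]], cv[a], cv[out_idx[2]], iso, nid);
            emit_tri(acc, e0, e1, e2, ref);
          } else if (nin == 3) {
            int a = out_idx[0];
            int e0 = edge_vertex(acc, cid[a], cid[in_idx[0]], cp[a],
                                 cp[in_idx[0]], cv[a], cv[in_idx[0]], iso, nid);
            int e1 = edge_vertex(acc, cid[a], cid[in_idx[1]], cp[a],
                                 cp[in_idx[1]], cv[a], cv[in_idx[1]], iso, nid);
            int e2 = edge_vertex(acc, cid[a], cid[in_idx[2]], cp[a],
                                 cp[in_idx[2]], cv[a], cv[in_idx[2]], iso, nid);
            emit_tri(acc, e0, e1, e2, ref);
          } else {  // nin == 2: quad split into two triangles
            int a = in_idx[0], b = in_idx[1];
            int c = out_idx[0], d = out_idx[1];
            int e0 = edge_vertex(acc, cid[a], cid[c], cp[a], cp[c], cv[a], cv[c], iso, nid);
            int e1 = edge_vertex(acc, cid[a], cid[d], cp[a], cp[d], cv[a], cv[d], iso, nid);
            int e2 = edge_vertex(acc, cid[b], cid[d], cp[b], cp[d], cv[b], cv[d], iso, nid);
            int e3 = edge_vertex(acc, cid[b], cid[c], cp[b], cp[c], cv[b], cv[c], iso, nid);
            emit_tri(acc, e0, e1, e2, ref);
            emit_tri(acc, e0, e2, e3, ref);
          }
        }
      }

  int nv = (int)acc.vx.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = acc.vx[v]; V(v, 1) = acc.vy[v]; V(v, 2) = acc.vz[v];
  }
  int nt = (int)acc.tri.size() / 3;
  IntegerMatrix F(nt, 3);
  for (int t = 0; t < nt; ++t) {
    F(t, 0) = acc.tri[3 * t] + 1;      // 1-based for R
    F(t, 1) = acc.tri[3 * t + 1] + 1;
    F(t, 2) = acc.tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// ---------------------------------------------------------------------------
// Unsigned distance from query points to a triangle mesh, via a uniform
// cubic-cell bin structure with ring-expansion search.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Ericson: closest point on triangle abc to point p; returns squared distance
static double pt_tri_d2(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { q[0]=a[0];q[1]=a[1];q[2]=a[2]; goto done; }
  {
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { q[0]=b[0];q[1]=b[1];q[2]=b[2]; goto done; }
    double vc = d1*d4 - d3*d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      double v = d1 / (d1 - d3);
      q[0]=a[0]+v*ab[0]; q[1]=a[1]+v*ab[1]; q[2]=a[2]+v*ab[2]; goto done;
    }
    double cpv[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
    double d5 = ab[0]*cpv[0]+ab[1]*cpv[1]+ab[2]*cpv[2];
    double d6 = ac[0]*cpv[0]+ac[1]*cpv[1]+ac[2]*cpv[2];
    if (d6 >= 0.0 && d5 <= d6) { q[0]=c[0];q[1]=c[1];q[2]=c[2]; goto done; }
    double vb = d5*d2 - d1*d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
      double w = d2 / (d2 - d6);
      q[0]=a[0]+w*ac[0]; q[1]=a[1]+w*ac[1]; q[2]=a[2]+w*ac[2]; goto done;
    }
    double va = d3*d6 - d5*d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      q[0]=b[0]+w*(c[0]-b[0]); q[1]=b[1]+w*(c[1]-b[1]); q[2]=b[2]+w*(c[2]-b[2]);
      goto done;
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    q[0]=a[0]+ab[0]*v+ac[0]*w; q[1]=a[1]+ab[1]*v+ac[1]*w; q[2]=a[2]+ab[2]*v+ac[2]*w;
  }
done:
  double dxv=p[0]-q[0], dyv=p[1]-q[1], dzv=p[2]-q[2];
  return dxv*dxv + dyv*dyv + dzv*dzv;
}

// [[Rcpp::export]]
NumericVector cpp_mesh_distance(NumericMatrix query, NumericMatrix V,
                                IntegerMatrix F, double cell) {
  int nq = query.nrow(), nt = F.nrow();
  NumericVector out(nq);
  if (nt == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int v = 0; v < V.nrow(); ++v)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], V(v, d));
      hi[d] = std::max(hi[d], V(v, d));
    }
  int nb[3];
  for (int d = 0; d < 3; ++d) {
    nb[d] = std::max(1, (int)std::ceil((hi[d] - lo[d]) / cell) + 1);
  }
  // CSR binning of triangles by bbox overlap
  R_xlen_t ncell = (R_xlen_t)nb[0] * nb[1] * nb[2];
  std::vector<int> counts(ncell, 0);
  std::vector<int> tmin(nt * 3), tmax(nt * 3);
  for (int t = 0; t < nt; ++t) {
    double bmin[3] = {R_PosInf, R_PosInf, R_PosInf};
    double bmax[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int c = 0; c < 3; ++c) {
      int v = F(t, c) - 1;
      for (int d = 0; d < 3; ++d) {
        bmin[d] = std::min(bmin[d], V(v, d));
        bmax[d] = std::max(bmax[d], V(v, d));
      }
    }
    for (int d = 0; d < 3; ++d) {
      int a = (int)clampd(std::floor((bmin[d] - lo[d]) / cell), 0, nb[d] - 1);
      int b = (int)clampd(std::floor((bmax[d] - lo[d]) / cell), 0, nb[d] - 1);
      tmin[t * 3 + d] = a; tmax[t * 3 + d] = b;
    }
    for (int kz = tmin[t*3+2]; kz <= tmax[t*3+2]; ++kz)
      for (int ky = tmin[t*3+1]; ky <= tmax[t*3+1]; ++ky)
        for (int kx = tmin[t*3]; kx <= tmax[t*3]; ++kx)
          counts[(R_xlen_t)kx + (R_xlen_t)nb[0] * (ky + (R_xlen_t)nb[1] * kz)]++;
  }
  std::vector<R_xlen_t> start(ncell + 1, 0);
  for (R_xlen_t c = 0; c < ncell; ++c) start[c + 1] = start[c] + counts[c];
  std::vector<int> items(start[ncell]);
  std::vector<R_xlen_t> fill(start.begin(), start.end() - 1);
  for (int t = 0; t < nt; ++t)
    for (int kz = tmin[t*3+2]; kz <= tmax[t*3+2]; ++kz)
      for (int ky = tmin[t*3+1]; ky <= tmax[t*3+1]; ++ky)
        for (int kx = tmin[t*3]; kx <= tmax[t*3]; ++kx) {
          R_xlen_t c = (R_xlen_t)kx + (R_xlen_t)nb[0] * (ky + (R_xlen_t)nb[1] * kz);
          items[fill[c]++] = t;
        }

  int max_ring = nb[0] + nb[1] + nb[2] + 2;
  for (int qi = 0; qi < nq; ++qi) {
    double p[3] = {query(qi, 0), query(qi, 1), query(qi, 2)};
    int c0[3];
    double outside = 0.0;  // distance from p to the bin volume
    for (int d = 0; d < 3; ++d) {
      c0[d] = (int)std::floor((p[d] - lo[d]) / cell);
      double e = 0.0;
      if (p[d] < lo[d]) e = lo[d] - p[d];
      else if (p[d] > lo[d] + nb[d] * cell) e = p[d] - (lo[d] + nb[d] * cell);
      outside += e * e;
      c0[d] = (int)clampd(c0[d], 0, nb[d] - 1);
    }
    double best = std::numeric_limits<double>::infinity();  // squared
    for (int ring = 0; ring < max_ring; ++ring) {
      double ring_lb = (ring - 1) * cell;
      if (ring_lb > 0 && ring_lb * ring_lb + outside >= best) break;
      bool any_cell = false;
      int x0 = c0[0] - ring, x1 = c0[0] + ring;
      int y0 = c0[1] - ring, y1 = c0[1] + ring;
      int z0 = c0[2] - ring, z1 = c0[2] + ring;
      for (int kz = z0; kz <= z1; ++kz) {
        if (kz < 0 || kz >= nb[2]) continue;
        for (int ky = y0; ky <= y1; ++ky) {
          if (ky < 0 || ky >= nb[1]) continue;
          bool face_z = (kz == z0 || kz == z1);
          bool face_y = (ky == y0 || ky == y1);
          int stepx = (face_z || face_y) ? 1 : (x1 - x0 > 0 ? x1 - x0 : 1);
          for (int kx = x0; kx <= x1; kx += stepx) {
            if (kx < 0 || kx >= nb[0]) continue;
            any_cell = true;
            R_xlen_t c = (R_xlen_t)kx + (R_xlen_t)nb[0] * (ky + (R_xlen_t)nb[1] * kz);
            for (R_xlen_t s = start[c]; s < start[c + 1]; ++s) {
              int t = items[s];
              int va = F(t, 0) - 1, vb = F(t, 1) - 1, vc = F(t, 2) - 1;
              double A[3] = {V(va,0), V(va,1), V(va,2)};
              double B[3] = {V(vb,0), V(vb,1), V(vb,2)};
              double C[3] = {V(vc,0), V(vc,1), V(vc,2)};
              double d2 = pt_tri_d2(p, A, B, C);
              if (d2 < best) best = d2;
            }
          }
        }
      }
      if (!any_cell && ring > 0) break;  // whole grid already covered
    }
    out[qi] = std::sqrt(best);
  }
  return out;
}
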