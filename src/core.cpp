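#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 26-connectivity seeded labelling
// ---------------------------------------------------------------------------

// Flood-fill each seed through the foreground with 26-connectivity.
// Returns an integer volume: 0 background/unreached, l for seed l.
// Stops with an R error if a seed is outside the mask or if two seeds
// share one connected component.
// [[Rcpp::export(name = ".cct_label_seeded")]]
IntegerVector cct_label_seeded(LogicalVector mask, IntegerVector dims,
                               IntegerMatrix seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int ns = seeds.nrow();
  for (int s = 0; s < ns; ++s) {
    int si = seeds(s, 0), sj = seeds(s, 1), sk = seeds(s, 2); // 0-based
    if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
      stop("seed %d lies outside the volume grid", s + 1);
    R_xlen_t idx = (R_xlen_t)si + nx * ((R_xlen_t)sj + (R_xlen_t)ny * sk);
    if (!mask[idx])
      stop("seed %d falls in background (not inside the mask)", s + 1);
    if (lab[idx] != 0)
      stop("seeds %d and %d fall in the same connected component",
           lab[idx], s + 1);
    int l = s + 1;
    std::queue<R_xlen_t> q;
    lab[idx] = l;
    q.push(idx);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int ck = (int)(cur / ((R_xlen_t)nx * ny));
      R_xlen_t rem = cur - (R_xlen_t)ck * nx * ny;
      int cj = (int)(rem / nx), ci = (int)(rem % nx);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int i2 = ci + di, j2 = cj + dj, k2 = ck + dk;
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
              continue;
            R_xlen_t nid = (R_xlen_t)i2 + nx * ((R_xlen_t)j2 + (R_xlen_t)ny * k2);
            if (!mask[nid] || lab[nid] == l) continue;
            if (lab[nid] != 0)
              stop("seeds %d and %d fall in the same connected component",
                   lab[nid], l);
            lab[nid] = l;
            q.push(nid);
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra isosurface
// ---------------------------------------------------------------------------

// Each grid cell is split into six tetrahedra sharing the main diagonal
// v0-v7; the split is chosen so that face diagonals agree between
// neighbouring cells, making the extracted surface watertight.  Surface
// vertices lie on cell edges (linear interpolation of the field at the
// iso level) and are shared through a global edge->vertex map.

static const int TET[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
};

static inline int mt_edge_vertex(MTState &st, R_xlen_t ga, R_xlen_t gb,
                                 double va, double vb, double level,
                                 const double *px, const double *py,
                                 const double *pz, int ia, int ib) {
  if (ga > gb) { std::swap(ga, gb); std::swap(va, vb); std::swap(ia, ib); }
  uint64_t key = ((uint64_t)ga << 32) | (uint64_t)gb;
  auto it = st.edge_vert.find(key);
  if (it != st.edge_vert.end()) return it->second;
  double t = (level - va) / (vb - va);
  int id = (int)st.vx.size();
  st.vx.push_back(px[ia] + t * (px[ib] - px[ia]));
  st.vy.push_back(py[ia] + t * (py[ib] - py[ia]));
  st.vz.push_back(pz[ia] + t * (pz[ib] - pz[ia]));
  st.edge_vert[key] = id;
  return id;
}

static inline void mt_emit(MTState &st, int a, int b, int c,
                           double inx, double iny, double inz) {
  // orient the facet so that its normal points away from the inside
  double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a], uz = st.vz[b] - st.vz[a];
  double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a], wz = st.vz[c] - st.vz[a];
  double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
  double cx = (st.vx[a] + st.vx[b] + st.vx[c]) / 3.0 - inx;
  double cy = (st.vy[a] + st.vy[b] + st.vy[c]) / 3.0 - iny;
  double cz = (st.vz[a] + st.vz[b] + st.vz[c]) / 3.0 - inz;
  if (nxv * cx + nyv * cy + nzv * cz < 0) std::swap(b, c);
  st.f1.push_back(a); st.f2.push_back(b); st.f3.push_back(c);
}

// [[Rcpp::export(name = ".cct_marching_tets")]]
List cct_marching_tets(NumericVector field, IntegerVector dims, double level,
                       NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  MTState st;
  const double *F = REAL(field);
  double px[8], py[8], pz[8], val[8];
  R_xlen_t gid[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          R_xlen_t g = (R_xlen_t)ci + nx * ((R_xlen_t)cj + (R_xlen_t)ny * ck);
          gid[c] = g; val[c] = F[g];
          px[c] = ox + ci * sx; py[c] = oy + cj * sy; pz[c] = oz + ck * sz;
          (val[c] >= level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = TET[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c)
            (val[tv[c]] >= level ? in[nin++] : out[nout++]) = tv[c];
          if (nin == 0 || nin == 4) continue;
          // centroid of inside corners, used only to orient facets
          double inx = 0, iny = 0, inz = 0;
          for (int c = 0; c < nin; ++c) { inx += px[in[c]]; iny += py[in[c]]; inz += pz[in[c]]; }
          inx /= nin; iny /= nin; inz /= nin;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            int others[3], no = 0;
            for (int c = 0; c < 4; ++c) if (tv[c] != apex) others[no++] = tv[c];
            int e[3];
            for (int c = 0; c < 3; ++c)
              e[c] = mt_edge_vertex(st, gid[apex], gid[others[c]],
                                    val[apex], val[others[c]], level,
                                    px, py, pz, apex, others[c]);
            mt_emit(st, e[0], e[1], e[2], inx, iny, inz);
          } else { // 2 in, 2 out: quad split into two facets
            int a = in[0], b = in[1], c0 = out[0], d0 = out[1];
            int e_ac = mt_edge_vertex(st, gid[a], gid[c0], val[a], val[c0], level, px, py, pz, a, c0);
            int e_ad = mt_edge_vertex(st, gid[a], gid[d0], val[a], val[d0], level, px, py, pz, a, d0);
            int e_bc = mt_edge_vertex(st, gid[b], gid[c0], val[b], val[c0], level, px, py, pz, b, c0);
            int e_bd = mt_edge_vertex(st, gid[b], gid[d0], val[b], val[d0], level, px, py, pz, b, d0);
            mt_emit(st, e_ac, e_ad, e_bd, inx, iny, inz);
            mt_emit(st, e_ac, e_bd, e_bc, inx, iny, inz);
          }
        }
      }
  int nv = (int)st.vx.size(), nf = (int)st.f1.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v,0)=st.vx[v]; V(v,1)=st.vy[v]; V(v,2)=st.vz[v]; }
  IntegerMatrix Fc(nf, 3);
  for (int f = 0; f < nf; ++f) { Fc(f,0)=st.f1[f]+1; Fc(f,1)=st.f2[f]+1; Fc(f,2)=st.f3[f]+1; }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// ---------------------------------------------------------------------------
// Polygon helpers (2-D, physical coordinates)
// ---------------------------------------------------------------------------

// Even-odd scanline fill of a simple polygon onto a voxel-centre grid.
// [[Rcpp::export(name = ".cct_polygon_fill")]]
LogicalMatrix cct_polygon_fill(NumericMatrix poly, double ox, double oy,
                               double sx, double sy, int nx, int ny) {
  LogicalMatrix out(nx, ny);
  int n = poly.nrow();
  std::vector<double> xs; xs.reserve(8);
  for (int j = 0; j < ny; ++j) {
    double ycen = oy + j * sy;
    xs.clear();
    for (int e = 0; e < n; ++e) {
      double x1 = poly(e, 0), y1 = poly(e, 1);
      double x2 = poly((e + 1) % n, 0), y2 = poly((e + 1) % n, 1);
      if ((y1 <= ycen && y2 > ycen) || (y2 <= ycen && y1 > ycen)) {
        double t = (ycen - y1) / (y2 - y1);
        xs.push_back(x1 + t * (x2 - x1));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      int i0 = (int)std::ceil((xs[p] - ox) / sx - 1e-12);
      int i1 = (int)std::floor((xs[p + 1] - ox) / sx + 1e-12);
      if (i0 < 0) i0 = 0;
      if (i1 >= nx) i1 = nx - 1;
      for (int i = i0; i <= i1; ++i) out(i, j) = true;
    }
  }
  return out;
}

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// Proper-intersection test between all non-adjacent edge pairs of a
// closed polygon (O(n^2); contours here have a few hundred vertices).
// [[Rcpp::export(name = ".cct_polygon_self_intersects")]]
bool cct_polygon_self_intersects(NumericMatrix poly) {
  int n = poly.nrow();
  for (int a = 0; a < n; ++a) {
    int a2 = (a + 1) % n;
    for (int b = a + 2; b < n; ++b) {
      int b2 = (b + 1) % n;
      if (b2 == a) continue; // adjacent through the wrap-around
      double p0x = poly(a,0), p0y = poly(a,1), p1x = poly(a2,0), p1y = poly(a2,1);
      double q0x = poly(b,0), q0y = poly(b,1), q1x = poly(b2,0), q1y = poly(b2,1);
      double d1 = cross2(p1x-p0x, p1y-p0y, q0x-p0x, q0y-p0y);
      double d2 = cross2(p1x-p0x, p1y-p0y, q1x-p0x, q1y-p0y);
      double d3 = cross2(q1x-q0x, q1y-q0y, p0x-q0x, p0y-q0y);
      double d4 = cross2(q1x-q0x, q1y-q0y, p1x-q0x, p1y-q0y);
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return true;
    }
  }
  return false;
}

// ---------------------------------------------------------------------------
// Point-to-triangle nearest distances with a uniform-grid index
// ---------------------------------------------------------------------------

// Closest point on triangle (a, b, c) to p (Ericson-style region walk).
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i]=a[i]+v*ab[i];
    return;
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i]=a[i]+w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i]=b[i]+w*(c[i]-b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i]=a[i]+ab[i]*v+ac[i]*w;
}

// [[Rcpp::export(name = ".cct_nearest_on_surface")]]
List cct_nearest_on_surface(NumericMatrix pts, NumericMatrix verts,
                            IntegerMatrix faces) {
  int np = pts.nrow(), nf = faces.nrow(), nv = verts.nrow();
  if (nf == 0) stop("target mesh has no faces");
  // flatten face corner coordinates once (cache-friendly inner loop)
  std::vector<double> fc(9 * (size_t)nf);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) {
      int vi = faces(f, c) - 1;
      for (int d = 0; d < 3; ++d)
        fc[9 * (size_t)f + 3 * c + d] = verts(vi, d);
    }
  // bounding box and grid resolution ~ cube root of face count
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) {
      if (verts(v,d) < lo[d]) lo[d] = verts(v,d);
      if (verts(v,d) > hi[d]) hi[d] = verts(v,d);
    }
  int ng = (int)std::ceil(std::cbrt((double)nf / 4.0));
  if (ng < 1) ng = 1; if (ng > 128) ng = 128;
  double cell[3];
  for (int d = 0; d < 3; ++d) {
    double ext = hi[d] - lo[d];
    if (ext <= 0) ext = 1e-9;
    cell[d] = ext / ng;
  }
  auto cidx = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / cell[d]);
    if (c < 0) c = 0; if (c >= ng) c = ng - 1;
    return c;
  };
  std::vector<std::vector<int> > bins((size_t)ng * ng * ng);
  for (int f = 0; f < nf; ++f) {
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int c = 0; c < 3; ++c) {
        double x = fc[9 * (size_t)f + 3 * c + d];
        if (x < mn) mn = x;
        if (x > mx) mx = x;
      }
      c0[d] = cidx(mn, d); c1[d] = cidx(mx, d);
    }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          bins[(size_t)i + ng * ((size_t)j + (size_t)ng * k)].push_back(f);
  }
  NumericVector dist(np);
  NumericMatrix close(np, 3);
  IntegerVector face_id(np);
  double p[3], q[3];
  for (int ip = 0; ip < np; ++ip) {
    for (int d = 0; d < 3; ++d) p[d] = pts(ip, d);
    int ci = cidx(p[0],0), cj = cidx(p[1],1), ck = cidx(p[2],2);
    double best = R_PosInf; double bq[3] = {0,0,0}; int bf = 0;
    for (int ring = 0; ring < 2 * ng; ++ring) {
      if (best < R_PosInf) {
        // stop once closer cells cannot exist
        double ring_lb = (ring - 1) * std::min(cell[0], std::min(cell[1], cell[2]));
        if (ring_lb > 0 && ring_lb * ring_lb > best) break;
      }
      bool any_cell = false;
      int i0 = ci - ring, i1 = ci + ring;
      for (int k = ck - ring; k <= ck + ring; ++k) {
        if (k < 0 || k >= ng) continue;
        for (int j = cj - ring; j <= cj + ring; ++j) {
          if (j < 0 || j >= ng) continue;
          for (int i = i0; i <= i1; ++i) {
            if (i < 0 || i >= ng) continue;
            // shell only
            if (ring > 0 && std::abs(i - ci) != ring && std::abs(j - cj) != ring &&
                std::abs(k - ck) != ring) continue;
            any_cell = true;
            const std::vector<int> &bin = bins[(size_t)i + ng * ((size_t)j + (size_t)ng * k)];
            for (size_t t = 0; t < bin.size(); ++t) {
              const double *tf = &fc[9 * (size_t)bin[t]];
              closest_on_tri(p, tf, tf + 3, tf + 6, q);
              double d2 = 0;
              for (int d = 0; d < 3; ++d) d2 += (q[d]-p[d])*(q[d]-p[d]);
              if (d2 < best) { best = d2; bq[0]=q[0]; bq[1]=q[1]; bq[2]=q[2]; bf = bin[t]; }
            }
          }
        }
      }
      if (!any_cell && ring >= ng) break;
    }
    dist[ip] = std::sqrt(best);
    close(ip,0)=bq[0]; close(ip,1)=bq[1]; close(ip,2)=bq[2];
    face_id[ip] = bf + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = close,
                      _["face"] = face_id);
}
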