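// Geometry kernels: marching-tetrahedra isosurface extraction, closest
// point-to-triangle queries (uniform-grid accelerated), 3D connected
// components, parity-fill voxelization of closed meshes, trilinear sampling
// and the partial-volume joint histogram used by the NMI registration engine.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra
// ---------------------------------------------------------------------------

// cube corner offsets, bit0 = x, bit1 = y, bit2 = z
static const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};

// six tetrahedra around the 0-7 diagonal
static const int TETS[6][4] = {
  {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};

struct TriPat { int n; int e[4][2]; }; // up to 2 triangles = 4 edge pairs? use 6
struct CasePat { int ntri; int edges[6][2]; };

// build the 16-case table for a positively oriented tet (a,b,c,d)=(0,1,2,3)
static void buildCaseTable(CasePat table[16]) {
  for (int m = 0; m < 16; ++m) table[m].ntri = 0;
  auto setTri = [&](int m, int i, int a0, int a1, int b0, int b1, int c0, int c1) {
    table[m].edges[3*i+0][0]=a0; table[m].edges[3*i+0][1]=a1;
    table[m].edges[3*i+1][0]=b0; table[m].edges[3*i+1][1]=b1;
    table[m].edges[3*i+2][0]=c0; table[m].edges[3*i+2][1]=c1;
  };
  // single inside
  table[1].ntri=1;  setTri(1,0, 0,1, 0,2, 0,3);
  table[2].ntri=1;  setTri(2,0, 1,0, 1,3, 1,2);
  table[4].ntri=1;  setTri(4,0, 2,0, 2,1, 2,3);
  table[8].ntri=1;  setTri(8,0, 3,0, 3,2, 3,1);
  // single outside (complement, reversed winding)
  table[14].ntri=1; setTri(14,0, 0,1, 0,3, 0,2);
  table[13].ntri=1; setTri(13,0, 1,0, 1,2, 1,3);
  table[11].ntri=1; setTri(11,0, 2,0, 2,3, 2,1);
  table[7].ntri=1;  setTri(7,0, 3,0, 3,1, 3,2);
  // two inside
  table[3].ntri=2;  setTri(3,0, 0,2, 0,3, 1,3); setTri(3,1, 0,2, 1,3, 1,2);
  table[5].ntri=2;  setTri(5,0, 0,3, 0,1, 2,1); setTri(5,1, 0,3, 2,1, 2,3);
  table[9].ntri=2;  setTri(9,0, 0,1, 0,2, 3,2); setTri(9,1, 0,1, 3,2, 3,1);
  table[6].ntri=2;  setTri(6,0, 1,0, 1,3, 2,3); setTri(6,1, 1,0, 2,3, 2,0);
  table[10].ntri=2; setTri(10,0, 1,2, 1,0, 3,0); setTri(10,1, 1,2, 3,0, 3,2);
  table[12].ntri=2; setTri(12,0, 2,0, 2,1, 3,1); setTri(12,1, 2,0, 3,1, 3,0);
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector values, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t nxy = (int64_t)nx * ny;
  CasePat table[16];
  buildCaseTable(table);

  // pre-orient the six tets (swap last two corners if negatively oriented)
  int tets[6][4];
  for (int t = 0; t < 6; ++t) {
    for (int k = 0; k < 4; ++k) tets[t][k] = TETS[t][k];
    double e1[3], e2[3], e3[3];
    for (int d = 0; d < 3; ++d) {
      e1[d] = CUBE[tets[t][1]][d] - CUBE[tets[t][0]][d];
      e2[d] = CUBE[tets[t][2]][d] - CUBE[tets[t][0]][d];
      e3[d] = CUBE[tets[t][3]][d] - CUBE[tets[t][0]][d];
    }
    double det = e1[0]*(e2[1]*e3[2]-e2[2]*e3[1])
               - e1[1]*(e2[0]*e3[2]-e2[2]*e3[0])
               + e1[2]*(e2[0]*e3[1]-e2[1]*e3[0]);
    if (det < 0) std::swap(tets[t][2], tets[t][3]);
  }

  std::unordered_map<uint64_t, int> edgeVert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto gidx = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)j * nx + (int64_t)k * nxy;
  };

  auto edgePoint = [&](int64_t ga, int64_t gb, double va, double vb) -> int {
    uint64_t key = ga < gb
      ? ((uint64_t)ga << 32) | (uint64_t)gb
      : ((uint64_t)gb << 32) | (uint64_t)ga;
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    double t = (iso - va) / (vb - va);
    int ai = (int)(ga % nx), aj = (int)((ga / nx) % ny), ak = (int)(ga / nxy);
    int bi = (int)(gb % nx), bj = (int)((gb / nx) % ny), bk = (int)(gb / nxy);
    vx.push_back(ai + t * (bi - ai));
    vy.push_back(aj + t * (bj - aj));
    vz.push_back(ak + t * (bk - ak));
    int id = (int)vx.size() - 1;
    edgeVert[key] = id;
    return id;
  };

  for (int k = 0; k + 1 < nz; ++k)
  for (int j = 0; j + 1 < ny; ++j)
  for (int i = 0; i + 1 < nx; ++i) {
    double cv[8]; int64_t cg[8]; bool any = false, all = true;
    for (int c = 0; c < 8; ++c) {
      cg[c] = gidx(i + CUBE[c][0], j + CUBE[c][1], k + CUBE[c][2]);
      cv[c] = values[cg[c]];
      bool in = cv[c] > iso;
      any = any || in; all = all && in;
    }
    if (!any || all) continue;
    for (int t = 0; t < 6; ++t) {
      int mask = 0;
      for (int c = 0; c < 4; ++c)
        if (cv[tets[t][c]] > iso) mask |= (1 << c);
      const CasePat &pat = table[mask];
      for (int q = 0; q < pat.ntri; ++q) {
        int vid[3];
        for (int e = 0; e < 3; ++e) {
          int ca = tets[t][pat.edges[3*q+e][0]];
          int cb = tets[t][pat.edges[3*q+e][1]];
          vid[e] = edgePoint(cg[ca], cg[cb], cv[ca], cv[cb]);
        }
        if (vid[0] == vid[1] || vid[1] == vid[2] || vid[0] == vid[2]) continue;
        tri.push_back(vid[0]); tri.push_back(vid[1]); tri.push_back(vid[2]);
      }
    }
  }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0)=vx[i]; V(i,1)=vy[i]; V(i,2)=vz[i]; }
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nt; ++i) {
    F(i,0)=tri[3*i]+1; F(i,1)=tri[3*i+1]+1; F(i,2)=tri[3*i+2]+1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Closest point on triangle (Ericson) + uniform-grid accelerated queries
// ---------------------------------------------------------------------------

static inline void closestOnTri(const double p[3], const double a[3],
                                const double b[3], const double c[3],
                                double out[3]) {
  double ab[3], ac[3], ap[3];
  for (int d=0; d<3; ++d){ ab[d]=b[d]-a[d]; ac[d]=c[d]-a[d]; ap[d]=p[d]-a[d]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for(int d=0;d<3;++d) out[d]=a[d]; return; }
  double bp[3]; for (int d=0; d<3; ++d) bp[d]=p[d]-b[d];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for(int d=0;d<3;++d) out[d]=b[d]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for(int d=0;d<3;++d) out[d]=a[d]+v*ab[d]; return;
  }
  double cp[3]; for (int d=0; d<3; ++d) cp[d]=p[d]-c[d];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for(int d=0;d<3;++d) out[d]=c[d]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for(int d=0;d<3;++d) out[d]=a[d]+w*ac[d]; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for(int d=0;d<3;++d) out[d]=b[d]+w*(c[d]-b[d]); return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for(int d=0;d<3;++d) out[d]=a[d]+ab[d]*v+ac[d]*w;
}

// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix pts, NumericMatrix vert, IntegerMatrix tri) {
  const int np = pts.nrow(), nt = tri.nrow(), nv = vert.nrow();
  // flatten triangle corner coordinates for fast access
  std::vector<double> V(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) V[3*i+d] = vert(i, d);
  std::vector<int> T(3 * nt);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c) T[3*t+c] = tri(t, c) - 1;

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) {
      if (V[3*i+d] < lo[d]) lo[d] = V[3*i+d];
      if (V[3*i+d] > hi[d]) hi[d] = V[3*i+d];
    }
  // isotropic cells: ~2 triangles per occupied cell, bounded total
  double ext[3], bboxVol = 1;
  for (int d = 0; d < 3; ++d) {
    ext[d] = std::max(hi[d] - lo[d], 1e-6);
    bboxVol *= ext[d];
  }
  double cs = std::cbrt(bboxVol / std::max(nt / 2.0, 1.0));
  int ncell[3];
  int64_t NC = 1;
  for (int d = 0; d < 3; ++d) {
    ncell[d] = std::max(1, std::min(128, (int)std::ceil(ext[d] / cs)));
    NC *= ncell[d];
  }
  std::vector< std::vector<int> > cells((size_t)NC);
  auto clampCell = [&](double x, int d) -> int {
    int c = (int)((x - lo[d]) / cs);
    if (c < 0) c = 0;
    if (c >= ncell[d]) c = ncell[d] - 1;
    return c;
  };
  for (int t = 0; t < nt; ++t) {
    double tlo[3], thi[3];
    for (int d = 0; d < 3; ++d) {
      double a = V[3*T[3*t]+d], b = V[3*T[3*t+1]+d], c = V[3*T[3*t+2]+d];
      tlo[d] = std::min(a, std::min(b, c));
      thi[d] = std::max(a, std::max(b, c));
    }
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = clampCell(tlo[d], d);
      c1[d] = clampCell(thi[d], d);
    }
    for (int iz = c0[2]; iz <= c1[2]; ++iz)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int ix = c0[0]; ix <= c1[0]; ++ix)
          cells[(size_t)ix + (size_t)ncell[0]*(iy + (size_t)ncell[1]*iz)].push_back(t);
  }

  NumericVector dist(np);
  NumericMatrix cpt(np, 3);
  IntegerVector fidx(np);
  int maxRing = ncell[0] + ncell[1] + ncell[2];

  for (int i = 0; i < np; ++i) {
    double p[3] = { pts(i,0), pts(i,1), pts(i,2) };
    int pc[3];
    // distance from the point to the grid region along each axis (the point
    // may lie outside the bounding box)
    double outside2 = 0;
    for (int d = 0; d < 3; ++d) {
      pc[d] = clampCell(p[d], d);
      double e = 0;
      if (p[d] < lo[d]) e = lo[d] - p[d];
      else if (p[d] > hi[d]) e = p[d] - hi[d];
      outside2 += e * e;
    }
    double best = R_PosInf, bq[3] = {0,0,0};
    int bt = -1;
    for (int ring = 0; ring <= maxRing; ++ring) {
      if (bt >= 0) {
        double lb = (ring - 1) * cs;
        double lb2 = lb > 0 ? lb * lb + outside2 : outside2;
        if (lb2 > best) break;
      }
      bool anyCell = false;
      int x0 = pc[0]-ring, x1 = pc[0]+ring;
      int y0 = pc[1]-ring, y1 = pc[1]+ring;
      int z0 = pc[2]-ring, z1 = pc[2]+ring;
      for (int iz = z0; iz <= z1; ++iz) {
        if (iz < 0 || iz >= ncell[2]) continue;
        bool zShell = (iz == z0 || iz == z1);
        for (int iy = y0; iy <= y1; ++iy) {
          if (iy < 0 || iy >= ncell[1]) continue;
          bool yShell = (iy == y0 || iy == y1);
          int xstep = (ring > 0 && !zShell && !yShell) ? (x1 - x0 > 0 ? x1 - x0 : 1) : 1;
          for (int ix = x0; ix <= x1; ix += xstep) {
            if (ix < 0 || ix >= ncell[0]) continue;
            anyCell = true;
            const std::vector<int> &cl =
              cells[(size_t)ix + (size_t)ncell[0]*(iy + (size_t)ncell[1]*iz)];
            for (size_t u = 0; u < cl.size(); ++u) {
              int t = cl[u];
              const double *a = &V[3*T[3*t]];
              const double *b = &V[3*T[3*t+1]];
              const double *c = &V[3*T[3*t+2]];
              double q[3];
              closestOnTri(p, a, b, c, q);
              double d2 = 0;
              for (int d = 0; d < 3; ++d) d2 += (p[d]-q[d])*(p[d]-q[d]);
              if (d2 < best) {
                best = d2; bt = t;
                for (int d = 0; d < 3; ++d) bq[d] = q[d];
              }
            }
          }
        }
      }
      if (!anyCell && bt >= 0 && ring > 0) break;
    }
    dist[i] = std::sqrt(best);
    fidx[i] = bt + 1;
    for (int d = 0; d < 3; ++d) cpt(i,d) = bq[d];
  }
  return List::create(_["distance"] = dist, _["closest"] = cpt, _["face"] = fidx);
}

// ---------------------------------------------------------------------------
// 3D connected components (6 or 26 connectivity)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> nb;
  for (int dz = -1; dz <= 1; ++dz)
  for (int dy = -1; dy <= 1; ++dy)
  for (int dx = -1; dx <= 1; ++dx) {
    if (!dx && !dy && !dz) continue;
    int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
    if (connectivity == 6 && man != 1) continue;
    nb.push_back(dx); nb.push_back(dy); nb.push_back(dz);
  }
  int cur = 0;
  std::vector<int64_t> stack;
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear(); stack.push_back(s); lab[s] = cur;
    while (!stack.empty()) {
      int64_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((int64_t)nx*ny));
      for (size_t q = 0; q < nb.size(); q += 3) {
        int ii = i + nb[q], jj = j + nb[q+1], kk = k + nb[q+2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        int64_t w = (int64_t)ii + (int64_t)jj*nx + (int64_t)kk*nx*ny;
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("ncomp") = cur;
  return lab;
}

// ---------------------------------------------------------------------------
// Parity-fill voxelization of a closed mesh
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix vert, IntegerMatrix tri,
                           IntegerVector dims, NumericVector origin,
                           NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  LogicalVector out(n, false);
  // tiny fixed offset breaks exact edge/vertex ray hits
  const double epsx = 1e-6 * spacing[0] * 0.7391;
  const double epsy = 1e-6 * spacing[1] * 0.5173;
  std::vector< std::vector<double> > cross((size_t)nx * ny);
  for (int t = 0; t < tri.nrow(); ++t) {
    double ax = vert(tri(t,0)-1,0), ay = vert(tri(t,0)-1,1), az = vert(tri(t,0)-1,2);
    double bx = vert(tri(t,1)-1,0), by = vert(tri(t,1)-1,1), bz = vert(tri(t,1)-1,2);
    double cx = vert(tri(t,2)-1,0), cy = vert(tri(t,2)-1,1), cz = vert(tri(t,2)-1,2);
    double xlo = std::min(ax, std::min(bx,cx)), xhi = std::max(ax, std::max(bx,cx));
    double ylo = std::min(ay, std::min(by,cy)), yhi = std::max(ay, std::max(by,cy));
    int i0 = (int)std::ceil((xlo - origin[0] - epsx) / spacing[0]);
    int i1 = (int)std::floor((xhi - origin[0] - epsx) / spacing[0]);
    int j0 = (int)std::ceil((ylo - origin[1] - epsy) / spacing[1]);
    int j1 = (int)std::floor((yhi - origin[1] - epsy) / spacing[1]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx-1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny-1);
    double d = (bx-ax)*(cy-ay) - (by-ay)*(cx-ax); // 2D projected area*2
    if (d == 0) continue;
    for (int j = j0; j <= j1; ++j) {
      double py = origin[1] + j * spacing[1] + epsy;
      for (int i = i0; i <= i1; ++i) {
        double px = origin[0] + i * spacing[0] + epsx;
        double w0 = ((bx-px)*(cy-py) - (by-py)*(cx-px)) / d;
        double w1 = ((cx-px)*(ay-py) - (cy-py)*(ax-px)) / d;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double z = w0*az + w1*bz + w2*cz;
        cross[(size_t)i + (size_t)j*nx].push_back(z);
      }
    }
  }
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i < nx; ++i) {
    std::vector<double> &zs = cross[(size_t)i + (size_t)j*nx];
    if (zs.empty()) continue;
    std::sort(zs.begin(), zs.end());
    size_t m = zs.size() - (zs.size() % 2); // defensive: drop unpaired crossing
    for (size_t q = 0; q + 1 < m; q += 2) {
      int k0 = (int)std::ceil((zs[q]   - origin[2]) / spacing[2]);
      int k1 = (int)std::floor((zs[q+1] - origin[2]) / spacing[2]);
      k0 = std::max(k0, 0); k1 = std::min(k1, nz-1);
      for (int k = k0; k <= k1; ++k)
        out[(int64_t)i + (int64_t)j*nx + (int64_t)k*nx*ny] = true;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear sampling and partial-volume joint histogram
// ---------------------------------------------------------------------------

// pts are continuous 0-based voxel index coordinates into arr
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericMatrix pts, NumericVector arr,
                            IntegerVector dims, double background) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = pts.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double x = pts(i,0), y = pts(i,1), z = pts(i,2);
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 < 0 || y0 < 0 || z0 < 0 || x0+1 >= nx || y0+1 >= ny || z0+1 >= nz) {
      out[i] = background; continue;
    }
    double fx = x-x0, fy = y-y0, fz = z-z0, acc = 0;
    for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
    for (int dx = 0; dx <= 1; ++dx) {
      double w = (dx ? fx : 1-fx) * (dy ? fy : 1-fy) * (dz ? fz : 1-fz);
      acc += w * arr[(int64_t)(x0+dx) + (int64_t)(y0+dy)*nx + (int64_t)(z0+dz)*nx*ny];
    }
    out[i] = acc;
  }
  return out;
}

// fixed-bin index per point (0-based, must be in [0, nbins)); moving intensity
// binned on [mlo, mlo + nbins*mbw); weights distributed trilinearly (PV
// interpolation). Points mapping outside the moving grid are dropped.
// [[Rcpp::export]]
NumericMatrix cpp_pv_hist(NumericMatrix pts, IntegerVector fbin,
                          NumericVector mov, IntegerVector dims,
                          int nbins, double mlo, double mbw) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix H(nbins, nbins);
  for (int i = 0; i < pts.nrow(); ++i) {
    double x = pts(i,0), y = pts(i,1), z = pts(i,2);
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 < 0 || y0 < 0 || z0 < 0 || x0+1 >= nx || y0+1 >= ny || z0+1 >= nz)
      continue;
    int fb = fbin[i];
    double fx = x-x0, fy = y-y0, fz = z-z0;
    for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
    for (int dx = 0; dx <= 1; ++dx) {
      double w = (dx ? fx : 1-fx) * (dy ? fy : 1-fy) * (dz ? fz : 1-fz);
      if (w <= 0) continue;
      double v = mov[(int64_t)(x0+dx) + (int64_t)(y0+dy)*nx + (int64_t)(z0+dz)*nx*ny];
      int mb = (int)std::floor((v - mlo) / mbw);
      if (mb < 0) mb = 0; if (mb >= nbins) mb = nbins - 1;
      H(fb, mb) += w;
    }
  }
  return H;
}
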