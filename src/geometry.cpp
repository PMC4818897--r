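#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Parity (ray-crossing) point containment and column voxelization for
// watertight triangle meshes. Faces are 0-based index triples.

// Fixed jittered ray direction: irrational-ish components so axis-aligned
// facet edges are never grazed for points on lattice coordinates.
static const double RD[3] = {0.5377671873, 0.7257412306, 0.4289771332};

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P) {
  const int nf = F.nrow(), np = P.nrow();
  LogicalVector inside(np);
  if (np == 0) return inside;

  // scale for the on-surface tolerance: mesh bbox diagonal
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] = R_PosInf; hi[c] = R_NegInf;
    for (int i = 0; i < V.nrow(); ++i) {
      if (V(i, c) < lo[c]) lo[c] = V(i, c);
      if (V(i, c) > hi[c]) hi[c] = V(i, c);
    }
  }
  const double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) +
                                (hi[1]-lo[1])*(hi[1]-lo[1]) +
                                (hi[2]-lo[2])*(hi[2]-lo[2]));
  const double eps_t = 1e-9 * std::max(1.0, diag);

  const double dlen = std::sqrt(RD[0]*RD[0] + RD[1]*RD[1] + RD[2]*RD[2]);
  const double d0 = RD[0]/dlen, d1 = RD[1]/dlen, d2 = RD[2]/dlen;

  for (int ip = 0; ip < np; ++ip) {
    const double px = P(ip, 0), py = P(ip, 1), pz = P(ip, 2);
    int crossings = 0;
    bool on_surface = false;
    for (int f = 0; f < nf; ++f) {
      const int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
      const double ax = V(ia,0), ay = V(ia,1), az = V(ia,2);
      const double e1x = V(ib,0)-ax, e1y = V(ib,1)-ay, e1z = V(ib,2)-az;
      const double e2x = V(ic,0)-ax, e2y = V(ic,1)-ay, e2z = V(ic,2)-az;
      // Moller-Trumbore
      const double hx = d1*e2z - d2*e2y;
      const double hy = d2*e2x - d0*e2z;
      const double hz = d0*e2y - d1*e2x;
      const double a = e1x*hx + e1y*hy + e1z*hz;
      const double l1 = std::sqrt(e1x*e1x+e1y*e1y+e1z*e1z);
      const double l2 = std::sqrt(e2x*e2x+e2y*e2y+e2z*e2z);
      if (std::fabs(a) < 1e-14 * l1 * l2) continue; // ray parallel to face
      const double fa = 1.0 / a;
      const double sx = px-ax, sy = py-ay, sz = pz-az;
      const double u = fa * (sx*hx + sy*hy + sz*hz);
      if (u < -1e-12 || u > 1.0 + 1e-12) continue;
      const double qx = sy*e1z - sz*e1y;
      const double qy = sz*e1x - sx*e1z;
      const double qz = sx*e1y - sy*e1x;
      const double v = fa * (d0*qx + d1*qy + d2*qz);
      if (v < -1e-12 || u + v > 1.0 + 1e-12) continue;
      const double t = fa * (e2x*qx + e2y*qy + e2z*qz);
      if (std::fabs(t) <= eps_t) { on_surface = true; break; }
      if (t > 0) ++crossings;
    }
    inside[ip] = on_surface || (crossings & 1);
  }
  return inside;
}

// Occupancy of voxel centers inside a mesh by parity fills along +x within
// each (y,z) column. Centers sit at origin + (index + 0.5 + tiny)*h where the
// per-dimension tiny offsets dodge exact facet/edge hits on round coordinates.
// Returns a logical vector in R array order dim = c(nx, ny, nz).
// [[Rcpp::export]]
LogicalVector cpp_voxel_occupancy(NumericMatrix V, IntegerMatrix F,
                                  double ox, double oy, double oz,
                                  double h, int nx, int ny, int nz) {
  const double sx = ox + (0.5 + 1.3e-4) * h;
  const double sy = oy + (0.5 + 2.3e-4) * h;
  const double sz = oz + (0.5 + 3.7e-4) * h;
  const int ncol = ny * nz;
  std::vector< std::vector<double> > crossings(ncol);

  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
    const double pyv[3] = {V(ia,1), V(ib,1), V(ic,1)};
    const double pzv[3] = {V(ia,2), V(ib,2), V(ic,2)};
    const double pxv[3] = {V(ia,0), V(ib,0), V(ic,0)};
    // full normal; its x component is twice the signed yz-projected area
    const double e1x = pxv[1]-pxv[0], e1y = pyv[1]-pyv[0], e1z = pzv[1]-pzv[0];
    const double e2x = pxv[2]-pxv[0], e2y = pyv[2]-pyv[0], e2z = pzv[2]-pzv[0];
    const double nxn = e1y*e2z - e1z*e2y;
    const double nyn = e1z*e2x - e1x*e2z;
    const double nzn = e1x*e2y - e1y*e2x;
    const double l1 = std::sqrt(e1x*e1x+e1y*e1y+e1z*e1z);
    const double l2 = std::sqrt(e2x*e2x+e2y*e2y+e2z*e2z);
    if (std::fabs(nxn) < 1e-14 * l1 * l2) continue; // parallel to ray axis
    const double nd = nxn*pxv[0] + nyn*pyv[0] + nzn*pzv[0];

    double ymin = std::min(pyv[0], std::min(pyv[1], pyv[2]));
    double ymax = std::max(pyv[0], std::max(pyv[1], pyv[2]));
    double zmin = std::min(pzv[0], std::min(pzv[1], pzv[2]));
    double zmax = std::max(pzv[0], std::max(pzv[1], pzv[2]));
    int jy0 = (int)std::ceil((ymin - sy) / h), jy1 = (int)std::floor((ymax - sy) / h);
    int jz0 = (int)std::ceil((zmin - sz) / h), jz1 = (int)std::floor((zmax - sz) / h);
    if (jy0 < 0) jy0 = 0; if (jy1 > ny - 1) jy1 = ny - 1;
    if (jz0 < 0) jz0 = 0; if (jz1 > nz - 1) jz1 = nz - 1;

    for (int jz = jz0; jz <= jz1; ++jz) {
      const double zc = sz + jz * h;
      for (int jy = jy0; jy <= jy1; ++jy) {
        const double yc = sy + jy * h;
        // pnpoly half-open crossing rule in the yz plane: a column exactly on
        // a shared edge is claimed by exactly one of the adjacent triangles,
        // so the parity along the column stays consistent.
        bool in = false;
        for (int k = 0, l = 2; k < 3; l = k++) {
          if (((pzv[k] > zc) != (pzv[l] > zc)) &&
              (yc < (pyv[l]-pyv[k]) * (zc-pzv[k]) / (pzv[l]-pzv[k]) + pyv[k]))
            in = !in;
        }
        if (!in) continue;
        const double xcross = (nd - nyn*yc - nzn*zc) / nxn;
        crossings[jy + (size_t)ny * jz].push_back(xcross);
      }
    }
  }

  LogicalVector occ((R_xlen_t)nx * ny * nz);
  for (int jz = 0; jz < nz; ++jz) {
    for (int jy = 0; jy < ny; ++jy) {
      std::vector<double> &cr = crossings[jy + (size_t)ny * jz];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      const size_t npair = cr.size() / 2; // odd leftovers dropped
      for (size_t p = 0; p < npair; ++p) {
        const double x1 = cr[2*p], x2 = cr[2*p + 1];
        int i0 = (int)std::ceil((x1 - sx) / h);
        int i1 = (int)std::floor((x2 - sx) / h);
        if (sx + i1 * h >= x2) --i1; // strict interior at the exit face
        if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
        for (int i = i0; i <= i1; ++i)
          occ[i + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz)] = true;
      }
    }
  }
  return occ;
}
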