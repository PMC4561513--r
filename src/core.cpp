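// Voxel-level cores: 26/6-connected component labeling, exact Euclidean
// distance transform, topology-preserving 3D thinning, and parallel-beam
// radon / back-projection kernels. Kept in C++ because they are the only
// hot loops in the package; everything else is vectorized R.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdlib>
#include <queue>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// connected-component labeling
// ---------------------------------------------------------------------------

// connectivity: 26 (full) or 6 (face). For 2D inputs pass nz = 1; the
// 26-neighborhood then degenerates to 8-connectivity and 6 to 4.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  IntegerVector lab(n, 0);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++cur;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int vx = (int)(v % nx), vy = (int)((v / nx) % ny), vz = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < offx.size(); ++k) {
        int ux = vx + offx[k], uy = vy + offy[k], uz = vz + offz[k];
        if (ux < 0 || ux >= nx || uy < 0 || uy >= ny || uz < 0 || uz >= nz)
          continue;
        R_xlen_t u = ux + (R_xlen_t)nx * (uy + (R_xlen_t)ny * uz);
        if (mask[u] && !lab[u]) { lab[u] = cur; q.push(u); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// separable over axes, anisotropic spacing supported
// ---------------------------------------------------------------------------

static void edt_1d(std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z, int n,
                   double w2) {
  // lower envelope of parabolas d(j) = w2*(j-i)^2 + f(i); sites with
  // infinite f (not yet reached by any background) are skipped
  int k = -1;
  for (int qi = 0; qi < n; ++qi) {
    if (f[qi] == HUGE_VAL) continue;
    double s = 0.0;
    while (k >= 0) {
      s = ((f[qi] + w2 * qi * qi) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (qi - v[k]));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = qi;
    z[k] = (k == 0) ? -HUGE_VAL : s;
    z[k + 1] = HUGE_VAL;
  }
  if (k < 0) {
    for (int qi = 0; qi < n; ++qi) d[qi] = HUGE_VAL;
    return;
  }
  int kk = 0;
  for (int qi = 0; qi < n; ++qi) {
    while (z[kk + 1] < qi) ++kk;
    d[qi] = w2 * (double)(qi - v[kk]) * (qi - v[kk]) + f[v[kk]];
  }
}

// squared distance from each true voxel to the nearest false voxel,
// in physical units given per-axis spacing
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? HUGE_VAL : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      for (int ix = 0; ix < nx; ++ix) f[ix] = out[base + ix];
      edt_1d(f, d, v, z, nx, spacing[0] * spacing[0]);
      for (int ix = 0; ix < nx; ++ix) out[base + ix] = d[ix];
    }
  // y pass
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy)
        f[iy] = out[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      edt_1d(f, d, v, z, ny, spacing[1] * spacing[1]);
      for (int iy = 0; iy < ny; ++iy)
        out[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = d[iy];
    }
  // z pass
  if (nz > 1)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        for (int iz = 0; iz < nz; ++iz)
          f[iz] = out[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        edt_1d(f, d, v, z, nz, spacing[2] * spacing[2]);
        for (int iz = 0; iz < nz; ++iz)
          out[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = d[iz];
      }
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] == HUGE_VAL) out[i] = NA_REAL;
  return out;
}

// ---------------------------------------------------------------------------
// topology-preserving sequential 3D thinning
// ---------------------------------------------------------------------------

// A border voxel may be deleted only if it is a simple point: removing it
// changes neither the number of 26-connected object components in its
// neighborhood nor the number of 6-connected background components in its
// 18-neighborhood (Malandain-Bertrand characterization). Deletion is fully
// sequential inside each of six directional sub-iterations, so every
// deletion is re-validated against the current object: topology is
// preserved by construction. Voxels with a single object neighbor
// (curve endpoints) are never deleted, which preserves centerline extent.

static inline int nb_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// true if some axis (face, edge or corner direction) has object voxels on
// both sides of the center: the object is locally "thick" along that axis.
// Voxels without any such pair are local extremities (curve ends, surface
// corners); deleting them shortens the skeleton rather than thinning it,
// so they are kept and left to graph-level spur pruning.
static bool has_opposite_pair(const bool nb[27]) {
  for (int i = 0; i < 13; ++i) { // 13 axes: i and 26-i are opposite cells
    if (nb[i] && nb[26 - i]) return true;
  }
  return false;
}

static bool is_simple(const bool nb[27]) {
  // 1: object voxels of the 26-neighborhood form one 26-connected component
  int lab[27] = {0};
  int ncomp = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || lab[i]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int top = 0;
    stack[top++] = i;
    lab[i] = ncomp;
    while (top) {
      int vtx = stack[--top];
      int vx = vtx % 3, vy = (vtx / 3) % 3, vz = vtx / 9;
      for (int u = 0; u < 27; ++u) {
        if (u == 13 || !nb[u] || lab[u]) continue;
        int ux = u % 3, uy = (u / 3) % 3, uz = u / 9;
        if (std::abs(ux - vx) <= 1 && std::abs(uy - vy) <= 1 &&
            std::abs(uz - vz) <= 1) {
          lab[u] = ncomp;
          stack[top++] = u;
        }
      }
    }
  }
  if (ncomp != 1) return false;
  // 2: background voxels of the 18-neighborhood (faces + edges), under
  // 6-connectivity, form one component that touches a face neighbor
  int lab2[27] = {0};
  int ncomp2 = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || nb[i] || lab2[i]) continue;
    int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    int manh = std::abs(ix) + std::abs(iy) + std::abs(iz);
    if (manh != 1) continue; // seed components only from face neighbors
    ++ncomp2;
    if (ncomp2 > 1) return false;
    int top = 0;
    stack[top++] = i;
    lab2[i] = ncomp2;
    while (top) {
      int vtx = stack[--top];
      int vx = vtx % 3 - 1, vy = (vtx / 3) % 3 - 1, vz = vtx / 9 - 1;
      for (int ddx = -1; ddx <= 1; ++ddx)
        for (int ddy = -1; ddy <= 1; ++ddy)
          for (int ddz = -1; ddz <= 1; ++ddz) {
            if (std::abs(ddx) + std::abs(ddy) + std::abs(ddz) != 1) continue;
            int ux = vx + ddx, uy = vy + ddy, uz = vz + ddz;
            if (ux < -1 || ux > 1 || uy < -1 || uy > 1 || uz < -1 || uz > 1)
              continue;
            int manu = std::abs(ux) + std::abs(uy) + std::abs(uz);
            if (manu > 2 || manu == 0) continue; // stay in N18, skip center
            int u = nb_index(ux, uy, uz);
            if (nb[u] || lab2[u]) continue;
            lab2[u] = ncomp2;
            stack[top++] = u;
          }
    }
  }
  return ncomp2 == 1;
}

// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<char> obj(n);
  for (R_xlen_t i = 0; i < n; ++i) obj[i] = mask[i] ? 1 : 0;

  // squared distance to background, used to schedule the erosion from the
  // surface inward (distance-ordered homotopic thinning); without this
  // ordering the six-directional peeling stays synchronized on jagged
  // tubes and can freeze diagonally packed voxel bundles that no single
  // simple-point deletion can dissolve
  NumericVector spacing = NumericVector::create(1.0, 1.0, 1.0);
  NumericVector edt = edt_sq_cpp(mask, dims, spacing);
  std::vector<double> levels;
  for (R_xlen_t i = 0; i < n; ++i)
    if (obj[i]) levels.push_back(edt[i]);
  std::sort(levels.begin(), levels.end());
  levels.erase(std::unique(levels.begin(), levels.end()), levels.end());

  auto at = [&](int x, int y, int z) -> char {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return obj[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  auto gather = [&](int x, int y, int z, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[nb_index(dx, dy, dz)] = at(x + dx, y + dy, z + dz) != 0;
  };
  auto n26 = [&](const bool nb[27]) {
    int c = 0;
    for (int i = 0; i < 27; ++i)
      if (i != 13 && nb[i]) ++c;
    return c;
  };

  const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1},  {0, -1, 0},
                          {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
  bool nb[27];
  std::vector<R_xlen_t> cand;

  // Thinning runs in two phases of directional sub-iterations.
  //
  // Phase A deletes a simple border voxel only when its opposite neighbor
  // along the sub-iteration direction is still object, i.e. only where the
  // object is at least two voxels thick along that direction. This rules
  // out the "zipper" failure of fully sequential thinning, where a
  // one-voxel-thick diagonal ladder is eaten from its end (each deletion
  // is simple, so topology is preserved while the centerline collapses).
  // The price is that diagonally offset one-voxel-thick ridges freeze.
  //
  // Phase B clears those ridges: a voxel may then be deleted when object
  // voxels face each other across it along any of the 13 neighborhood axes
  // (face, edge or corner). Curve endpoints have no such pair, so phase B
  // cannot shorten a clean centerline; it only dissolves redundant
  // parallel ridges, whose leftover one-voxel stubs are handled by
  // graph-level spur pruning.
  // Phase A: distance-ordered directional erosion. At each distance level,
  // simple border voxels are deleted sequentially per direction, but only
  // where the object has an opposite object neighbor along that direction
  // (two voxels thick along d). The support rule prevents the "zipper"
  // failure of fully sequential thinning, where a one-voxel-thick diagonal
  // ladder would be eaten from its end (each deletion simple, topology
  // preserved, centerline collapsed). One-voxel-thick leftovers are then
  // dissolved by phase B, whose 13-axis opposite-pair rule deletes
  // redundant parallel ridges but cannot shorten a clean centerline
  // (curve endpoints have no opposite pair).
  for (size_t lev = 0; lev <= levels.size(); ++lev) {
    bool phaseB = lev == levels.size();
    double lmax = phaseB ? 0.0 : levels[lev];
    bool changed = true;
    while (changed) {
      changed = false;
      for (int d = 0; d < 6; ++d) {
        cand.clear();
        for (int iz = 0; iz < nz; ++iz)
          for (int iy = 0; iy < ny; ++iy)
            for (int ix = 0; ix < nx; ++ix) {
              R_xlen_t i = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
              if (!obj[i]) continue;
              if (!phaseB && edt[i] > lmax) continue;
              if (at(ix + dirs[d][0], iy + dirs[d][1], iz + dirs[d][2]))
                continue; // not a border voxel in this direction
              if (!phaseB &&
                  !at(ix - dirs[d][0], iy - dirs[d][1], iz - dirs[d][2]))
                continue; // 1-thick along d: erode from another direction
              gather(ix, iy, iz, nb);
              int cnt = n26(nb);
              if (cnt <= 1) continue; // endpoint or isolated: keep
              if (phaseB && !has_opposite_pair(nb)) continue;
              if (is_simple(nb)) cand.push_back(i);
            }
        for (size_t k = 0; k < cand.size(); ++k) {
          R_xlen_t i = cand[k];
          int ix = (int)(i % nx), iy = (int)((i / nx) % ny),
              iz = (int)(i / ((R_xlen_t)nx * ny));
          gather(ix, iy, iz, nb);
          int cnt = n26(nb);
          if (cnt <= 1) continue;
          if (!phaseB &&
              !at(ix - dirs[d][0], iy - dirs[d][1], iz - dirs[d][2]))
            continue; // support along d vanished during this sub-iteration
          if (phaseB && !has_opposite_pair(nb)) continue;
          if (!is_simple(nb)) continue; // re-validate against current state
          obj[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = obj[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// parallel-beam radon transform and back-projection (bilinear sampling)
// ---------------------------------------------------------------------------

static inline double pix(const NumericMatrix &img, int i, int j) {
  if (i < 0 || i >= img.nrow() || j < 0 || j >= img.ncol()) return 0.0;
  return img(i, j);
}

// line integrals in pixel units (caller multiplies by pixel size);
// theta in radians; detector bins coincide with the image grid
// [[Rcpp::export(name = ".radon_cpp")]]
NumericMatrix radon_cpp(NumericMatrix img, NumericVector theta) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("slice must be square");
  const int na = theta.size();
  const double c = (n - 1) / 2.0;
  NumericMatrix out(n, na);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(theta[a]), st = std::sin(theta[a]);
    for (int is = 0; is < n; ++is) {
      const double s = is - c;
      double acc = 0.0;
      for (int it = 0; it < n; ++it) {
        const double t = it - c;
        const double x = c + s * ct - t * st;
        const double y = c + s * st + t * ct;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        if (x0 < -1 || x0 > n - 1 || y0 < -1 || y0 > n - 1) continue;
        const double fx = x - x0, fy = y - y0;
        acc += pix(img, x0, y0) * (1 - fx) * (1 - fy) +
               pix(img, x0 + 1, y0) * fx * (1 - fy) +
               pix(img, x0, y0 + 1) * (1 - fx) * fy +
               pix(img, x0 + 1, y0 + 1) * fx * fy;
      }
      out(is, a) = acc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".backproject_cpp")]]
NumericMatrix backproject_cpp(NumericMatrix sino, NumericVector theta, int n) {
  const int nd = sino.nrow();
  const int na = sino.ncol();
  if (theta.size() != na) stop("angle count does not match sinogram");
  const double c = (n - 1) / 2.0;
  const double cd = (nd - 1) / 2.0;
  NumericMatrix out(n, n);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(theta[a]), st = std::sin(theta[a]);
    for (int iy = 0; iy < n; ++iy) {
      const double yc = iy - c;
      for (int ix = 0; ix < n; ++ix) {
        const double s = (ix - c) * ct + yc * st + cd;
        const int s0 = (int)std::floor(s);
        if (s0 < -1 || s0 > nd - 1) continue;
        const double fs = s - s0;
        double v = 0.0;
        if (s0 >= 0) v += sino(s0, a) * (1 - fs);
        if (s0 + 1 < nd) v += sino(s0 + 1, a) * fs;
        out(ix, iy) += v;
      }
    }
  }
  return out;
}
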