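// Voxel-level kernels: Crofton configuration sums, 3D filters, labelling,
// oblique plane resampling. Volumes use axis order (z, y, x) with z the
// fastest-varying index (R column-major), world coordinate = index * spacing.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + (size_t)ny * x);
}

// 2x2x2 configuration index; bit k = dz + 2*dy + 4*dx
static inline int config_at(const int* o, int z, int y, int x, int nz, int ny) {
  int c = 0;
  for (int dx = 0; dx < 2; ++dx)
    for (int dy = 0; dy < 2; ++dy)
      for (int dz = 0; dz < 2; ++dz)
        if (o[idx3(z + dz, y + dy, x + dx, nz, ny)])
          c |= 1 << (dz + 2 * dy + 4 * dx);
  return c;
}

// [[Rcpp::export]]
double cpp_crofton_sum(LogicalVector occ, NumericVector table) {
  IntegerVector d = occ.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const int* o = LOGICAL(occ);
  const double* tab = REAL(table);
  double s = 0.0;
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z)
        s += tab[config_at(o, z, y, x, nz, ny)];
  return s;
}

// Per-configuration cell counts over the whole volume (for LUT diagnostics).
// [[Rcpp::export]]
NumericVector cpp_config_histogram(LogicalVector occ) {
  IntegerVector d = occ.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const int* o = LOGICAL(occ);
  NumericVector h(256);
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z)
        h[config_at(o, z, y, x, nz, ny)] += 1.0;
  return h;
}

// Crofton sum restricted to 2x2x2 cells whose center lies in the half-open
// oriented prism: frame coords t_u in [-hu, hu), t_v in [-hv, hv),
// t_w in [wlo, whi). The center rule makes the number of counted cells per
// lattice row exactly side/spacing for commensurate rectangles (unbiased at
// every ROI size). All world quantities in micrometres, vectors given as
// (z, y, x) components.
// [[Rcpp::export]]
double cpp_crofton_prism(LogicalVector occ, NumericVector table,
                         NumericVector spacing, NumericVector center,
                         NumericVector u, NumericVector v, NumericVector n,
                         double hu, double hv, double wlo, double whi) {
  IntegerVector d = occ.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const int* o = LOGICAL(occ);
  const double* tab = REAL(table);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];

  // index bounding box of the prism (conservative)
  double rad[3];
  for (int a = 0; a < 3; ++a) {
    double wext = std::max(std::fabs(wlo), std::fabs(whi));
    rad[a] = hu * std::fabs(u[a]) + hv * std::fabs(v[a]) + wext * std::fabs(n[a]);
  }
  int z0 = std::max(0, (int)std::floor((center[0] - rad[0]) / sz) - 1);
  int z1 = std::min(nz - 2, (int)std::ceil((center[0] + rad[0]) / sz));
  int y0 = std::max(0, (int)std::floor((center[1] - rad[1]) / sy) - 1);
  int y1 = std::min(ny - 2, (int)std::ceil((center[1] + rad[1]) / sy));
  int x0 = std::max(0, (int)std::floor((center[2] - rad[2]) / sx) - 1);
  int x1 = std::min(nx - 2, (int)std::ceil((center[2] + rad[2]) / sx));

  // frame-coordinate increments per voxel step along each lattice axis
  double uz = u[0] * sz, uy = u[1] * sy, ux = u[2] * sx;
  double vz = v[0] * sz, vy = v[1] * sy, vx = v[2] * sx;
  double wz = n[0] * sz, wy = n[1] * sy, wx = n[2] * sx;
  double cu = center[0] * u[0] + center[1] * u[1] + center[2] * u[2];
  double cv = center[0] * v[0] + center[1] * v[1] + center[2] * v[2];
  double cw = center[0] * n[0] + center[1] * n[1] + center[2] * n[2];

  double s = 0.0;
  for (int x = x0; x <= x1; ++x)
    for (int y = y0; y <= y1; ++y)
      for (int z = z0; z <= z1; ++z) {
        int cfg = config_at(o, z, y, x, nz, ny);
        if (tab[cfg] == 0.0) continue;  // uniform or zero-contribution cell
        double tu = (z + 0.5) * uz + (y + 0.5) * uy + (x + 0.5) * ux - cu;
        double tv = (z + 0.5) * vz + (y + 0.5) * vy + (x + 0.5) * vx - cv;
        double tw = (z + 0.5) * wz + (y + 0.5) * wy + (x + 0.5) * wx - cw;
        if (tu >= -hu && tu < hu && tv >= -hv && tv < hv &&
            tw >= wlo && tw < whi)
          s += tab[cfg];
      }
  return s;
}

// 3D non-local means, cubic patches and search windows, replicate borders.
// [[Rcpp::export]]
NumericVector cpp_nlm3d(NumericVector vol, int patch_r, int search_r, double h) {
  IntegerVector d = vol.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const double* in = REAL(vol);
  NumericVector out(vol.size());
  out.attr("dim") = d;
  double* op = REAL(out);
  int pr = patch_r, sr = search_r;
  int npatch = (2 * pr + 1) * (2 * pr + 1) * (2 * pr + 1);
  double h2n = h * h * npatch;

  auto clampi = [](int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); };

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double wsum = 0.0, acc = 0.0;
        for (int qx = x - sr; qx <= x + sr; ++qx)
          for (int qy = y - sr; qy <= y + sr; ++qy)
            for (int qz = z - sr; qz <= z + sr; ++qz) {
              double ssd = 0.0;
              for (int px = -pr; px <= pr; ++px)
                for (int py = -pr; py <= pr; ++py)
                  for (int pz = -pr; pz <= pr; ++pz) {
                    double a = in[idx3(clampi(z + pz, nz), clampi(y + py, ny),
                                       clampi(x + px, nx), nz, ny)];
                    double b = in[idx3(clampi(qz + pz, nz), clampi(qy + py, ny),
                                       clampi(qx + px, nx), nz, ny)];
                    double diff = a - b;
                    ssd += diff * diff;
                  }
              double w = std::exp(-ssd / h2n);
              wsum += w;
              acc += w * in[idx3(clampi(qz, nz), clampi(qy, ny), clampi(qx, nx),
                                 nz, ny)];
            }
        op[idx3(z, y, x, nz, ny)] = acc / wsum;
      }
  return out;
}

// 3D median filter over a cubic window of radius r, clamped at borders.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, int r) {
  IntegerVector d = vol.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const double* in = REAL(vol);
  NumericVector out(vol.size());
  out.attr("dim") = d;
  double* op = REAL(out);
  std::vector<double> buf;
  buf.reserve((2 * r + 1) * (2 * r + 1) * (2 * r + 1));
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int qx = std::max(0, x - r); qx <= std::min(nx - 1, x + r); ++qx)
          for (int qy = std::max(0, y - r); qy <= std::min(ny - 1, y + r); ++qy)
            for (int qz = std::max(0, z - r); qz <= std::min(nz - 1, z + r); ++qz)
              buf.push_back(in[idx3(qz, qy, qx, nz, ny)]);
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        op[idx3(z, y, x, nz, ny)] = med;
      }
  return out;
}

// Separable convolution along one axis (0 = z, 1 = y, 2 = x), replicate borders.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, NumericVector kernel, int axis) {
  IntegerVector d = vol.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const double* in = REAL(vol);
  const double* k = REAL(kernel);
  int kr = (kernel.size() - 1) / 2;
  NumericVector out(vol.size());
  out.attr("dim") = d;
  double* op = REAL(out);
  int nax[3] = {nz, ny, nx};
  int n = nax[axis];
  auto clampi = [n](int i) { return i < 0 ? 0 : (i >= n ? n - 1 : i); };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        for (int t = -kr; t <= kr; ++t) {
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz = clampi(z + t);
          else if (axis == 1) yy = clampi(y + t);
          else xx = clampi(x + t);
          acc += k[t + kr] * in[idx3(zz, yy, xx, nz, ny)];
        }
        op[idx3(z, y, x, nz, ny)] = acc;
      }
  return out;
}

// Connected-component labelling, 26-connectivity, BFS.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector occ) {
  IntegerVector d = occ.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const int* o = LOGICAL(occ);
  size_t ntot = (size_t)nz * ny * nx;
  IntegerVector lab((R_xlen_t)ntot);
  lab.attr("dim") = d;
  int* L = INTEGER(lab);
  std::fill(L, L + ntot, 0);
  std::vector<int> queue;
  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i0 = idx3(z, y, x, nz, ny);
        if (!o[i0] || L[i0]) continue;
        ++next;
        L[i0] = next;
        queue.clear();
        queue.push_back(i0);
        while (!queue.empty()) {
          int i = queue.back();
          queue.pop_back();
          int cz = i % nz, rem = i / nz;
          int cy = rem % ny, cx = rem / ny;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                int zz = cz + dz, yy = cy + dy, xx = cx + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                    xx < 0 || xx >= nx)
                  continue;
                int j = idx3(zz, yy, xx, nz, ny);
                if (o[j] && !L[j]) {
                  L[j] = next;
                  queue.push_back(j);
                }
              }
        }
      }
  return lab;
}

// Binary erosion by a cubic structuring element of radius r (out-of-volume
// treated as background, so borders erode).
// [[Rcpp::export]]
LogicalVector cpp_erode3d(LogicalVector occ, int r) {
  IntegerVector d = occ.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const int* o = LOGICAL(occ);
  LogicalVector out(occ.size());
  out.attr("dim") = d;
  int* op = LOGICAL(out);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool all = true;
        for (int qx = x - r; qx <= x + r && all; ++qx)
          for (int qy = y - r; qy <= y + r && all; ++qy)
            for (int qz = z - r; qz <= z + r && all; ++qz) {
              if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                  qz < 0 || qz >= nz || !o[idx3(qz, qy, qx, nz, ny)])
                all = false;
            }
        op[idx3(z, y, x, nz, ny)] = all;
      }
  return out;
}

// Topmost tissue index along z for each lateral column; -1 when empty.
// [[Rcpp::export]]
IntegerMatrix cpp_height_field(LogicalVector occ) {
  IntegerVector d = occ.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const int* o = LOGICAL(occ);
  IntegerMatrix H(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int top = -1;
      for (int z = nz - 1; z >= 0; --z)
        if (o[idx3(z, y, x, nz, ny)]) { top = z; break; }
      H(y, x) = top;
    }
  return H;
}

// Resample an oriented plane from a volume. Sample (i, j) lies at
// point + (i - (nu-1)/2) * ps * u + (j - (nv-1)/2) * ps * v, i fastest.
// interp: 0 = nearest, 1 = trilinear. Out-of-volume samples return NA.
// [[Rcpp::export]]
NumericMatrix cpp_resample_plane(NumericVector vol, NumericVector spacing,
                                 NumericVector point, NumericVector u,
                                 NumericVector v, int nu, int nv, double ps,
                                 int interp) {
  IntegerVector d = vol.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  const double* in = REAL(vol);
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  NumericMatrix out(nu, nv);
  double cu = (nu - 1) / 2.0, cv = (nv - 1) / 2.0;
  for (int j = 0; j < nv; ++j)
    for (int i = 0; i < nu; ++i) {
      double pz = point[0] + (i - cu) * ps * u[0] + (j - cv) * ps * v[0];
      double py = point[1] + (i - cu) * ps * u[1] + (j - cv) * ps * v[1];
      double px = point[2] + (i - cu) * ps * u[2] + (j - cv) * ps * v[2];
      double fz = pz / sz, fy = py / sy, fx = px / sx;
      if (interp == 0) {
        int z = (int)std::lround(fz), y = (int)std::lround(fy),
            x = (int)std::lround(fx);
        out(i, j) = (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
                        ? NA_REAL
                        : in[idx3(z, y, x, nz, ny)];
      } else {
        int z0 = (int)std::floor(fz), y0 = (int)std::floor(fy),
            x0 = (int)std::floor(fx);
        if (z0 < 0 || z0 >= nz - 1 || y0 < 0 || y0 >= ny - 1 || x0 < 0 ||
            x0 >= nx - 1) {
          // tolerate exact upper-boundary samples
          if (fz >= 0 && fz <= nz - 1 && fy >= 0 && fy <= ny - 1 && fx >= 0 &&
              fx <= nx - 1) {
            z0 = std::min(z0, nz - 2); y0 = std::min(y0, ny - 2);
            x0 = std::min(x0, nx - 2);
          } else {
            out(i, j) = NA_REAL;
            continue;
          }
        }
        double tz = fz - z0, ty = fy - y0, tx = fx - x0;
        double acc = 0.0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy)
            for (int dz = 0; dz < 2; ++dz) {
              double w = (dz ? tz : 1 - tz) * (dy ? ty : 1 - ty) *
                         (dx ? tx : 1 - tx);
              acc += w * in[idx3(z0 + dz, y0 + dy, x0 + dx, nz, ny)];
            }
        out(i, j) = acc;
      }
    }
  return out;
}

// Columnar occupancy fill: voxel (z,y,x) is tissue iff z*sz < T(y,x).
// The mucosal phantoms are columnar solids (open crypt wells), so a single
// top-height map per lateral column describes them exactly.
// [[Rcpp::export]]
LogicalVector cpp_occ_from_height(NumericMatrix T, double sz, int nz) {
  int ny = T.nrow(), nx = T.ncol();
  LogicalVector occ((R_xlen_t)nz * ny * nx);
  occ.attr("dim") = IntegerVector::create(nz, ny, nx);
  int* o = LOGICAL(occ);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double t = T(y, x);
      int ztop = (int)std::ceil(t / sz);  // first z with z*sz >= t
      if (ztop > nz) ztop = nz;
      if (ztop < 0) ztop = 0;
      // handle exact boundary: z*sz < t strictly
      while (ztop > 0 && (ztop - 1) * sz >= t) --ztop;
      int* col = o + idx3(0, y, x, nz, ny);
      for (int z = 0; z < ztop; ++z) col[z] = 1;
      for (int z = ztop; z < nz; ++z) col[z] = 0;
    }
  return occ;
}

// [[Rcpp::export]]
NumericVector cpp_as_double(LogicalVector occ) {
  NumericVector out(occ.size());
  out.attr("dim") = occ.attr("dim");
  const int* o = LOGICAL(occ);
  double* p = REAL(out);
  for (R_xlen_t i = 0; i < occ.size(); ++i) p[i] = o[i] ? 1.0 : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_map_levels(LogicalVector occ, double background, double tissue) {
  NumericVector out(occ.size());
  out.attr("dim") = occ.attr("dim");
  const int* o = LOGICAL(occ);
  double* p = REAL(out);
  for (R_xlen_t i = 0; i < occ.size(); ++i) p[i] = o[i] ? tissue : background;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_threshold(NumericVector vals, double threshold, bool bright) {
  LogicalVector out(vals.size());
  out.attr("dim") = vals.attr("dim");
  const double* v = REAL(vals);
  int* o = LOGICAL(out);
  for (R_xlen_t i = 0; i < vals.size(); ++i)
    o[i] = bright ? (v[i] >= threshold) : (v[i] < threshold);
  return out;
}

// scale integer sample values into [0,1] for TIFF writing; the half-step
// offset guards against truncation in the writer, clamped to [0,1]
// [[Rcpp::export]]
NumericVector cpp_scale01(NumericVector vals, double factor) {
  NumericVector out(vals.size());
  out.attr("dim") = vals.attr("dim");
  const double* v = REAL(vals);
  double* p = REAL(out);
  for (R_xlen_t i = 0; i < vals.size(); ++i) {
    double s = (v[i] + 0.5) * factor;
    p[i] = s < 0 ? 0 : (s > 1 ? 1 : s);
  }
  return out;
}
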