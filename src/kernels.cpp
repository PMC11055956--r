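// Low-level voxel kernels for 3D stack processing.
//
// All volumes are R arrays with dim = (nz, ny, nx); the linear index of
// voxel (iz, iy, ix) is iz + nz * (iy + ny * ix) (0-based here, 1-based in
// R). Physical spacing is passed per axis in micrometres; outside the
// volume counts as background everywhere.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>
#include <cstring>

using namespace Rcpp;

static const double BIG = 1e30;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

struct Dims {
  int nz, ny, nx;
  long n() const { return (long)nz * ny * nx; }
  long idx(int z, int y, int x) const { return (long)z + (long)nz * ((long)y + (long)ny * x); }
};

static Dims get_dims(const RObject& v) {
  IntegerVector d = v.attr("dim");
  if (d.size() != 3) stop("expected a 3-D array");
  Dims dm;
  dm.nz = d[0]; dm.ny = d[1]; dm.nx = d[2];
  return dm;
}

// ---------------------------------------------------------------- median ---

// Exact sliding-histogram median for integer-valued volumes in [0, nbins).
// The window multiset difference between consecutive z positions
// telescopes even with replicated (clamped) edges, so one uniform slide
// handles the whole column.
static void median_box_hist(const double* v, double* out, const Dims& d,
                            int rz, int ry, int rx, int nbins) {
  int m = (2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1);
  int ncols = (2 * ry + 1) * (2 * rx + 1);
  int half = m / 2;  // 0-based index of the lower median
  std::vector<long> colbase(ncols);
  std::vector<int> hist(nbins);
  for (int x = 0; x < d.nx; ++x) {
    for (int y = 0; y < d.ny; ++y) {
      int k = 0;
      for (int ox = -rx; ox <= rx; ++ox) {
        int xx = clampi(x + ox, 0, d.nx - 1);
        for (int oy = -ry; oy <= ry; ++oy) {
          int yy = clampi(y + oy, 0, d.ny - 1);
          colbase[k++] = d.idx(0, yy, xx);
        }
      }
      std::fill(hist.begin(), hist.end(), 0);
      for (int cb = 0; cb < ncols; ++cb)
        for (int oz = -rz; oz <= rz; ++oz)
          ++hist[(int)v[colbase[cb] + clampi(oz, 0, d.nz - 1)]];
      for (int z = 0; z < d.nz; ++z) {
        if (z > 0) {
          for (int cb = 0; cb < ncols; ++cb) {
            --hist[(int)v[colbase[cb] + clampi(z - 1 - rz, 0, d.nz - 1)]];
            ++hist[(int)v[colbase[cb] + clampi(z + rz, 0, d.nz - 1)]];
          }
        }
        int cum = 0, b = 0;
        while (cum + hist[b] <= half) cum += hist[b++];
        out[d.idx(z, y, x)] = b;
      }
    }
  }
}

// Box median filter with half-widths (rz, ry, rx) and replicated edges.
// Integer-valued 8/16-bit-range data takes an exact histogram fast path.
// [[Rcpp::export]]
NumericVector cpp_median_box(NumericVector vol, int rz, int ry, int rx) {
  Dims d = get_dims(vol);
  NumericVector out(vol.size());
  out.attr("dim") = vol.attr("dim");
  if (rz == 0 && ry == 0 && rx == 0) {
    std::copy(vol.begin(), vol.end(), out.begin());
    return out;
  }
  bool integral = true;
  double vmax = 0;
  for (long i = 0; i < (long)vol.size(); ++i) {
    double x = vol[i];
    if (x < 0 || x != std::floor(x)) { integral = false; break; }
    if (x > vmax) vmax = x;
  }
  if (integral && vmax < 4096) {
    median_box_hist(vol.begin(), out.begin(), d, rz, ry, rx, (int)vmax + 1);
    return out;
  }
  int m = (2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1);
  std::vector<double> buf(m);
  const double* v = vol.begin();
  // precomputed linear offsets for the interior fast path
  std::vector<long> off;
  off.reserve(m);
  for (int ox = -rx; ox <= rx; ++ox)
    for (int oy = -ry; oy <= ry; ++oy)
      for (int oz = -rz; oz <= rz; ++oz)
        off.push_back((long)oz + (long)d.nz * ((long)oy + (long)d.ny * ox));
  for (int x = 0; x < d.nx; ++x) {
    bool xin = x >= rx && x < d.nx - rx;
    for (int y = 0; y < d.ny; ++y) {
      bool yin = xin && y >= ry && y < d.ny - ry;
      for (int z = 0; z < d.nz; ++z) {
        long c = d.idx(z, y, x);
        if (yin && z >= rz && z < d.nz - rz) {
          for (int k = 0; k < m; ++k) buf[k] = v[c + off[k]];
        } else {
          int k = 0;
          for (int ox = -rx; ox <= rx; ++ox) {
            int xx = clampi(x + ox, 0, d.nx - 1);
            for (int oy = -ry; oy <= ry; ++oy) {
              int yy = clampi(y + oy, 0, d.ny - 1);
              for (int oz = -rz; oz <= rz; ++oz) {
                int zz = clampi(z + oz, 0, d.nz - 1);
                buf[k++] = v[d.idx(zz, yy, xx)];
              }
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[c] = buf[m / 2];
      }
    }
  }
  return out;
}

// ------------------------------------------------------------------ blur ---

static void blur_axis(std::vector<double>& src, std::vector<double>& dst,
                      const Dims& d, int axis, double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) { dst = src; return; }
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  int len = axis == 0 ? d.nz : (axis == 1 ? d.ny : d.nx);
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        double acc = 0.0;
        int pos = axis == 0 ? z : (axis == 1 ? y : x);
        for (int i = -r; i <= r; ++i) {
          int p = clampi(pos + i, 0, len - 1);
          long j = axis == 0 ? d.idx(p, y, x) : (axis == 1 ? d.idx(z, p, x) : d.idx(z, y, p));
          acc += k[i + r] * src[j];
        }
        dst[d.idx(z, y, x)] = acc;
      }
}

// Separable Gaussian blur; sigmas are in voxel units per axis, <= 0 skips
// the axis. Edges replicate.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, double sz, double sy, double sx) {
  Dims d = get_dims(vol);
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  double sig[3] = {sz, sy, sx};
  for (int axis = 0; axis < 3; ++axis) {
    if (sig[axis] > 0) {
      blur_axis(a, b, d, axis, sig[axis]);
      std::swap(a, b);
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = vol.attr("dim");
  return out;
}

// ---------------------------------------------------- connected components ---

// Label foreground components; connectivity 6 or 26. Background label 0.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, int connectivity) {
  Dims d = get_dims(mask);
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = mask.attr("dim");
  std::vector<int> offz, offy, offx;
  for (int ox = -1; ox <= 1; ++ox)
    for (int oy = -1; oy <= 1; ++oy)
      for (int oz = -1; oz <= 1; ++oz) {
        if (ox == 0 && oy == 0 && oz == 0) continue;
        int manh = std::abs(ox) + std::abs(oy) + std::abs(oz);
        if (connectivity == 6 && manh != 1) continue;
        offz.push_back(oz); offy.push_back(oy); offx.push_back(ox);
      }
  int nb = offz.size();
  int cur = 0;
  std::vector<long> stack;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        long i = d.idx(z, y, x);
        if (!mask[i] || lab[i]) continue;
        ++cur;
        lab[i] = cur;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          long j = stack.back(); stack.pop_back();
          int jz = j % d.nz;
          long r = j / d.nz;
          int jy = r % d.ny, jx = r / d.ny;
          for (int q = 0; q < nb; ++q) {
            int zz = jz + offz[q], yy = jy + offy[q], xx = jx + offx[q];
            if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
            long jj = d.idx(zz, yy, xx);
            if (mask[jj] && !lab[jj]) { lab[jj] = cur; stack.push_back(jj); }
          }
        }
      }
  return lab;
}

// ------------------------------------------------------------------- EDT ---

// Felzenszwalb & Huttenlocher 1-D squared distance transform on samples at
// positions i * w.
static void dt1d(std::vector<double>& f, std::vector<double>& dout,
                 std::vector<int>& v, std::vector<double>& zb, int n, double w) {
  const double NEG_INF = -std::numeric_limits<double>::infinity();
  const double POS_INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = NEG_INF;
  zb[1] = POS_INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = POS_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (zb[k + 1] < xq) ++k;
    double xv = v[k] * w;
    dout[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Anisotropic Euclidean distance (µm, voxel centre to voxel centre) from
// every voxel to the nearest TRUE voxel of `src`. All-false source gives
// +Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector src, double dz, double dy, double dx) {
  Dims d = get_dims(src);
  long n = d.n();
  std::vector<double> g(n);
  for (long i = 0; i < n; ++i) g[i] = src[i] ? 0.0 : BIG;

  int maxlen = std::max(d.nz, std::max(d.ny, d.nx));
  std::vector<double> f(maxlen), dd(maxlen), zb(maxlen + 1);
  std::vector<int> v(maxlen);

  // z axis
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y) {
      for (int z = 0; z < d.nz; ++z) f[z] = g[d.idx(z, y, x)];
      dt1d(f, dd, v, zb, d.nz, dz);
      for (int z = 0; z < d.nz; ++z) g[d.idx(z, y, x)] = dd[z];
    }
  // y axis
  for (int x = 0; x < d.nx; ++x)
    for (int z = 0; z < d.nz; ++z) {
      for (int y = 0; y < d.ny; ++y) f[y] = g[d.idx(z, y, x)];
      dt1d(f, dd, v, zb, d.ny, dy);
      for (int y = 0; y < d.ny; ++y) g[d.idx(z, y, x)] = dd[y];
    }
  // x axis
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y) {
      for (int x = 0; x < d.nx; ++x) f[x] = g[d.idx(z, y, x)];
      dt1d(f, dd, v, zb, d.nx, dx);
      for (int x = 0; x < d.nx; ++x) g[d.idx(z, y, x)] = dd[x];
    }

  NumericVector out(n);
  for (long i = 0; i < n; ++i)
    out[i] = g[i] >= BIG ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = src.attr("dim");
  return out;
}

// --------------------------------------------------------- skeletonization ---

// 27-cell cube adjacency tables for the simple-point test, built once.
namespace cube {
  static bool adj26[27][27];
  static bool adj6[27][27];
  static bool in18[27];
  static bool face[27];   // 6-neighbours of the centre
  static bool built = false;

  static void build() {
    if (built) return;
    int cz[27], cy[27], cx[27];
    for (int c = 0; c < 27; ++c) {
      cz[c] = c % 3 - 1;
      cy[c] = (c / 3) % 3 - 1;
      cx[c] = c / 9 - 1;
      int manh = std::abs(cz[c]) + std::abs(cy[c]) + std::abs(cx[c]);
      in18[c] = manh >= 1 && manh <= 2;
      face[c] = manh == 1;
    }
    for (int a = 0; a < 27; ++a)
      for (int b = 0; b < 27; ++b) {
        int ddz = std::abs(cz[a] - cz[b]), ddy = std::abs(cy[a] - cy[b]), ddx = std::abs(cx[a] - cx[b]);
        int cheb = std::max(ddz, std::max(ddy, ddx));
        int manh = ddz + ddy + ddx;
        adj26[a][b] = (a != b) && cheb == 1;
        adj6[a][b] = (a != b) && manh == 1;
      }
    built = true;
  }
}

// Extract the 3x3x3 neighbourhood of voxel i into cube[] (centre included).
static inline void fill_cube(const std::vector<char>& m, const Dims& d,
                             int z, int y, int x, bool cubev[27]) {
  for (int c = 0; c < 27; ++c) {
    int zz = z + c % 3 - 1, yy = y + (c / 3) % 3 - 1, xx = x + c / 9 - 1;
    cubev[c] = zz >= 0 && zz < d.nz && yy >= 0 && yy < d.ny && xx >= 0 && xx < d.nx &&
               m[d.idx(zz, yy, xx)];
  }
}

// A border voxel is simple iff deleting it preserves local topology:
// exactly one 26-component of foreground in N26, and exactly one
// 6-component of background in N18 that touches a face neighbour.
static bool is_simple(const bool cubev[27]) {
  using namespace cube;
  // foreground 26-components in N26 (exclude centre 13)
  int comp[27];
  for (int c = 0; c < 27; ++c) comp[c] = -1;
  int ncomp_fg = 0;
  int stack[27], sp;
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !cubev[c] || comp[c] >= 0) continue;
    comp[c] = ncomp_fg;
    sp = 0; stack[sp++] = c;
    while (sp) {
      int a = stack[--sp];
      for (int b = 0; b < 27; ++b)
        if (b != 13 && cubev[b] && comp[b] < 0 && adj26[a][b]) {
          comp[b] = ncomp_fg;
          stack[sp++] = b;
        }
    }
    ++ncomp_fg;
  }
  if (ncomp_fg != 1) return false;

  // background 6-components within N18 touching a face neighbour
  for (int c = 0; c < 27; ++c) comp[c] = -1;
  int ncomp_bg = 0;
  for (int c = 0; c < 27; ++c) {
    if (!in18[c] || cubev[c] || comp[c] >= 0) continue;
    bool touches = false;
    comp[c] = ncomp_bg;
    sp = 0; stack[sp++] = c;
    while (sp) {
      int a = stack[--sp];
      if (face[a]) touches = true;
      for (int b = 0; b < 27; ++b)
        if (in18[b] && !cubev[b] && comp[b] < 0 && adj6[a][b]) {
          comp[b] = ncomp_bg;
          stack[sp++] = b;
        }
    }
    if (touches) ++ncomp_bg;
  }
  return ncomp_bg == 1;
}

static inline int fg_neighbour_count(const bool cubev[27]) {
  int n = 0;
  for (int c = 0; c < 27; ++c)
    if (c != 13 && cubev[c]) ++n;
  return n;
}

// Sequential curve thinning with six directional sub-iterations. Endpoints
// (<= 1 foreground neighbour) are preserved, so tube tips survive down to a
// one-voxel curve.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask) {
  cube::build();
  Dims d = get_dims(mask);
  long n = d.n();
  std::vector<char> m(n);
  for (long i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  // active voxel list (foreground only)
  std::vector<long> fg;
  for (long i = 0; i < n; ++i)
    if (m[i]) fg.push_back(i);

  const int dirz[6] = {1, -1, 0, 0, 0, 0};
  const int diry[6] = {0, 0, 1, -1, 0, 0};
  const int dirx[6] = {0, 0, 0, 0, 1, -1};

  bool cubev[27];
  std::vector<long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (long i : fg) {
        if (!m[i]) continue;
        int z = i % d.nz;
        long r = i / d.nz;
        int y = r % d.ny, x = r / d.ny;
        int zz = z + dirz[dir], yy = y + diry[dir], xx = x + dirx[dir];
        bool borders = zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx ||
                       !m[d.idx(zz, yy, xx)];
        if (!borders) continue;
        fill_cube(m, d, z, y, x, cubev);
        if (fg_neighbour_count(cubev) <= 1) continue;  // endpoint
        if (is_simple(cubev)) cand.push_back(i);
      }
      // delete sequentially, re-checking so topology is never broken
      for (long i : cand) {
        int z = i % d.nz;
        long r = i / d.nz;
        int y = r % d.ny, x = r / d.ny;
        fill_cube(m, d, z, y, x, cubev);
        if (fg_neighbour_count(cubev) <= 1) continue;
        if (!is_simple(cubev)) continue;
        m[i] = 0;
        changed = true;
      }
    }
    // compact the active list occasionally
    std::vector<long> keep;
    keep.reserve(fg.size());
    for (long i : fg)
      if (m[i]) keep.push_back(i);
    fg.swap(keep);
  }

  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = mask.attr("dim");
  return out;
}

// Number of foreground 26-neighbours for every voxel of a mask.
// [[Rcpp::export]]
IntegerVector cpp_neighbour_count(LogicalVector mask) {
  Dims d = get_dims(mask);
  IntegerVector out(mask.size(), 0);
  out.attr("dim") = mask.attr("dim");
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        long i = d.idx(z, y, x);
        if (!mask[i]) continue;
        int cnt = 0;
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = -1; oz <= 1; ++oz) {
              if (!ox && !oy && !oz) continue;
              int zz = z + oz, yy = y + oy, xx = x + ox;
              if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
              if (mask[d.idx(zz, yy, xx)]) ++cnt;
            }
        out[i] = cnt;
      }
  return out;
}

// ---------------------------------------------------------- local maxima ---

// TRUE where vol > threshold and >= every 26-neighbour.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector vol, double threshold) {
  Dims d = get_dims(vol);
  LogicalVector out(vol.size(), false);
  out.attr("dim") = vol.attr("dim");
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        long i = d.idx(z, y, x);
        double v = vol[i];
        if (!(v > threshold)) continue;
        bool ok = true;
        for (int ox = -1; ox <= 1 && ok; ++ox)
          for (int oy = -1; oy <= 1 && ok; ++oy)
            for (int oz = -1; oz <= 1 && ok; ++oz) {
              if (!ox && !oy && !oz) continue;
              int zz = z + oz, yy = y + oy, xx = x + ox;
              if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
              if (vol[d.idx(zz, yy, xx)] > v) ok = false;
            }
        if (ok) out[i] = true;
      }
  return out;
}

// ---------------------------------------------------------- ball stamping ---

// Render spheres (µm centres/radii) into a volume by taking the voxelwise
// maximum with `value`. Used for tubes (dense centreline samples) and cell
// orbs. Returns the number of spheres that had to be clipped at the bounds.
// [[Rcpp::export]]
int cpp_stamp_balls(NumericVector vol, NumericMatrix centers, NumericVector radii,
                    double dz, double dy, double dx, double value) {
  Dims d = get_dims(vol);
  int clipped = 0;
  for (int s = 0; s < centers.nrow(); ++s) {
    double cz = centers(s, 0), cy = centers(s, 1), cx = centers(s, 2);
    double r = radii[s];
    int z0 = (int)std::floor((cz - r) / dz), z1 = (int)std::ceil((cz + r) / dz);
    int y0 = (int)std::floor((cy - r) / dy), y1 = (int)std::ceil((cy + r) / dy);
    int x0 = (int)std::floor((cx - r) / dx), x1 = (int)std::ceil((cx + r) / dx);
    if (z0 < 0 || y0 < 0 || x0 < 0 || z1 >= d.nz || y1 >= d.ny || x1 >= d.nx) ++clipped;
    z0 = clampi(z0, 0, d.nz - 1); z1 = clampi(z1, 0, d.nz - 1);
    y0 = clampi(y0, 0, d.ny - 1); y1 = clampi(y1, 0, d.ny - 1);
    x0 = clampi(x0, 0, d.nx - 1); x1 = clampi(x1, 0, d.nx - 1);
    double r2 = r * r;
    for (int x = x0; x <= x1; ++x) {
      double ex = x * dx - cx;
      for (int y = y0; y <= y1; ++y) {
        double ey = y * dy - cy;
        for (int z = z0; z <= z1; ++z) {
          double ez = z * dz - cz;
          if (ex * ex + ey * ey + ez * ez <= r2) {
            long i = d.idx(z, y, x);
            if (vol[i] < value) vol[i] = value;
          }
        }
      }
    }
  }
  return clipped;
}
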