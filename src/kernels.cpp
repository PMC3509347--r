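// Low-level numeric kernels for 3D volumes.
//
// Conventions shared with the R side:
//  - volumes are column-major 3D arrays, 0-based voxel indices here;
//  - deformation fields are [nx, ny, nz, 3] arrays of displacements in
//    voxel units of the fixed grid: out(x) = in(x + disp(x));
//  - out-of-bounds sampling either replicates the nearest edge voxel
//    (scalar images) or returns a constant background (label maps).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double sample_trilinear(const double* v, int nx, int ny, int nz,
                                      double x, double y, double z,
                                      bool edge, double bg) {
  if (!edge) {
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
      return bg;
  }
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1;
  if (y > ny - 1) y = ny - 1;
  if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = clampi(x0 + 1, 0, nx - 1);
  int y1 = clampi(y0 + 1, 0, ny - 1);
  int z1 = clampi(z0 + 1, 0, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
#define V(i, j, k) v[(i) * sx + (j) * sy + (k) * sz]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double sample_nearest(const double* v, int nx, int ny, int nz,
                                    double x, double y, double z,
                                    bool edge, double bg) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
    if (!edge) return bg;
    i = clampi(i, 0, nx - 1); j = clampi(j, 0, ny - 1); k = clampi(k, 0, nz - 1);
  }
  return v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

static IntegerVector get_dim3(const NumericVector& v) {
  IntegerVector d = v.attr("dim");
  if (d.size() < 3) stop("expected a 3D (or 4D field) array");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, NumericVector disp,
                       bool nearest, bool edge, double bg) {
  IntegerVector d = get_dim3(vol);
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (disp.size() != 3 * n) stop("deformation field does not match volume grid");
  NumericVector out(n);
  const double* v = vol.begin();
  const double* dp = disp.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + dp[idx], y = j + dp[idx + n], z = k + dp[idx + 2 * n];
        out[idx] = nearest ? sample_nearest(v, nx, ny, nz, x, y, z, edge, bg)
                           : sample_trilinear(v, nx, ny, nz, x, y, z, edge, bg);
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Sample input at M %*% x + t (voxel coordinates), used for rigid transforms.
// [[Rcpp::export]]
NumericVector cpp_affine_warp(NumericVector vol, NumericMatrix M, NumericVector t,
                              IntegerVector odim, bool nearest, bool edge, double bg) {
  IntegerVector d = get_dim3(vol);
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* v = vol.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + t[0];
        double y = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + t[1];
        double z = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + t[2];
        out[idx] = nearest ? sample_nearest(v, nx, ny, nz, x, y, z, edge, bg)
                           : sample_trilinear(v, nx, ny, nz, x, y, z, edge, bg);
      }
  out.attr("dim") = odim;
  return out;
}

// Separable Gaussian smoothing, sigma per axis in voxel units, edge replication.
static void gauss_axis(std::vector<double>& buf, int nx, int ny, int nz,
                       int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int r = -radius; r <= radius; ++r) {
    kern[r + radius] = std::exp(-0.5 * r * r / (sigma * sigma));
    s += kern[r + radius];
  }
  for (double& k : kern) k /= s;
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  int na = n[axis];
  R_xlen_t sa = stride[axis];
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(na);
  const double* kp = kern.data();
  double* lp = line.data();
  int lo_end = std::min(radius, na);
  int hi_start = std::max(na - radius, lo_end);
  for (int q = 0; q < n[b2]; ++q)
    for (int p = 0; p < n[b1]; ++p) {
      R_xlen_t base = p * stride[b1] + q * stride[b2];
      for (int i = 0; i < na; ++i) lp[i] = buf[base + i * sa];
      for (int i = 0; i < lo_end; ++i) {
        double acc = 0;
        for (int r = -radius; r <= radius; ++r)
          acc += kp[r + radius] * lp[clampi(i + r, 0, na - 1)];
        buf[base + i * sa] = acc;
      }
      for (int i = lo_end; i < hi_start; ++i) {
        double acc = 0;
        const double* c = lp + i - radius;
        for (int r = 0; r <= 2 * radius; ++r) acc += kp[r] * c[r];
        buf[base + i * sa] = acc;
      }
      for (int i = hi_start; i < na; ++i) {
        double acc = 0;
        for (int r = -radius; r <= radius; ++r)
          acc += kp[r + radius] * lp[clampi(i + r, 0, na - 1)];
        buf[base + i * sa] = acc;
      }
    }
}

// Smooth all three components of a deformation field with one sigma.
// [[Rcpp::export]]
NumericVector cpp_smooth_field(NumericVector disp, IntegerVector dim,
                               double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(clone(disp));
  if (sigma > 0)
    for (int c = 0; c < 3; ++c) {
      std::vector<double> buf(out.begin() + c * n, out.begin() + (c + 1) * n);
      for (int a = 0; a < 3; ++a) gauss_axis(buf, nx, ny, nz, a, sigma);
      std::copy(buf.begin(), buf.end(), out.begin() + c * n);
    }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, NumericVector sigma_vox) {
  IntegerVector d = get_dim3(vol);
  int nx = d[0], ny = d[1], nz = d[2];
  std::vector<double> buf(vol.begin(), vol.end());
  for (int a = 0; a < 3; ++a) gauss_axis(buf, nx, ny, nz, a, sigma_vox[a]);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = d;
  return out;
}

// Jacobian determinant of x -> x + disp(x); central differences in the
// interior, one-sided at the boundary faces.
// [[Rcpp::export]]
NumericVector cpp_jacobian(NumericVector disp, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double* dp = disp.begin();
  NumericVector out(n);
  int nn[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        int pos[3] = {i, j, k};
        double J[3][3];
        for (int b = 0; b < 3; ++b) { // derivative axis
          int lo = pos[b] > 0 ? pos[b] - 1 : pos[b];
          int hi = pos[b] < nn[b] - 1 ? pos[b] + 1 : pos[b];
          double h = (double)(hi - lo);
          for (int a = 0; a < 3; ++a) { // field component
            double vhi = dp[idx + (hi - pos[b]) * stride[b] + a * n];
            double vlo = dp[idx + (lo - pos[b]) * stride[b] + a * n];
            J[a][b] = (vhi - vlo) / h + (a == b ? 1.0 : 0.0);
          }
        }
        out[idx] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
                 - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
                 + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  out.attr("dim") = dim;
  return out;
}

// Block-average subsampling; partial edge blocks average over available voxels.
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector vol, int f) {
  IntegerVector d = get_dim3(vol);
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = (nx + f - 1) / f, oy = (ny + f - 1) / f, oz = (nz + f - 1) / f;
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* v = vol.begin();
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double acc = 0; int cnt = 0;
        for (int kk = k * f; kk < std::min((k + 1) * f, nz); ++kk)
          for (int jj = j * f; jj < std::min((j + 1) * f, ny); ++jj)
            for (int ii = i * f; ii < std::min((i + 1) * f, nx); ++ii) {
              acc += v[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
              ++cnt;
            }
        out[i + (R_xlen_t)ox * (j + (R_xlen_t)oy * k)] = acc / cnt;
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Trilinear resample onto an output grid via per-axis affine index map
// in_coord = a * out_index + b (edge-clamped).
// [[Rcpp::export]]
NumericVector cpp_resample_grid(NumericVector vol, IntegerVector odim,
                                NumericVector a, NumericVector b) {
  IntegerVector d = get_dim3(vol);
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* v = vol.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx)
        out[idx] = sample_trilinear(v, nx, ny, nz,
                                    a[0] * i + b[0], a[1] * j + b[1],
                                    a[2] * k + b[2], true, 0.0);
  out.attr("dim") = odim;
  return out;
}

// compose(outer, inner)(x) = disp_outer(x) + disp_inner(x + disp_outer(x))
// [[Rcpp::export]]
NumericVector cpp_compose(NumericVector outer, NumericVector inner,
                          IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(3 * n);
  const double* od = outer.begin();
  const double* id = inner.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + od[idx], y = j + od[idx + n], z = k + od[idx + 2 * n];
        for (int a = 0; a < 3; ++a)
          out[idx + a * n] = od[idx + a * n] +
            sample_trilinear(id + a * n, nx, ny, nz, x, y, z, true, 0.0);
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// Demons-style update u = (F - W) grad(W) / (|grad W|^2 + kappa (F - W)^2),
// plus the current mean squared difference.
// [[Rcpp::export]]
List cpp_demons_update(NumericVector fixed, NumericVector warped, double kappa) {
  IntegerVector d = get_dim3(fixed);
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector u(3 * n);
  const double* F = fixed.begin();
  const double* W = warped.begin();
  double msd = 0;
  int nn[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double diff = F[idx] - W[idx];
        msd += diff * diff;
        int pos[3] = {i, j, k};
        double g[3], g2 = 0;
        for (int b = 0; b < 3; ++b) {
          int lo = pos[b] > 0 ? pos[b] - 1 : pos[b];
          int hi = pos[b] < nn[b] - 1 ? pos[b] + 1 : pos[b];
          g[b] = (W[idx + (hi - pos[b]) * stride[b]] -
                  W[idx + (lo - pos[b]) * stride[b]]) / (double)(hi - lo);
          g2 += g[b] * g[b];
        }
        double denom = g2 + kappa * diff * diff;
        if (denom > 1e-12)
          for (int a = 0; a < 3; ++a) u[idx + a * n] = diff * g[a] / denom;
      }
  u.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["u"] = u, _["msd"] = msd / n);
}

// [[Rcpp::export]]
double cpp_max_norm(NumericVector disp, IntegerVector dim) {
  R_xlen_t n = (R_xlen_t)dim[0] * dim[1] * dim[2];
  const double* dp = disp.begin();
  double m = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = dp[i] * dp[i] + dp[i + n] * dp[i + n] + dp[i + 2 * n] * dp[i + 2 * n];
    if (v > m) m = v;
  }
  return std::sqrt(m);
}

// Sum of values over the (2r+1)^3 cube centred at each voxel, clipped at
// the borders (separable running box sums).
static void box_axis(std::vector<double>& buf, int nx, int ny, int nz,
                     int axis, int r) {
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  int na = n[axis];
  R_xlen_t sa = stride[axis];
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(na), cum(na + 1);
  for (int q = 0; q < n[b2]; ++q)
    for (int p = 0; p < n[b1]; ++p) {
      R_xlen_t base = p * stride[b1] + q * stride[b2];
      cum[0] = 0;
      for (int i = 0; i < na; ++i) cum[i + 1] = cum[i] + buf[base + i * sa];
      for (int i = 0; i < na; ++i) {
        int lo = std::max(0, i - r), hi = std::min(na - 1, i + r);
        buf[base + i * sa] = cum[hi + 1] - cum[lo];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_box_sum(NumericVector vol, int radius) {
  IntegerVector d = get_dim3(vol);
  std::vector<double> buf(vol.begin(), vol.end());
  for (int a = 0; a < 3; ++a) box_axis(buf, d[0], d[1], d[2], a, radius);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = d;
  return out;
}

// Binary dilation by an explicit offset list (K x 3 integer matrix).
// [[Rcpp::export]]
IntegerVector cpp_dilate_offsets(IntegerVector mask, IntegerMatrix offsets) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        for (int o = 0; o < offsets.nrow(); ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            out[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] = 1;
        }
      }
  out.attr("dim") = d;
  return out;
}

// Discrete AdaBoost with decision stumps.
// y in {-1, +1}; h(x) = polarity * sign(x[feature] > threshold ? +1 : -1).
// Thresholds scanned at midpoints of sorted distinct feature values.
// [[Rcpp::export]]
List cpp_adaboost_train(NumericMatrix X, IntegerVector y, NumericVector w0,
                        int T) {
  int n = X.nrow(), d = X.ncol();
  std::vector<std::vector<int>> order(d, std::vector<int>(n));
  for (int f = 0; f < d; ++f) {
    for (int i = 0; i < n; ++i) order[f][i] = i;
    const double* col = &X(0, f);
    std::sort(order[f].begin(), order[f].end(),
              [col](int a, int b) { return col[a] < col[b]; });
  }
  std::vector<double> w(w0.begin(), w0.end());
  double ws = 0; for (double v : w) ws += v;
  for (double& v : w) v /= ws;

  std::vector<int> feat, pol;
  std::vector<double> thr, alpha, eps_trace, err_trace;
  std::vector<double> score(n, 0.0);

  for (int t = 0; t < T; ++t) {
    int best_f = -1, best_pol = 1;
    double best_err = 0.5, best_thr = 0;
    for (int f = 0; f < d; ++f) {
      const std::vector<int>& ord = order[f];
      const double* col = &X(0, f);
      // err for stump "predict +1 when x > thr", thr below all values:
      double err = 0;
      for (int i = 0; i < n; ++i) if (y[i] < 0) err += w[i];
      double prev = col[ord[0]];
      double running = err;
      for (int s = 0; s < n - 1; ++s) {
        int i = ord[s];
        running += (y[i] > 0) ? w[i] : -w[i];
        double nxt = col[ord[s + 1]];
        if (nxt == prev) continue;
        double cand_thr = 0.5 * (prev + nxt);
        prev = nxt;
        if (running < best_err) {
          best_err = running; best_f = f; best_thr = cand_thr; best_pol = 1;
        }
        if (1.0 - running < best_err) {
          best_err = 1.0 - running; best_f = f; best_thr = cand_thr; best_pol = -1;
        }
      }
    }
    if (best_f < 0 || best_err >= 0.5 - 1e-9) break;
    double eps = best_err;
    double a = 0.5 * std::log((1.0 - eps) / std::max(eps, 1e-12));
    feat.push_back(best_f); thr.push_back(best_thr);
    pol.push_back(best_pol); alpha.push_back(a); eps_trace.push_back(eps);
    double wsum = 0;
    int nerr = 0;
    for (int i = 0; i < n; ++i) {
      int h = (X(i, best_f) > best_thr ? 1 : -1) * best_pol;
      w[i] *= std::exp(-a * y[i] * h);
      wsum += w[i];
      score[i] += a * h;
      // ensemble decision: mislabeled iff score > 0 (ties keep initial label)
      int pred = score[i] > 0 ? 1 : -1;
      if (pred != y[i]) ++nerr;
    }
    for (int i = 0; i < n; ++i) w[i] /= wsum;
    err_trace.push_back((double)nerr / n);
    if (eps < 1e-12) break;
  }
  return List::create(_["feature"] = wrap(feat), _["threshold"] = wrap(thr),
                      _["polarity"] = wrap(pol), _["alpha"] = wrap(alpha),
                      _["eps"] = wrap(eps_trace), _["train_err"] = wrap(err_trace));
}

// [[Rcpp::export]]
NumericVector cpp_boost_score(NumericMatrix X, IntegerVector feat,
                              NumericVector thr, IntegerVector pol,
                              NumericVector alpha) {
  int n = X.nrow(), T = feat.size();
  NumericVector s(n);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i)
      s[i] += alpha[t] * ((X(i, feat[t]) > thr[t] ? 1 : -1) * pol[t]);
  return s;
}
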