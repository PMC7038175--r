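#include <Rcpp.h>
using namespace Rcpp;

// Symmetric (edge-inclusive) reflection of an out-of-range index.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Correlation of a 1D/2D/3D array with a centred 1D kernel along one axis,
// reflected boundaries: out(i) = sum_u k(u) * x(i + u), u = -R..R.
// [[Rcpp::export]]
NumericVector cpp_correlate1d(const NumericVector& x, const IntegerVector& dim,
                              const NumericVector& kernel, int axis) {
  const int nd = dim.size();
  const int n1 = dim[0];
  const int n2 = nd > 1 ? dim[1] : 1;
  const int n3 = nd > 2 ? dim[2] : 1;
  const int nk = kernel.size();
  const int R = (nk - 1) / 2;
  if (axis < 0 || axis >= nd) stop("axis out of range");
  NumericVector out(x.size());
  const double* px = x.begin();
  const double* pk = kernel.begin();
  double* po = out.begin();
  const R_xlen_t s[3] = {1, (R_xlen_t)n1, (R_xlen_t)n1 * n2};
  const int nn[3] = {n1, n2, n3};
  const R_xlen_t sa = s[axis];
  const int na = nn[axis];
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t base0 = (R_xlen_t)k * s[2] + (R_xlen_t)j * s[1];
      for (int i = 0; i < n1; ++i) {
        const R_xlen_t idx = base0 + i;
        const int ia = (axis == 0) ? i : (axis == 1 ? j : k);
        double acc = 0.0;
        if (ia >= R && ia + R < na) {
          const double* p = px + idx - (R_xlen_t)R * sa;
          for (int t = 0; t < nk; ++t, p += sa) acc += pk[t] * (*p);
        } else {
          for (int t = 0; t < nk; ++t) {
            const int ja = reflect_idx(ia + t - R, na);
            acc += pk[t] * px[idx + (R_xlen_t)(ja - ia) * sa];
          }
        }
        po[idx] = acc;
      }
    }
  }
  return out;
}

// Catmull-Rom weights for fractional offset f (4 taps at -1, 0, 1, 2).
static inline void cr_weights(double f, double* w) {
  const double f2 = f * f, f3 = f2 * f;
  w[0] = -0.5 * f + f2 - 0.5 * f3;
  w[1] = 1.0 - 2.5 * f2 + 1.5 * f3;
  w[2] = 0.5 * f + 2.0 * f2 - 1.5 * f3;
  w[3] = -0.5 * f2 + 0.5 * f3;
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Separable cubic (Catmull-Rom) sampling with clamped edges.
static double sample_cubic(const double* pv, int n1, int n2, int n3,
                           R_xlen_t s2, R_xlen_t s3, double xs, double ys,
                           double zs, bool is3d) {
  int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys), z0 = (int)std::floor(zs);
  double wx[4], wy[4], wz[4];
  cr_weights(xs - x0, wx);
  cr_weights(ys - y0, wy);
  cr_weights(zs - z0, wz);
  const int nz = is3d ? 4 : 1;
  if (!is3d) { wz[0] = 1.0; z0 = 0; }
  double acc = 0.0;
  for (int c = 0; c < nz; ++c) {
    const int zc = clampi(z0 - 1 + c, 0, n3 - 1);
    double accy = 0.0;
    for (int b = 0; b < 4; ++b) {
      const int yb = clampi(y0 - 1 + b, 0, n2 - 1);
      const R_xlen_t base = (R_xlen_t)yb * s2 + (R_xlen_t)zc * s3;
      double accx = 0.0;
      for (int a = 0; a < 4; ++a) {
        accx += wx[a] * pv[clampi(x0 - 1 + a, 0, n1 - 1) + base];
      }
      accy += wy[b] * accx;
    }
    acc += (is3d ? wz[c] : 1.0) * accy;
  }
  return acc;
}

// Backward warping with edge clamping: out(x) = vol(x + u(x), ...).
// method 0 = linear, 1 = cubic Catmull-Rom. Pass w = R_NilValue in 2D.
// [[Rcpp::export]]
NumericVector cpp_warp(const NumericVector& vol, const IntegerVector& dim,
                       const NumericVector& u, const NumericVector& v,
                       Nullable<NumericVector> w_, int method = 0) {
  const int nd = dim.size();
  const int n1 = dim[0];
  const int n2 = nd > 1 ? dim[1] : 1;
  const int n3 = nd > 2 ? dim[2] : 1;
  const bool is3d = w_.isNotNull() && nd == 3;
  NumericVector w;
  if (is3d) w = w_.get();
  NumericVector out(vol.size());
  const double* pv = vol.begin();
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  R_xlen_t idx = 0;
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i, ++idx) {
        double xs = clampd(i + u[idx], 0.0, n1 - 1.0);
        double ys = clampd(j + v[idx], 0.0, n2 - 1.0);
        double zs = is3d ? clampd(k + w[idx], 0.0, n3 - 1.0) : 0.0;
        if (method == 1) {
          out[idx] = sample_cubic(pv, n1, n2, n3, s2, s3, xs, ys, zs, is3d);
          continue;
        }
        int x0 = (int)std::floor(xs); if (x0 > n1 - 2) x0 = n1 > 1 ? n1 - 2 : 0;
        int y0 = (int)std::floor(ys); if (y0 > n2 - 2) y0 = n2 > 1 ? n2 - 2 : 0;
        int z0 = (int)std::floor(zs); if (z0 > n3 - 2) z0 = n3 > 1 ? n3 - 2 : 0;
        double fx = xs - x0, fy = ys - y0, fz = zs - z0;
        const R_xlen_t b = x0 + (R_xlen_t)y0 * s2 + (R_xlen_t)z0 * s3;
        const int dx = n1 > 1 ? 1 : 0;
        const int dy = n2 > 1 ? (int)s2 : 0;
        double c00 = pv[b] * (1 - fx) + pv[b + dx] * fx;
        double c10 = pv[b + dy] * (1 - fx) + pv[b + dy + dx] * fx;
        double v0 = c00 * (1 - fy) + c10 * fy;
        if (is3d && n3 > 1) {
          const R_xlen_t bz = b + s3;
          double c01 = pv[bz] * (1 - fx) + pv[bz + dx] * fx;
          double c11 = pv[bz + dy] * (1 - fx) + pv[bz + dy + dx] * fx;
          double v1 = c01 * (1 - fy) + c11 * fy;
          out[idx] = v0 * (1 - fz) + v1 * fz;
        } else {
          out[idx] = v0;
        }
      }
    }
  }
  return out;
}

// Resample an array onto a new grid where target index i maps to source
// coordinate i * 0.5 (used to upsample pyramid-level flow fields; the
// coarse grid sits on every second sample of the fine grid).
// [[Rcpp::export]]
NumericVector cpp_upsample2(const NumericVector& x, const IntegerVector& dim,
                            const IntegerVector& newdim) {
  const int nd = dim.size();
  const int n1 = dim[0];
  const int n2 = nd > 1 ? dim[1] : 1;
  const int n3 = nd > 2 ? dim[2] : 1;
  const int m1 = newdim[0];
  const int m2 = nd > 1 ? newdim[1] : 1;
  const int m3 = nd > 2 ? newdim[2] : 1;
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  const double* pv = x.begin();
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  R_xlen_t idx = 0;
  for (int k = 0; k < m3; ++k) {
    for (int j = 0; j < m2; ++j) {
      for (int i = 0; i < m1; ++i, ++idx) {
        double xs = clampd(i * 0.5, 0.0, n1 - 1.0);
        double ys = clampd(j * 0.5, 0.0, n2 - 1.0);
        double zs = clampd(k * 0.5, 0.0, n3 - 1.0);
        int x0 = (int)std::floor(xs); if (x0 > n1 - 2) x0 = n1 > 1 ? n1 - 2 : 0;
        int y0 = (int)std::floor(ys); if (y0 > n2 - 2) y0 = n2 > 1 ? n2 - 2 : 0;
        int z0 = (int)std::floor(zs); if (z0 > n3 - 2) z0 = n3 > 1 ? n3 - 2 : 0;
        double fx = xs - x0, fy = ys - y0, fz = zs - z0;
        const R_xlen_t b = x0 + (R_xlen_t)y0 * s2 + (R_xlen_t)z0 * s3;
        const int dx = n1 > 1 ? 1 : 0;
        const int dy = n2 > 1 ? (int)s2 : 0;
        double c00 = pv[b] * (1 - fx) + pv[b + dx] * fx;
        double c10 = pv[b + dy] * (1 - fx) + pv[b + dy + dx] * fx;
        double v0 = c00 * (1 - fy) + c10 * fy;
        if (n3 > 1) {
          const R_xlen_t bz = b + s3;
          double c01 = pv[bz] * (1 - fx) + pv[bz + dx] * fx;
          double c11 = pv[bz + dy] * (1 - fx) + pv[bz + dy + dx] * fx;
          double v1 = c01 * (1 - fy) + c11 * fy;
          out[idx] = v0 * (1 - fz) + v1 * fz;
        } else {
          out[idx] = v0;
        }
      }
    }
  }
  return out;
}

static inline double neighbor_mean(const double* q, int i, int j, int k,
                                   int n1, int n2, int n3, R_xlen_t s2,
                                   R_xlen_t s3, bool is3d) {
  const R_xlen_t idx = i + (R_xlen_t)j * s2 + (R_xlen_t)k * s3;
  // Replicated boundary: an out-of-range neighbour is the centre itself.
  double acc = q[i > 0 ? idx - 1 : idx] + q[i < n1 - 1 ? idx + 1 : idx] +
               q[j > 0 ? idx - s2 : idx] + q[j < n2 - 1 ? idx + s2 : idx];
  if (is3d) {
    acc += q[k > 0 ? idx - s3 : idx] + q[k < n3 - 1 ? idx + s3 : idx];
    return acc / 6.0;
  }
  return acc / 4.0;
}

// Jacobi-style solver for the per-voxel normal equations of the linearised
// flow energy: (J + alpha I) d_new = r + alpha * (nbhd_mean(w0 + d) - w0),
// with an exact cofactor solve of the (2x2 or 3x3) per-voxel system each
// sweep. J holds the data-term matrix (upper triangle), r the data-term
// right-hand side; w0 is the accumulated flow kept fixed during the solve.
// [[Rcpp::export]]
List cpp_flow_solve(const List& J, const List& r, const List& w0,
                    const IntegerVector& dim, double alpha, int niter,
                    double tol) {
  const int nd = dim.size();
  const bool is3d = nd == 3;
  const int n1 = dim[0];
  const int n2 = nd > 1 ? dim[1] : 1;
  const int n3 = nd > 2 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;

  NumericVector J11 = J["J11"], J12 = J["J12"], J22 = J["J22"];
  NumericVector J13, J23, J33;
  NumericVector r1 = r["r1"], r2 = r["r2"], r3;
  NumericVector u0 = w0["u"], v0 = w0["v"], w0z;
  if (is3d) {
    J13 = as<NumericVector>(J["J13"]);
    J23 = as<NumericVector>(J["J23"]);
    J33 = as<NumericVector>(J["J33"]);
    r3 = as<NumericVector>(r["r3"]);
    w0z = as<NumericVector>(w0["w"]);
  }

  NumericVector du(n), dv(n), dw(is3d ? n : 0);
  // totals = w0 + d, the quantity whose neighbourhood mean couples voxels
  NumericVector tu(n), tv(n), tw(is3d ? n : 0);
  for (R_xlen_t q = 0; q < n; ++q) { tu[q] = u0[q]; tv[q] = v0[q]; }
  if (is3d) for (R_xlen_t q = 0; q < n; ++q) tw[q] = w0z[q];

  std::vector<double> deltas;
  int it = 0;
  const double jitter = 1e-12;
  for (it = 0; it < niter; ++it) {
    double accum = 0.0;
    NumericVector nu(n), nv(n), nw(is3d ? n : 0);
    R_xlen_t idx = 0;
    for (int k = 0; k < n3; ++k) {
      for (int j = 0; j < n2; ++j) {
        for (int i = 0; i < n1; ++i, ++idx) {
          double bu = r1[idx] + alpha * (neighbor_mean(tu.begin(), i, j, k, n1, n2, n3, s2, s3, is3d) - u0[idx]);
          double bv = r2[idx] + alpha * (neighbor_mean(tv.begin(), i, j, k, n1, n2, n3, s2, s3, is3d) - v0[idx]);
          double a11 = J11[idx] + alpha, a12 = J12[idx], a22 = J22[idx] + alpha;
          double nu_i, nv_i, nw_i = 0.0;
          if (is3d) {
            double bw = r3[idx] + alpha * (neighbor_mean(tw.begin(), i, j, k, n1, n2, n3, s2, s3, true) - w0z[idx]);
            double a13 = J13[idx], a23 = J23[idx], a33 = J33[idx] + alpha;
            double det = a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13) + a13 * (a12 * a23 - a22 * a13);
            if (std::abs(det) < jitter) { a11 += 1e-8; a22 += 1e-8; a33 += 1e-8;
              det = a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13) + a13 * (a12 * a23 - a22 * a13); }
            nu_i = (bu * (a22 * a33 - a23 * a23) + bv * (a13 * a23 - a12 * a33) + bw * (a12 * a23 - a13 * a22)) / det;
            nv_i = (bu * (a13 * a23 - a12 * a33) + bv * (a11 * a33 - a13 * a13) + bw * (a12 * a13 - a11 * a23)) / det;
            nw_i = (bu * (a12 * a23 - a13 * a22) + bv * (a12 * a13 - a11 * a23) + bw * (a11 * a22 - a12 * a12)) / det;
          } else {
            double det = a11 * a22 - a12 * a12;
            if (std::abs(det) < jitter) { a11 += 1e-8; a22 += 1e-8; det = a11 * a22 - a12 * a12; }
            nu_i = (bu * a22 - bv * a12) / det;
            nv_i = (bv * a11 - bu * a12) / det;
          }
          accum += std::abs(nu_i - du[idx]) + std::abs(nv_i - dv[idx]);
          if (is3d) accum += std::abs(nw_i - dw[idx]);
          nu[idx] = nu_i; nv[idx] = nv_i;
          if (is3d) nw[idx] = nw_i;
        }
      }
    }
    du = nu; dv = nv;
    if (is3d) dw = nw;
    for (R_xlen_t q = 0; q < n; ++q) { tu[q] = u0[q] + du[q]; tv[q] = v0[q] + dv[q]; }
    if (is3d) for (R_xlen_t q = 0; q < n; ++q) tw[q] = w0z[q] + dw[q];
    double mean_delta = accum / (n * (is3d ? 3.0 : 2.0));
    deltas.push_back(mean_delta);
    if (mean_delta < tol) { ++it; break; }
  }
  return List::create(_["du"] = du, _["dv"] = dv,
                      _["dw"] = is3d ? (SEXP)dw : R_NilValue,
                      _["iterations"] = it, _["deltas"] = wrap(deltas));
}
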