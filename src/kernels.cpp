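#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Sample src (nx,ny,nz, column-major) at continuous 0-based voxel index.
// mode 0: trilinear, pad outside; mode 1: nearest neighbour, pad outside;
// mode 2: trilinear with edge clamping (used for internal field resampling).
static double sample3(const double* src, int nx, int ny, int nz,
                      double x, double y, double z, int mode, double pad) {
  if (mode == 2) {
    x = clampd(x, 0.0, nx - 1.0);
    y = clampd(y, 0.0, ny - 1.0);
    z = clampd(z, 0.0, nz - 1.0);
  }
  if (mode == 1) {
    long i = std::lround(x), j = std::lround(y), k = std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return pad;
    return src[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
  }
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) return pad;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  // degenerate axes (n == 1): keep index 0 and zero fraction
  double fx = (nx > 1) ? x - x0 : 0.0;
  double fy = (ny > 1) ? y - y0 : 0.0;
  double fz = (nz > 1) ? z - z0 : 0.0;
  int x1 = (nx > 1) ? x0 + 1 : x0;
  int y1 = (ny > 1) ? y0 + 1 : y0;
  int z1 = (nz > 1) ? z0 + 1 : z0;
  size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * (size_t)ny;
  const double* p = src;
  double c000 = p[x0 * sx + y0 * sy + z0 * sz];
  double c100 = p[x1 * sx + y0 * sy + z0 * sz];
  double c010 = p[x0 * sx + y1 * sy + z0 * sz];
  double c110 = p[x1 * sx + y1 * sy + z0 * sz];
  double c001 = p[x0 * sx + y0 * sy + z1 * sz];
  double c101 = p[x1 * sx + y0 * sy + z1 * sz];
  double c011 = p[x0 * sx + y1 * sy + z1 * sz];
  double c111 = p[x1 * sx + y1 * sy + z1 * sz];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample `src` (its own grid geometry) onto the target grid.  The point
// mapping moving -> fixed is p |-> p + translation (+ field, evaluated on
// the target grid), so the pull-back sample point for target-space physical
// location x is x - translation + d(x).  `field`, when present, has length
// 3 * prod(tdim), component-major blocks (dx then dy then dz), in mm.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector src, IntegerVector sdim,
                       NumericVector sspacing, NumericVector sorigin,
                       IntegerVector tdim, NumericVector tspacing,
                       NumericVector torigin, NumericVector translation,
                       Nullable<NumericVector> field, bool nearest,
                       double pad, bool clampEdge = false) {
  int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  size_t tn = (size_t)tnx * tny * tnz;
  NumericVector out((R_xlen_t)tn);
  const double* sp = REAL(src);
  const double* fp = nullptr;
  if (field.isNotNull()) {
    NumericVector f(field);
    if ((size_t)f.size() != 3 * tn) stop("displacement field size mismatch");
    fp = REAL(f);
  }
  int mode = nearest ? 1 : (clampEdge ? 2 : 0);
  size_t idx = 0;
  for (int k = 0; k < tnz; ++k) {
    double pz = torigin[2] + k * tspacing[2];
    for (int j = 0; j < tny; ++j) {
      double py = torigin[1] + j * tspacing[1];
      for (int i = 0; i < tnx; ++i, ++idx) {
        double px = torigin[0] + i * tspacing[0];
        double qx = px - translation[0];
        double qy = py - translation[1];
        double qz = pz - translation[2];
        if (fp) {
          qx += fp[idx];
          qy += fp[idx + tn];
          qz += fp[idx + 2 * tn];
        }
        double vx = (qx - sorigin[0]) / sspacing[0];
        double vy = (qy - sorigin[1]) / sspacing[1];
        double vz = (qz - sorigin[2]) / sspacing[2];
        out[idx] = sample3(sp, snx, sny, snz, vx, vy, vz, mode, pad);
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing of one scalar component, replicate-edge
// boundary, kernel truncated at 3 sigma (axis skipped when sigma < 0.2 vox).
static void smooth_component(double* v, double* tmp, int nx, int ny, int nz,
                             const double* sigma) {
  size_t n = (size_t)nx * ny * nz;
  int dims[3] = {nx, ny, nz};
  size_t strides[3] = {1, (size_t)nx, (size_t)nx * (size_t)ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s < 0.2 || dims[ax] < 2) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (auto& w : ker) w /= sum;
    int d = dims[ax];
    size_t st = strides[ax];
    // iterate over all lines along axis ax
    int oa1 = (ax + 1) % 3, oa2 = (ax + 2) % 3;
    for (int b = 0; b < dims[oa2]; ++b) {
      for (int a = 0; a < dims[oa1]; ++a) {
        size_t base = (size_t)a * strides[oa1] + (size_t)b * strides[oa2];
        for (int p = 0; p < d; ++p) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int q = p + t;
            if (q < 0) q = 0;
            if (q >= d) q = d - 1;
            acc += ker[t + r] * v[base + (size_t)q * st];
          }
          tmp[base + (size_t)p * st] = acc;
        }
      }
    }
    std::copy(tmp, tmp + n, v);
  }
}

// [[Rcpp::export]]
NumericVector cpp_smooth_field(NumericVector field, IntegerVector dim,
                               NumericVector sigmaVox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out = clone(field);
  std::vector<double> tmp(n);
  double sig[3] = {sigmaVox[0], sigmaVox[1], sigmaVox[2]};
  for (int c = 0; c < 3; ++c)
    smooth_component(REAL(out) + c * n, tmp.data(), nx, ny, nz, sig);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_smooth_volume(NumericVector vol, IntegerVector dim,
                                NumericVector sigmaVox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  std::vector<double> tmp((size_t)nx * ny * nz);
  double sig[3] = {sigmaVox[0], sigmaVox[1], sigmaVox[2]};
  smooth_component(REAL(out), tmp.data(), nx, ny, nz, sig);
  out.attr("dim") = dim;
  return out;
}

// Demons-style deformable registration at one resolution level.
// Fixed and moving are intensity-normalised by the caller.  The force is the
// classic intensity-difference update (F - W) grad(F) / (|grad F|^2 + (F-W)^2)
// capped at stepCap mm per iteration, with Gaussian regularisation of the
// accumulated field after every iteration.  Deterministic.
// [[Rcpp::export]]
NumericVector cpp_demons(NumericVector fixedv, IntegerVector fdim,
                         NumericVector fspacing, NumericVector forigin,
                         NumericVector movingv, IntegerVector mdim,
                         NumericVector mspacing, NumericVector morigin,
                         NumericVector translation, NumericVector initField,
                         int iters, NumericVector sigmaVox, double stepCap,
                         double normK, double g2min) {
  int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  size_t n = (size_t)nx * ny * nz;
  if ((size_t)initField.size() != 3 * n) stop("init field size mismatch");
  NumericVector field = clone(initField);
  const double* F = REAL(fixedv);

  // gradient of the fixed image in intensity / mm (central differences)
  std::vector<double> gx(n), gy(n), gz(n);
  {
    size_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          int im = i > 0 ? i - 1 : i, ip = i < nx - 1 ? i + 1 : i;
          int jm = j > 0 ? j - 1 : j, jp = j < ny - 1 ? j + 1 : j;
          int km = k > 0 ? k - 1 : k, kp = k < nz - 1 ? k + 1 : k;
          size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
          double dxv = (ip - im) * fspacing[0];
          double dyv = (jp - jm) * fspacing[1];
          double dzv = (kp - km) * fspacing[2];
          gx[idx] = dxv > 0 ? (F[ip * sx + j * sy + (size_t)k * sz] -
                               F[im * sx + j * sy + (size_t)k * sz]) / dxv : 0.0;
          gy[idx] = dyv > 0 ? (F[i * sx + jp * sy + (size_t)k * sz] -
                               F[i * sx + jm * sy + (size_t)k * sz]) / dyv : 0.0;
          gz[idx] = dzv > 0 ? (F[i * sx + j * sy + (size_t)kp * sz] -
                               F[i * sx + j * sy + (size_t)km * sz]) / dzv : 0.0;
        }
  }

  std::vector<double> tmp(n);
  double sig[3] = {sigmaVox[0], sigmaVox[1], sigmaVox[2]};
  const double* M = REAL(movingv);
  int snx = mdim[0], sny = mdim[1], snz = mdim[2];
  double* fld = REAL(field);

  for (int it = 0; it < iters; ++it) {
    size_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      double pz = forigin[2] + k * fspacing[2];
      for (int j = 0; j < ny; ++j) {
        double py = forigin[1] + j * fspacing[1];
        for (int i = 0; i < nx; ++i, ++idx) {
          double px = forigin[0] + i * fspacing[0];
          double qx = px - translation[0] + fld[idx];
          double qy = py - translation[1] + fld[idx + n];
          double qz = pz - translation[2] + fld[idx + 2 * n];
          double w = sample3(M, snx, sny, snz,
                             (qx - morigin[0]) / mspacing[0],
                             (qy - morigin[1]) / mspacing[1],
                             (qz - morigin[2]) / mspacing[2], 2, 0.0);
          double diff = F[idx] - w;
          double g2 = gx[idx] * gx[idx] + gy[idx] * gy[idx] + gz[idx] * gz[idx];
          // ITK-style normalisation: K ~ mean voxel spacing keeps the step
          // in mm units commensurate with the intensity scale
          if (g2 < g2min) continue;  // no reliable edge signal here
          double denom = g2 + diff * diff / (normK * normK);
          if (denom < 1e-12) continue;
          double ux = diff * gx[idx] / denom;
          double uy = diff * gy[idx] / denom;
          double uz = diff * gz[idx] / denom;
          double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          if (nrm > stepCap) {
            double sc = stepCap / nrm;
            ux *= sc; uy *= sc; uz *= sc;
          }
          fld[idx] += ux;
          fld[idx + n] += uy;
          fld[idx + 2 * n] += uz;
        }
      }
    }
    for (int c = 0; c < 3; ++c)
      smooth_component(fld + c * n, tmp.data(), nx, ny, nz, sig);
  }
  return field;
}

// Directed minimum Euclidean distances: for each row of A (physical mm
// coordinates) the distance to the closest row of B.
// [[Rcpp::export]]
NumericVector cpp_directed_min_dists(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Block-mean downsampling by integer factors (trailing partial blocks are
// dropped so every output voxel averages a full f-block).
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector v, IntegerVector dim,
                             IntegerVector f) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int fx = f[0], fy = f[1], fz = f[2];
  int ox = nx / fx, oy = ny / fy, oz = nz / fz;
  if (ox < 1 || oy < 1 || oz < 1) stop("factor too large for grid");
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* p = REAL(v);
  size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  double inv = 1.0 / (fx * fy * fz);
  size_t oidx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++oidx) {
        double acc = 0.0;
        for (int kk = 0; kk < fz; ++kk)
          for (int jj = 0; jj < fy; ++jj)
            for (int ii = 0; ii < fx; ++ii)
              acc += p[(size_t)(i * fx + ii) * sx +
                       (size_t)(j * fy + jj) * sy +
                       (size_t)(k * fz + kk) * sz];
        out[oidx] = acc * inv;
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
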