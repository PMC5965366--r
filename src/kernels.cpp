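#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column-major linear index into an (nx,ny,nz) array.
static inline R_xlen_t lin3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Trilinear sample of a scalar grid at one world point.
// border: 0 = zero outside, 1 = clamp to edge.
static double tri_sample(const double* a, int nx, int ny, int nz,
                         const double* sp, const double* o,
                         double x, double y, double z, int border) {
  double fx = (x - o[0]) / sp[0];
  double fy = (y - o[1]) / sp[1];
  double fz = (z - o[2]) / sp[2];
  if (border == 0) {
    if (fx < -0.5 || fy < -0.5 || fz < -0.5 ||
        fx > nx - 0.5 || fy > ny - 0.5 || fz > nz - 0.5) return 0.0;
  }
  if (border == 1) {
    if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
    if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
    if (fz < 0) fz = 0; if (fz > nz - 1) fz = nz - 1;
  }
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  double v = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    int k = k0 + dk; if (k < 0 || k >= nz) continue;
    double wz = dk ? tz : 1.0 - tz; if (wz == 0.0) continue;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj; if (j < 0 || j >= ny) continue;
      double wy = dj ? ty : 1.0 - ty; if (wy == 0.0) continue;
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di; if (i < 0 || i >= nx) continue;
        double wx = di ? tx : 1.0 - tx; if (wx == 0.0) continue;
        v += wx * wy * wz * a[lin3(i, j, k, nx, ny)];
      }
    }
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts, int border) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double* a = arr.begin();
  for (R_xlen_t p = 0; p < n; ++p)
    out[p] = tri_sample(a, nx, ny, nz, spacing.begin(), origin.begin(),
                        pts(p, 0), pts(p, 1), pts(p, 2), border);
  return out;
}

// Trilinear sample of a 3-vector field stored as (nx,ny,nz,3); zero outside.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear_vec(NumericVector arr, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t comp = (R_xlen_t)nx * ny * nz;
  R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  const double* a = arr.begin();
  for (R_xlen_t p = 0; p < n; ++p)
    for (int c = 0; c < 3; ++c)
      out(p, c) = tri_sample(a + c * comp, nx, ny, nz,
                             spacing.begin(), origin.begin(),
                             pts(p, 0), pts(p, 1), pts(p, 2), 0);
  return out;
}

// Resample a scalar grid onto a target geometry. mode: 0 nearest, 1 trilinear.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           NumericVector ssp, NumericVector sorg,
                           IntegerVector tdim, NumericVector tsp,
                           NumericVector torg, int mode) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int mx = tdim[0], my = tdim[1], mz = tdim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* a = src.begin();
  R_xlen_t q = 0;
  for (int k = 0; k < mz; ++k) {
    double z = torg[2] + k * tsp[2];
    for (int j = 0; j < my; ++j) {
      double y = torg[1] + j * tsp[1];
      for (int i = 0; i < mx; ++i, ++q) {
        double x = torg[0] + i * tsp[0];
        if (mode == 0) {
          int ii = (int)std::floor((x - sorg[0]) / ssp[0] + 0.5);
          int jj = (int)std::floor((y - sorg[1]) / ssp[1] + 0.5);
          int kk = (int)std::floor((z - sorg[2]) / ssp[2] + 0.5);
          if (ii < 0) ii = 0; if (ii >= nx) ii = nx - 1;
          if (jj < 0) jj = 0; if (jj >= ny) jj = ny - 1;
          if (kk < 0) kk = 0; if (kk >= nz) kk = nz - 1;
          out[q] = a[lin3(ii, jj, kk, nx, ny)];
        } else {
          out[q] = tri_sample(a, nx, ny, nz, ssp.begin(), sorg.begin(),
                              x, y, z, 1);
        }
      }
    }
  }
  return out;
}

// Radiological depth (g/cm^3 * mm) from grid entry to each point along the
// ray from a common source, by fixed-step marching with trilinear density.
// [[Rcpp::export]]
NumericVector cpp_radiological_depth(NumericVector dens, IntegerVector dim,
                                     NumericVector spacing, NumericVector origin,
                                     NumericVector source, NumericMatrix pts,
                                     double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* a = dens.begin();
  const double* sp = spacing.begin();
  const double* o = origin.begin();
  // grid bounding box (outer voxel faces)
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] = o[c] - 0.5 * sp[c];
    hi[c] = o[c] + (dim[c] - 0.5) * sp[c];
  }
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double dx = px - source[0], dy = py - source[1], dz = pz - source[2];
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L <= 0) { out[p] = 0; continue; }
    dx /= L; dy /= L; dz /= L;
    // entry parameter into the bbox along the ray from the source
    double t0 = 0.0, t1 = L;
    double sd[3] = {dx, dy, dz};
    double s0[3] = {source[0], source[1], source[2]};
    bool miss = false;
    for (int c = 0; c < 3; ++c) {
      if (std::fabs(sd[c]) < 1e-12) {
        if (s0[c] < lo[c] || s0[c] > hi[c]) { miss = true; break; }
      } else {
        double ta = (lo[c] - s0[c]) / sd[c];
        double tb = (hi[c] - s0[c]) / sd[c];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    if (miss || t1 <= t0) { out[p] = 0; continue; }
    if (t1 > L) t1 = L;  // integrate only up to the point
    double acc = 0.0, t = t0;
    while (t < t1) {
      double h = std::min(step, t1 - t);
      double tm = t + 0.5 * h;
      acc += h * tri_sample(a, nx, ny, nz, sp, o,
                            s0[0] + tm * dx, s0[1] + tm * dy, s0[2] + tm * dz, 0);
      t += h;
    }
    out[p] = acc;
  }
  return out;
}

// Error-function edge profile of a 1D bixel of width w centred at 0,
// evaluated at offset u with penumbra sigma.
static inline double edge_profile(double u, double w, double sigma) {
  double s = sigma * std::sqrt(2.0);
  return 0.5 * (std::erf((u + 0.5 * w) / s) - std::erf((u - 0.5 * w) / s));
}

// Dose-influence triplets for one (beam, phase): rows bixels, cols voxels.
// depth: radiological depth per voxel; bev: voxel lateral offsets (n x 2)
// scaled to the isocenter plane; bix: bixel centres (m x 2) in the same frame.
// Entries below cutoff * (per-bixel max) are dropped.
// [[Rcpp::export]]
List cpp_dose_influence(NumericVector depth, NumericMatrix bev,
                        NumericMatrix bix, double bw_x, double bw_y,
                        double A, double mu, double sigma, double cutoff) {
  R_xlen_t n = depth.size();
  int m = bix.nrow();
  double reach = 0.5 * std::max(bw_x, bw_y) + 6.0 * sigma;
  std::vector<int> ri, cj;
  std::vector<double> vx;
  std::vector<double> att(n);
  for (R_xlen_t v = 0; v < n; ++v) att[v] = A * std::exp(-mu * depth[v]);
  std::vector<double> tmp;
  std::vector<R_xlen_t> idx;
  for (int b = 0; b < m; ++b) {
    tmp.clear(); idx.clear();
    double bxc = bix(b, 0), byc = bix(b, 1);
    double mx = 0.0;
    for (R_xlen_t v = 0; v < n; ++v) {
      double du = bev(v, 0) - bxc;
      if (du > reach || du < -reach) continue;
      double dv = bev(v, 1) - byc;
      if (dv > reach || dv < -reach) continue;
      double val = att[v] * edge_profile(du, bw_x, sigma) *
                   edge_profile(dv, bw_y, sigma);
      if (val <= 0) continue;
      tmp.push_back(val); idx.push_back(v);
      if (val > mx) mx = val;
    }
    double thr = cutoff * mx;
    for (size_t q = 0; q < tmp.size(); ++q) {
      if (tmp[q] >= thr) {
        ri.push_back(b + 1);          // 1-based for Matrix::sparseMatrix
        cj.push_back((int)idx[q] + 1);
        vx.push_back(tmp[q]);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(cj), _["x"] = wrap(vx));
}

// Push a scalar density/energy grid through a displacement field by subvoxel
// splitting, depositing into the nearest destination voxel on the same
// geometry. Voxels outside `box` (0-based, inclusive; the displacement
// support) are transferred identically. Returns deposited grid + lost total.
// [[Rcpp::export]]
List cpp_push_deposit(NumericVector src, IntegerVector dim,
                      NumericVector spacing, NumericVector origin,
                      NumericVector dvf, IntegerVector ddim,
                      NumericVector dsp, NumericVector dorg,
                      int s, IntegerVector box) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = ddim[0], my = ddim[1], mz = ddim[2];
  R_xlen_t comp = (R_xlen_t)mx * my * mz;
  const double* a = src.begin();
  const double* f = dvf.begin();
  const double* sp = spacing.begin();
  const double* o = origin.begin();
  NumericVector dep((R_xlen_t)nx * ny * nz);
  double* d = dep.begin();
  double lost = 0.0;
  double frac = 1.0 / ((double)s * s * s);
  int i0 = box[0], i1 = box[1], j0 = box[2], j1 = box[3], k0 = box[4], k1 = box[5];
  for (int k = 0; k < nz; ++k) {
    bool kz = (k >= k0 && k <= k1);
    for (int j = 0; j < ny; ++j) {
      bool jz = kz && (j >= j0 && j <= j1);
      for (int i = 0; i < nx; ++i) {
        R_xlen_t q = lin3(i, j, k, nx, ny);
        double V = a[q];
        if (V == 0.0) continue;
        if (!(jz && i >= i0 && i <= i1)) { d[q] += V; continue; }
        double cx = o[0] + i * sp[0], cy = o[1] + j * sp[1], cz = o[2] + k * sp[2];
        double Vs = V * frac;
        for (int c2 = 0; c2 < s; ++c2) {
          double z = cz + ((c2 + 0.5) / s - 0.5) * sp[2];
          for (int b2 = 0; b2 < s; ++b2) {
            double y = cy + ((b2 + 0.5) / s - 0.5) * sp[1];
            for (int a2 = 0; a2 < s; ++a2) {
              double x = cx + ((a2 + 0.5) / s - 0.5) * sp[0];
              // clamp-border sampling: constant fields stay constant up to
              // the outermost subvoxels; phantom fields vanish at their
              // support-box faces so clamping still yields zero beyond
              double ux = tri_sample(f, mx, my, mz, dsp.begin(), dorg.begin(), x, y, z, 1);
              double uy = tri_sample(f + comp, mx, my, mz, dsp.begin(), dorg.begin(), x, y, z, 1);
              double uz = tri_sample(f + 2 * comp, mx, my, mz, dsp.begin(), dorg.begin(), x, y, z, 1);
              int ti = (int)std::floor((x + ux - o[0]) / sp[0] + 0.5);
              int tj = (int)std::floor((y + uy - o[1]) / sp[1] + 0.5);
              int tk = (int)std::floor((z + uz - o[2]) / sp[2] + 0.5);
              if (ti < 0 || ti >= nx || tj < 0 || tj >= ny || tk < 0 || tk >= nz)
                lost += Vs;
              else
                d[lin3(ti, tj, tk, nx, ny)] += Vs;
            }
          }
        }
      }
    }
  }
  return List::create(_["dep"] = dep, _["lost"] = lost);
}
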