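#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Linear interpolation on a uniform energy grid (built in R by log-log
// interpolation of the packaged stopping-power table). Shared, via the same
// arithmetic, with the plain-R oracle used in tests.
static inline double lookup_S(double E, double E0, double dE,
                              const double* S, int n) {
  double f = (E - E0) / dE;
  int i = (int)f;
  if (i < 0) i = 0;
  if (i >= n - 1) i = n - 2;
  double w = f - i;
  return S[i] + w * (S[i + 1] - S[i]);
}

// Straight-track CSDA transport of alpha particles from the centre of the
// central voxel of a cubic grid. Per step of length `step_um` the energy
// S(E)*step is deposited at the step midpoint's voxel; when the remaining
// energy falls to the cutoff the whole residual is deposited locally, so
// per-track energy conservation is exact. Accumulates per-voxel sums and
// sums of squares of per-event deposits (for standard errors).
//
// Branch counts are allocated deterministically by the caller (cumulative
// rounding of the branch fractions), so the kernel total is exactly the
// branch-weighted mean initial energy. Uses R's RNG, two uniforms per
// event (direction), so a fixed R seed reproduces the kernel bitwise.
// [[Rcpp::export]]
List cpp_transport_kernel(int dim, double voxel_um,
                          NumericVector branch_counts, NumericVector branch_E0,
                          NumericVector E_grid0, double E_step,
                          NumericVector S_dense,
                          double step_um, double cutoff_MeV) {
  const int half = (dim - 1) / 2;
  const double inv_v = 1.0 / voxel_um;
  const R_xlen_t nvox = (R_xlen_t)dim * dim * dim;
  NumericVector sum(nvox), sumsq(nvox);
  const double* Sd = S_dense.begin();
  const int nS = S_dense.size();
  const double Egrid0 = E_grid0[0];
  const int nb = branch_counts.size();

  RNGScope scope;
  for (int b = 0; b < nb; ++b) {
  for (double ev = 0; ev < branch_counts[b]; ev += 1.0) {
    double mu = 2.0 * unif_rand() - 1.0;
    double phi = 2.0 * M_PI * unif_rand();
    double st = std::sqrt(std::max(0.0, 1.0 - mu * mu));
    double dx = st * std::cos(phi), dy = st * std::sin(phi), dz = mu;

    double E = branch_E0[b];
    double px = 0.0, py = 0.0, pz = 0.0;  // um, origin at grid centre
    R_xlen_t cur = -1;
    double acc = 0.0;
    bool alive = true;
    while (alive) {
      double S = lookup_S(E, Egrid0, E_step, Sd, nS);
      double dep = S * step_um;
      double mx, my, mz;  // deposition point
      if (E - dep <= cutoff_MeV) {
        dep = E;          // residual (incl. sub-cutoff energy) locally
        mx = px; my = py; mz = pz;
        alive = false;
      } else {
        mx = px + 0.5 * step_um * dx;
        my = py + 0.5 * step_um * dy;
        mz = pz + 0.5 * step_um * dz;
        px += step_um * dx; py += step_um * dy; pz += step_um * dz;
        E -= dep;
      }
      double fx = mx * inv_v + 0.5 + half;
      double fy = my * inv_v + 0.5 + half;
      double fz = mz * inv_v + 0.5 + half;
      R_xlen_t idx = -1;
      if (fx >= 0 && fx < dim && fy >= 0 && fy < dim && fz >= 0 && fz < dim)
        idx = (R_xlen_t)(int)fx +
              (R_xlen_t)dim * ((int)fy + (R_xlen_t)dim * (int)fz);
      if (idx != cur) {
        if (cur >= 0 && acc > 0.0) { sum[cur] += acc; sumsq[cur] += acc * acc; }
        cur = idx;
        acc = 0.0;
      }
      if (idx >= 0) acc += dep;
    }
    if (cur >= 0 && acc > 0.0) { sum[cur] += acc; sumsq[cur] += acc * acc; }
  }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq);
}

// 8-connected component labelling of a binary matrix (nonzero = foreground).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (x(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + nr * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = pr + dr, cc = pc + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (x(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr + nr * cc);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Inverse-mapped affine warp with bilinear interpolation and zero fill.
// Pixel-centre coordinates: x = column index, y = row index, 0-based.
// `minv` is the 2x3 inverse map: (x_in, y_in)' = minv %*% (x_out, y_out, 1)'.
// [[Rcpp::export]]
NumericMatrix cpp_affine_warp(NumericMatrix img, NumericMatrix minv,
                              int out_nrow, int out_ncol) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_nrow, out_ncol);
  double a11 = minv(0, 0), a12 = minv(0, 1), a13 = minv(0, 2);
  double a21 = minv(1, 0), a22 = minv(1, 1), a23 = minv(1, 2);
  for (int c = 0; c < out_ncol; ++c) {
    for (int r = 0; r < out_nrow; ++r) {
      double xi = a11 * c + a12 * r + a13;
      double yi = a21 * c + a22 * r + a23;
      int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
      double wx = xi - x0, wy = yi - y0;
      double v = 0.0;
      for (int j = 0; j <= 1; ++j) {
        for (int i = 0; i <= 1; ++i) {
          int xx = x0 + i, yy = y0 + j;
          if (xx < 0 || xx >= nc || yy < 0 || yy >= nr) continue;
          double w = (i ? wx : 1.0 - wx) * (j ? wy : 1.0 - wy);
          v += w * img(yy, xx);
        }
      }
      out(r, c) = v;
    }
  }
  return out;
}
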