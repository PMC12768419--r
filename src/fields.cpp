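// Reaction-diffusion step for scalar fields on the cell lattice.
//
// dc/dt = div(D(x,y) grad c) - kd * c + sources, with D read from the cell
// type occupying each voxel and harmonic-mean diffusivity at voxel faces
// (conserves flux across material interfaces such as the superficial-cell
// barrier).  Two schemes:
//   * "implicit": operator splitting - exact exponential decay, then
//     backward-Euler diffusion sweeps (locally one-dimensional, Thomas
//     algorithm), unconditionally stable and positivity-preserving.
//   * "ftcs": forward-time central-space with the substep count supplied by
//     the caller; errors out on instability instead of clipping.
// Boundaries: lateral no-flux (zero-D wall columns also enforce this); top
// and bottom rows optionally pinned to zero concentration (Dirichlet).
// Source voxels (tear film) are re-clamped after every substep.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static void clamp_sources(double *c, const int *src_idx, int nsrc, double value) {
  for (int i = 0; i < nsrc; ++i) c[src_idx[i]] = value;
}

static inline double face_D(double d1, double d2) {
  if (d1 <= 0.0 || d2 <= 0.0) return 0.0;
  return 2.0 * d1 * d2 / (d1 + d2);
}

// Thomas solve of (I - dt*A) x = rhs for one line, A in flux form with face
// diffusivities Df[i] between node i and i+1 (length n-1).  No-flux ends.
static void solve_line(std::vector<double> &a, std::vector<double> &b,
                       std::vector<double> &cc, std::vector<double> &d, int n) {
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * cc[i - 1];
    d[i] -= m * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = (d[i] - cc[i] * d[i + 1]) / b[i];
}

// [[Rcpp::export]]
void field_step_implicit(NumericVector conc, IntegerVector spin, IntegerVector ctype,
                         int W, int H, NumericVector D_by_type, NumericVector kd,
                         double dt, int nsub, IntegerVector source_idx,
                         double source_value, bool dirichlet_tb) {
  double *c = REAL(conc);
  const int *sp = INTEGER(spin);
  const int *ct = INTEGER(ctype);
  const double *Dt = REAL(D_by_type);
  const double *kdt = REAL(kd);
  int kdn = kd.size();
  const int *src = INTEGER(source_idx);
  int nsrc = source_idx.size();
  if (nsub < 1) stop("nsub must be >= 1");
  double h = dt / nsub;

  // voxel diffusivities and decay factors from occupying cell type (a scalar
  // kd applies uniformly; a vector gives per-type decay, e.g. cellular uptake)
  std::vector<double> D((size_t)W * H), dec((size_t)W * H);
  std::vector<char> is_src((size_t)W * H, 0);
  for (int i = 0; i < nsrc; ++i) is_src[src[i]] = 1;
  for (int i = 0; i < W * H; ++i) {
    int s = sp[i];
    int t = s == 0 ? 0 : ct[s - 1];
    D[i] = Dt[t];
    dec[i] = std::exp(-(kdn == 1 ? kdt[0] : kdt[t]) * h);
  }

  std::vector<double> a(std::max(W, H)), b(std::max(W, H)), cc(std::max(W, H)),
      d(std::max(W, H));

  for (int sub = 0; sub < nsub; ++sub) {
    clamp_sources(c, src, nsrc, source_value);
    for (int i = 0; i < W * H; ++i) c[i] *= dec[i];
    clamp_sources(c, src, nsrc, source_value);

    // x sweeps (no-flux ends)
    for (int y = 0; y < H; ++y) {
      double *row = c + (size_t)W * y;
      const double *Drow = &D[(size_t)W * y];
      const char *srow = &is_src[(size_t)W * y];
      for (int x = 0; x < W; ++x) {
        double Dw = x > 0 ? face_D(Drow[x - 1], Drow[x]) : 0.0;
        double De = x < W - 1 ? face_D(Drow[x], Drow[x + 1]) : 0.0;
        a[x] = -h * Dw;
        cc[x] = -h * De;
        b[x] = 1.0 + h * (Dw + De);
        d[x] = row[x];
        if (srow[x]) { a[x] = 0.0; cc[x] = 0.0; b[x] = 1.0; d[x] = source_value; }
      }
      solve_line(a, b, cc, d, W);
      for (int x = 0; x < W; ++x) row[x] = d[x];
    }

    // y sweeps
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        int i = x + W * y;
        double Ds = y > 0 ? face_D(D[i - W], D[i]) : 0.0;
        double Dn = y < H - 1 ? face_D(D[i], D[i + W]) : 0.0;
        a[y] = -h * Ds;
        cc[y] = -h * Dn;
        b[y] = 1.0 + h * (Ds + Dn);
        d[y] = c[i];
        if (is_src[i]) { a[y] = 0.0; cc[y] = 0.0; b[y] = 1.0; d[y] = source_value; }
      }
      if (dirichlet_tb) {
        b[0] = 1.0; cc[0] = 0.0; d[0] = 0.0;
        b[H - 1] = 1.0; a[H - 1] = 0.0; d[H - 1] = 0.0;
      }
      solve_line(a, b, cc, d, H);
      for (int y = 0; y < H; ++y) c[x + W * y] = d[y];
    }

    clamp_sources(c, src, nsrc, source_value);
  }
}

// [[Rcpp::export]]
void field_step_ftcs(NumericVector conc, IntegerVector spin, IntegerVector ctype,
                     int W, int H, NumericVector D_by_type, NumericVector kd,
                     double dt, int nsub, IntegerVector source_idx,
                     double source_value, bool dirichlet_tb) {
  double *c = REAL(conc);
  const int *sp = INTEGER(spin);
  const int *ct = INTEGER(ctype);
  const double *Dt = REAL(D_by_type);
  const double *kdt = REAL(kd);
  int kdn = kd.size();
  const int *src = INTEGER(source_idx);
  int nsrc = source_idx.size();
  if (nsub < 1) stop("nsub must be >= 1");
  double h = dt / nsub;

  std::vector<double> D((size_t)W * H), kv((size_t)W * H), cn((size_t)W * H);
  std::vector<char> is_src((size_t)W * H, 0);
  for (int i = 0; i < nsrc; ++i) is_src[src[i]] = 1;
  for (int i = 0; i < W * H; ++i) {
    int s = sp[i];
    int t = s == 0 ? 0 : ct[s - 1];
    D[i] = Dt[t];
    kv[i] = kdn == 1 ? kdt[0] : kdt[t];
  }

  for (int sub = 0; sub < nsub; ++sub) {
    clamp_sources(c, src, nsrc, source_value);
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        int i = x + W * y;
        double flux = 0.0;
        if (x > 0)     flux += face_D(D[i - 1], D[i]) * (c[i - 1] - c[i]);
        if (x < W - 1) flux += face_D(D[i], D[i + 1]) * (c[i + 1] - c[i]);
        if (y > 0)     flux += face_D(D[i - W], D[i]) * (c[i - W] - c[i]);
        if (y < H - 1) flux += face_D(D[i], D[i + W]) * (c[i + W] - c[i]);
        cn[i] = is_src[i] ? source_value : c[i] + h * flux - h * kv[i] * c[i];
      }
    }
    if (dirichlet_tb) {
      for (int x = 0; x < W; ++x) { cn[x] = 0.0; cn[x + (size_t)W * (H - 1)] = 0.0; }
    }
    for (int i = 0; i < W * H; ++i) {
      if (cn[i] < 0.0) stop("FTCS step produced a negative concentration; increase the substep count");
      c[i] = cn[i];
    }
    clamp_sources(c, src, nsrc, source_value);
  }
}
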