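// Cellular Potts (Glazier-Graner-Hogeweg) lattice kernel.
//
// The lattice is a W x H grid stored column-major-in-x: voxel (x, y) lives at
// index x + W * y, 0-based, y = 0 at the bottom (stromal side).  spin[i] holds
// the cell id occupying voxel i (0 = medium).  Per-cell bookkeeping vectors
// are indexed by id (element id - 1) and are modified in place; R owns them
// and guarantees capacity.
//
// Neighborhoods: 2nd order (8-connected) for contact energy and copy-attempt
// candidates; 1st order (4-connected) for surface bookkeeping.  All randomness
// comes from R's RNG (unif_rand) so trajectories are a pure function of the
// R seed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NB8X[8] = {1, -1, 0, 0, 1, 1, -1, -1};
static const int NB8Y[8] = {0, 0, 1, -1, 1, -1, 1, -1};
static const int NB4X[4] = {1, -1, 0, 0};
static const int NB4Y[4] = {0, 0, 1, -1};

struct PottsCtx {
  int *spin;
  int W, H;
  int *ctype;        // per id
  double *vol, *tvol, *surf, *tsurf, *sumx, *sumy;
  const double *J;   // ntype x ntype, column-major
  int ntype;
  const double *lam_vol;   // per type
  const double *lam_surf;  // per type
  const int *frozen;       // per type
  // chemotaxis: nfield concentration grids, lambda per (field, type)
  std::vector<const double *> fields;
  const double *chemo;     // nfield x ntype column-major (nfield rows)
  int nfield;
  // links: rows (id1, id2, k, L0); per-id adjacency
  const double *links;
  int nlink;
  std::vector<std::vector<int> > link_of; // id-1 -> link row indices
  double temperature;
};

static inline int type_of(const PottsCtx &C, int id) {
  return id == 0 ? 0 : C.ctype[id - 1];
}

static inline double Jget(const PottsCtx &C, int ta, int tb) {
  return C.J[ta + C.ntype * tb];
}

// Energy change for copying the spin at voxel a onto voxel b.
static double delta_h(const PottsCtx &C, int a, int b) {
  const int W = C.W, H = C.H;
  int s = C.spin[a], sb = C.spin[b];
  if (s == sb) return 0.0;
  int ts = type_of(C, s), tb = type_of(C, sb);
  int xb = b % W, yb = b / W;

  // contact over 8-neighborhood of b
  double dH = 0.0;
  for (int k = 0; k < 8; ++k) {
    int xn = xb + NB8X[k], yn = yb + NB8Y[k];
    if (xn < 0 || xn >= W || yn < 0 || yn >= H) continue;
    int sn = C.spin[xn + W * yn];
    int tn = type_of(C, sn);
    if (sn != s)  dH += Jget(C, ts, tn);
    if (sn != sb) dH -= Jget(C, tb, tn);
  }

  // volume constraints (quadratic): gaining voxel for s, losing for sb
  if (s != 0 && C.lam_vol[ts] > 0) {
    double V = C.vol[s - 1], Vt = C.tvol[s - 1];
    dH += C.lam_vol[ts] * ((V + 1 - Vt) * (V + 1 - Vt) - (V - Vt) * (V - Vt));
  }
  if (sb != 0 && C.lam_vol[tb] > 0) {
    double V = C.vol[sb - 1], Vt = C.tvol[sb - 1];
    dH += C.lam_vol[tb] * ((V - 1 - Vt) * (V - 1 - Vt) - (V - Vt) * (V - Vt));
  }

  // surface constraints over 4-neighborhood (out-of-lattice counts as boundary)
  if ((s != 0 && C.lam_surf[ts] > 0) || (sb != 0 && C.lam_surf[tb] > 0)) {
    int dSs = 0, dSb = 0;
    for (int k = 0; k < 4; ++k) {
      int xn = xb + NB4X[k], yn = yb + NB4Y[k];
      int sn = (xn < 0 || xn >= W || yn < 0 || yn >= H) ? -1 : C.spin[xn + W * yn];
      dSs += (sn == s) ? -1 : 1;
      dSb += (sn == sb) ? 1 : -1;
    }
    if (s != 0 && C.lam_surf[ts] > 0) {
      double S = C.surf[s - 1], St = C.tsurf[s - 1];
      dH += C.lam_surf[ts] * ((S + dSs - St) * (S + dSs - St) - (S - St) * (S - St));
    }
    if (sb != 0 && C.lam_surf[tb] > 0) {
      double S = C.surf[sb - 1], St = C.tsurf[sb - 1];
      dH += C.lam_surf[tb] * ((S + dSb - St) * (S + dSb - St) - (S - St) * (S - St));
    }
  }

  // chemotaxis: bias on the extending (source) cell
  if (s != 0 && C.nfield > 0) {
    for (int f = 0; f < C.nfield; ++f) {
      double lam = C.chemo[f + C.nfield * ts];
      if (lam != 0.0) dH -= lam * (C.fields[f][b] - C.fields[f][(size_t)0 + a]);
    }
  }

  // Hookean center-to-center links (src gains voxel b, tgt loses it)
  if (C.nlink > 0 && ((s != 0 && !C.link_of[s - 1].empty()) ||
                      (sb != 0 && !C.link_of[sb - 1].empty()))) {
    double nsx = 0, nsy = 0, nsV = 0, nbx = 0, nby = 0, nbV = 0;
    if (s != 0) {
      nsV = C.vol[s - 1] + 1;
      nsx = (C.sumx[s - 1] + xb) / nsV;
      nsy = (C.sumy[s - 1] + yb) / nsV;
    }
    bool sb_vanishes = (sb != 0 && C.vol[sb - 1] <= 1);
    if (sb != 0 && !sb_vanishes) {
      nbV = C.vol[sb - 1] - 1;
      nbx = (C.sumx[sb - 1] - xb) / nbV;
      nby = (C.sumy[sb - 1] - yb) / nbV;
    }
    std::vector<int> seen;
    for (int which = 0; which < 2; ++which) {
      int c = which == 0 ? s : sb;
      if (c == 0) continue;
      if (which == 1 && sb_vanishes) continue; // pruned next MCS
      const std::vector<int> &lk = C.link_of[c - 1];
      for (size_t q = 0; q < lk.size(); ++q) {
        int r = lk[q];
        bool dup = false;
        for (size_t z = 0; z < seen.size(); ++z) if (seen[z] == r) dup = true;
        if (dup) continue;
        seen.push_back(r);
        int id1 = (int)C.links[r], id2 = (int)C.links[r + C.nlink];
        double kk = C.links[r + 2 * C.nlink], L0 = C.links[r + 3 * C.nlink];
        double x1o = C.sumx[id1 - 1] / C.vol[id1 - 1], y1o = C.sumy[id1 - 1] / C.vol[id1 - 1];
        double x2o = C.sumx[id2 - 1] / C.vol[id2 - 1], y2o = C.sumy[id2 - 1] / C.vol[id2 - 1];
        double x1n = x1o, y1n = y1o, x2n = x2o, y2n = y2o;
        if (id1 == s) { x1n = nsx; y1n = nsy; }
        if (id2 == s) { x2n = nsx; y2n = nsy; }
        if (id1 == sb && !sb_vanishes) { x1n = nbx; y1n = nby; }
        if (id2 == sb && !sb_vanishes) { x2n = nbx; y2n = nby; }
        double Lo = std::sqrt((x1o - x2o) * (x1o - x2o) + (y1o - y2o) * (y1o - y2o));
        double Ln = std::sqrt((x1n - x2n) * (x1n - x2n) + (y1n - y2n) * (y1n - y2n));
        dH += kk * ((Ln - L0) * (Ln - L0) - (Lo - L0) * (Lo - L0));
      }
    }
  }
  return dH;
}

static PottsCtx make_ctx(IntegerVector spin, int W, int H,
                         IntegerVector ctype, NumericVector vol, NumericVector tvol,
                         NumericVector surf, NumericVector tsurf,
                         NumericVector sumx, NumericVector sumy,
                         NumericMatrix J, double temperature,
                         NumericVector lam_vol, NumericVector lam_surf,
                         IntegerVector frozen,
                         List fields, NumericMatrix chemo,
                         NumericMatrix links) {
  PottsCtx C;
  C.spin = INTEGER(spin); C.W = W; C.H = H;
  C.ctype = INTEGER(ctype);
  C.vol = REAL(vol); C.tvol = REAL(tvol);
  C.surf = REAL(surf); C.tsurf = REAL(tsurf);
  C.sumx = REAL(sumx); C.sumy = REAL(sumy);
  C.J = REAL(J); C.ntype = J.nrow();
  C.lam_vol = REAL(lam_vol); C.lam_surf = REAL(lam_surf);
  C.frozen = INTEGER(frozen);
  C.nfield = fields.size();
  for (int f = 0; f < C.nfield; ++f) {
    NumericVector fv = fields[f];
    C.fields.push_back(REAL(fv));
  }
  C.chemo = REAL(chemo);
  C.links = REAL(links);
  C.nlink = links.nrow();
  C.temperature = temperature;
  int maxid = ctype.size();
  C.link_of.resize(maxid);
  for (int r = 0; r < C.nlink; ++r) {
    int id1 = (int)C.links[r], id2 = (int)C.links[r + C.nlink];
    if (id1 >= 1 && id1 <= maxid) C.link_of[id1 - 1].push_back(r);
    if (id2 >= 1 && id2 <= maxid) C.link_of[id2 - 1].push_back(r);
  }
  return C;
}

// [[Rcpp::export]]
double cpm_delta_h(IntegerVector spin, int W, int H,
                   IntegerVector ctype, NumericVector vol, NumericVector tvol,
                   NumericVector surf, NumericVector tsurf,
                   NumericVector sumx, NumericVector sumy,
                   NumericMatrix J, double temperature,
                   NumericVector lam_vol, NumericVector lam_surf,
                   IntegerVector frozen, List fields, NumericMatrix chemo,
                   NumericMatrix links, int src_voxel, int tgt_voxel) {
  if (src_voxel < 0 || src_voxel >= W * H || tgt_voxel < 0 || tgt_voxel >= W * H)
    stop("voxel index out of bounds");
  PottsCtx C = make_ctx(spin, W, H, ctype, vol, tvol, surf, tsurf, sumx, sumy,
                        J, temperature, lam_vol, lam_surf, frozen, fields,
                        chemo, links);
  int sb = C.spin[tgt_voxel];
  if (sb != 0 && C.frozen[type_of(C, sb)]) return R_PosInf;
  return delta_h(C, src_voxel, tgt_voxel);
}

// One Monte Carlo sweep: n_attempts random source/neighbor copy attempts.
// Returns the number of accepted copies.  Mutates spin and cell bookkeeping
// in place.
// [[Rcpp::export]]
int cpm_sweep(IntegerVector spin, int W, int H,
              IntegerVector ctype, NumericVector vol, NumericVector tvol,
              NumericVector surf, NumericVector tsurf,
              NumericVector sumx, NumericVector sumy,
              NumericMatrix J, double temperature,
              NumericVector lam_vol, NumericVector lam_surf,
              IntegerVector frozen, List fields, NumericMatrix chemo,
              NumericMatrix links, int n_attempts) {
  PottsCtx C = make_ctx(spin, W, H, ctype, vol, tvol, surf, tsurf, sumx, sumy,
                        J, temperature, lam_vol, lam_surf, frozen, fields,
                        chemo, links);
  GetRNGstate();
  int accepted = 0;
  const int N = W * H;
  for (int it = 0; it < n_attempts; ++it) {
    int a = (int)(unif_rand() * N); if (a >= N) a = N - 1;
    int k = (int)(unif_rand() * 8); if (k >= 8) k = 7;
    int xa = a % W, ya = a / W;
    int xb = xa + NB8X[k], yb = ya + NB8Y[k];
    if (xb < 0 || xb >= W || yb < 0 || yb >= H) continue;
    int b = xb + W * yb;
    int s = C.spin[a], sb = C.spin[b];
    if (s == sb) continue;
    int ts = type_of(C, s), tb = type_of(C, sb);
    if (C.frozen[ts] || C.frozen[tb]) continue;
    double dH = delta_h(C, a, b);
    bool ok = dH <= 0.0 || unif_rand() < std::exp(-dH / C.temperature);
    if (!ok) continue;
    // apply: b takes spin s
    C.spin[b] = s;
    int dSs = 0, dSb = 0;
    for (int q = 0; q < 4; ++q) {
      int xn = xb + NB4X[q], yn = yb + NB4Y[q];
      int sn = (xn < 0 || xn >= W || yn < 0 || yn >= H) ? -1 : C.spin[xn + W * yn];
      // note: spin[b] already updated but b is not its own neighbor
      dSs += (sn == s) ? -1 : 1;
      dSb += (sn == sb) ? 1 : -1;
    }
    if (s != 0) {
      C.vol[s - 1] += 1; C.sumx[s - 1] += xb; C.sumy[s - 1] += yb;
      C.surf[s - 1] += dSs;
    }
    if (sb != 0) {
      C.vol[sb - 1] -= 1; C.sumx[sb - 1] -= xb; C.sumy[sb - 1] -= yb;
      C.surf[sb - 1] += dSb;
    }
    ++accepted;
  }
  PutRNGstate();
  return accepted;
}

// Full recomputation of per-cell volume, centroid sums and (4-neighborhood)
// surface from the grid.  Used after direct voxel surgery (injury, sloughing)
// and at initialization.
// [[Rcpp::export]]
List cpm_recount(IntegerVector spin, int W, int H, int maxid) {
  NumericVector vol(maxid), sx(maxid), sy(maxid), sf(maxid);
  const int *sp = INTEGER(spin);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int s = sp[x + W * y];
      if (s <= 0 || s > maxid) continue;
      vol[s - 1] += 1; sx[s - 1] += x; sy[s - 1] += y;
      for (int k = 0; k < 4; ++k) {
        int xn = x + NB4X[k], yn = y + NB4Y[k];
        int sn = (xn < 0 || xn >= W || yn < 0 || yn >= H) ? -1 : sp[xn + W * yn];
        if (sn != s) sf[s - 1] += 1;
      }
    }
  }
  return List::create(_["volume"] = vol, _["sum_x"] = sx, _["sum_y"] = sy,
                      _["surface"] = sf);
}

// Per-cell neighbor census: counts of adjacent voxels by type over the
// 8-neighborhood (matrix maxid x ntype), plus the number of the cell's own
// voxels sharing a face (4-neighborhood) with basement membrane types.
// [[Rcpp::export]]
List cpm_contacts(IntegerVector spin, int W, int H, IntegerVector ctype,
                  int maxid, int ntype, IntegerVector membrane_types) {
  IntegerMatrix nb(maxid, ntype);
  IntegerVector epbm(maxid);
  const int *sp = INTEGER(spin);
  const int *ct = INTEGER(ctype);
  std::vector<char> is_mem(ntype, 0);
  for (int i = 0; i < membrane_types.size(); ++i) is_mem[membrane_types[i]] = 1;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int s = sp[x + W * y];
      if (s <= 0 || s > maxid) continue;
      bool touches_mem = false;
      for (int k = 0; k < 8; ++k) {
        int xn = x + NB8X[k], yn = y + NB8Y[k];
        if (xn < 0 || xn >= W || yn < 0 || yn >= H) continue;
        int sn = sp[xn + W * yn];
        if (sn == s) continue;
        int tn = sn == 0 ? 0 : ct[sn - 1];
        nb(s - 1, tn) += 1;
        if (k < 4 && is_mem[tn]) touches_mem = true;
      }
      if (touches_mem) epbm[s - 1] += 1;
    }
  }
  return List::create(_["neighbor_counts"] = nb, _["epbm_area"] = epbm);
}

// Sum of a scalar field over each cell's voxels (for per-cell means).
// [[Rcpp::export]]
NumericVector cpm_field_sums(NumericVector conc, IntegerVector spin, int maxid) {
  NumericVector out(maxid);
  const int *sp = INTEGER(spin);
  const double *c = REAL(conc);
  int N = spin.size();
  for (int i = 0; i < N; ++i) {
    int s = sp[i];
    if (s > 0 && s <= maxid) out[s - 1] += c[i];
  }
  return out;
}
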