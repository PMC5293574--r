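// Compiled core: energy model and Metropolis single-monomer kinetics.
//
// Units: k_B T = 1 (energies), l_max = 1 (lengths).  Positions are an
// (N+1) x 3 matrix, column-major; the wall is the plane z = 0.
// All randomness comes from R's RNG (unif_rand), so set.seed() at the R
// level makes every trajectory reproducible.  Per trial move exactly five
// uniform deviates are drawn, in this order: bead index, dx, dy, dz,
// acceptance eta.  eta is drawn even for moves rejected by the hard
// constraints (z' < 0, z' > z_max) so the stream position per trial is fixed.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct MP {
  double lmin, lmax, l0, r0, k;
  double alpha, rmin_ev, eps_ev;
  double b, eps_a, alpha_s, rmin_s;
  double pair_cutoff;  // <= 0 disables the excluded-volume tail cutoff
  // derived, precomputed once per call
  double lmin2, lmax2, cut2, fene_pref;
};

static MP parse_params(const List& p) {
  MP m;
  m.lmin    = as<double>(p["l_min"]);
  m.lmax    = as<double>(p["l_max"]);
  m.l0      = as<double>(p["l0"]);
  m.r0      = as<double>(p["r0"]);
  m.k       = as<double>(p["k_spring"]);
  m.alpha   = as<double>(p["alpha"]);
  m.rmin_ev = as<double>(p["r_min_ev"]);
  m.eps_ev  = as<double>(p["eps_ev"]);
  m.b       = as<double>(p["b"]);
  m.eps_a   = as<double>(p["eps_a"]);
  m.alpha_s = as<double>(p["alpha_s"]);
  m.rmin_s  = as<double>(p["r_min_s"]);
  m.pair_cutoff = as<double>(p["pair_cutoff"]);
  m.lmin2 = m.lmin * m.lmin;
  m.lmax2 = m.lmax * m.lmax;
  m.cut2 = m.pair_cutoff > 0.0 ? m.pair_cutoff * m.pair_cutoff : R_PosInf;
  m.fene_pref = -0.5 * m.k * m.r0 * m.r0;
  return m;
}

static inline double fene_e(double l, const MP& m) {
  if (l <= m.lmin || l >= m.lmax) return R_PosInf;
  double x = (l - m.l0) / m.r0;
  return -0.5 * m.k * m.r0 * m.r0 * std::log(1.0 - x * x);
}

static inline double morse_e(double r, const MP& m) {
  if (m.pair_cutoff > 0.0 && r >= m.pair_cutoff) return 0.0;
  double e = std::exp(-m.alpha * (r - m.rmin_ev));
  return m.eps_ev * (e * e - 2.0 * e);
}

// Surface attraction: one Morse term per bead in its height z.  No tail
// cutoff (a single cheap term per bead); the tail itself is ~1e-13 eps_a
// at z = 2 so this is numerically indistinguishable from a cutoff policy.
static inline double surf_e(double z, const MP& m) {
  if (m.eps_a == 0.0) return 0.0;
  double e = std::exp(-m.alpha_s * (z - m.rmin_s));
  return m.eps_a * (e * e - 2.0 * e);
}

// Bending at interior bead j uses the angle phi between successive bond
// vectors (phi = 0 when straight): U = b (1 - cos phi).  Equivalent to
// b (1 + cos theta) with theta the interior bond-bond angle.
static inline double bend_from_vecs(double ax, double ay, double az,
                                    double bx, double by, double bz,
                                    const MP& m) {
  double na = std::sqrt(ax * ax + ay * ay + az * az);
  double nb = std::sqrt(bx * bx + by * by + bz * bz);
  double c = (ax * bx + ay * by + az * bz) / (na * nb);
  if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
  return m.b * (1.0 - c);
}

// Accessors into a column-major position matrix, with one bead overridden.
struct Pos {
  const double* X;
  int n;
  int ov;             // overridden bead (-1 = none)
  double ox, oy, oz;
  inline double x(int i) const { return i == ov ? ox : X[i]; }
  inline double y(int i) const { return i == ov ? oy : X[i + n]; }
  inline double z(int i) const { return i == ov ? oz : X[i + 2 * n]; }
  inline double dist(int i, int j) const {
    double dx = x(i) - x(j), dy = y(i) - y(j), dz = z(i) - z(j);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  inline double bond(int i) const { return dist(i, i + 1); }  // bond i: beads i,i+1
  inline double bend_at(int j, const MP& m) const {           // interior bead j
    return bend_from_vecs(x(j) - x(j - 1), y(j) - y(j - 1), z(j) - z(j - 1),
                          x(j + 1) - x(j), y(j + 1) - y(j), z(j + 1) - z(j), m);
  }
};

// [[Rcpp::export]]
NumericVector cpp_total_energy(const NumericMatrix& pos, const List& params) {
  MP m = parse_params(params);
  int n = pos.nrow();
  Pos P{REAL(pos), n, -1, 0, 0, 0};
  double uf = 0, um = 0, ub = 0, us = 0;
  for (int i = 0; i + 1 < n; ++i) uf += fene_e(P.bond(i), m);
  double cut2 = m.pair_cutoff > 0 ? m.pair_cutoff * m.pair_cutoff : R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = P.x(i) - P.x(j), dy = P.y(i) - P.y(j), dz = P.z(i) - P.z(j);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < cut2) um += morse_e(std::sqrt(r2), m);
    }
  }
  for (int j = 1; j + 1 < n; ++j) ub += P.bend_at(j, m);
  for (int i = 0; i < n; ++i) us += surf_e(P.z(i), m);
  double tot = uf + um + ub + us;
  return NumericVector::create(_["u_fene"] = uf, _["u_morse"] = um,
                               _["u_bend"] = ub, _["u_surf"] = us,
                               _["u_total"] = tot);
}

// FENE energy from the squared bond length (caller checks the range).
static inline double fene_e2(double l2, const MP& m) {
  double x = (std::sqrt(l2) - m.l0) / m.r0;
  return m.fene_pref * std::log1p(-x * x);
}

// Energy change for moving `bead` (0-based) to (nx, ny, nz).
// Touches only the <=2 bonds, <=3 angles, the bead's surface term and the
// pair terms involving the moved bead.  The pair scan is two-pass: squared
// distances first (branch-free, vectorisable), then the few in-range pairs.
static double delta_core(const double* X, int n, int bead,
                         double nx, double ny, double nz, const MP& m) {
  const double* xs = X;
  const double* ys = X + n;
  const double* zs = X + 2 * n;
  double ox = xs[bead], oy = ys[bead], oz = zs[bead];
  double dU = 0;

  if (bead > 0) {
    double dx = nx - xs[bead - 1], dy = ny - ys[bead - 1],
           dz = nz - zs[bead - 1];
    double l2 = dx * dx + dy * dy + dz * dz;
    if (l2 <= m.lmin2 || l2 >= m.lmax2) return R_PosInf;
    dx = ox - xs[bead - 1]; dy = oy - ys[bead - 1]; dz = oz - zs[bead - 1];
    dU += fene_e2(l2, m) - fene_e2(dx * dx + dy * dy + dz * dz, m);
  }
  if (bead + 1 < n) {
    double dx = nx - xs[bead + 1], dy = ny - ys[bead + 1],
           dz = nz - zs[bead + 1];
    double l2 = dx * dx + dy * dy + dz * dz;
    if (l2 <= m.lmin2 || l2 >= m.lmax2) return R_PosInf;
    dx = ox - xs[bead + 1]; dy = oy - ys[bead + 1]; dz = oz - zs[bead + 1];
    dU += fene_e2(l2, m) - fene_e2(dx * dx + dy * dy + dz * dz, m);
  }
  if (m.b != 0.0) {
    Pos Po{X, n, -1, 0, 0, 0};
    Pos Pn{X, n, bead, nx, ny, nz};
    for (int j = bead - 1; j <= bead + 1; ++j)
      if (j >= 1 && j + 1 < n) dU += Pn.bend_at(j, m) - Po.bend_at(j, m);
  }
  if (m.eps_a != 0.0) dU += surf_e(nz, m) - surf_e(oz, m);

  double cut2 = m.cut2;
  double buf_o[1024], buf_n[1024];
  double* r2o = n <= 1024 ? buf_o : new double[n];
  double* r2n = n <= 1024 ? buf_n : new double[n];
  for (int j = 0; j < n; ++j) {
    double xj = xs[j], yj = ys[j], zj = zs[j];
    double dx = ox - xj, dy = oy - yj, dz = oz - zj;
    r2o[j] = dx * dx + dy * dy + dz * dz;
    dx = nx - xj; dy = ny - yj; dz = nz - zj;
    r2n[j] = dx * dx + dy * dy + dz * dz;
  }
  int lo = bead - 1 > 0 ? bead - 1 : 0;
  int hi = bead + 2 < n ? bead + 2 : n;
  for (int j = 0; j < lo; ++j) {
    if (r2o[j] < cut2) dU -= morse_e(std::sqrt(r2o[j]), m);
    if (r2n[j] < cut2) dU += morse_e(std::sqrt(r2n[j]), m);
  }
  for (int j = hi; j < n; ++j) {
    if (r2o[j] < cut2) dU -= morse_e(std::sqrt(r2o[j]), m);
    if (r2n[j] < cut2) dU += morse_e(std::sqrt(r2n[j]), m);
  }
  if (n > 1024) { delete[] r2o; delete[] r2n; }
  return dU;
}

// [[Rcpp::export]]
double cpp_delta_energy(const NumericMatrix& pos, int bead,
                        const NumericVector& newp, const List& params) {
  MP m = parse_params(params);
  return delta_core(REAL(pos), pos.nrow(), bead - 1,
                    newp[0], newp[1], newp[2], m);
}

// Shared acceptance rule: Delta = min(exp(-dU), 1); accept iff eta < Delta.
static inline bool accept_move(double dU, double eta) {
  double Delta = (dU <= 0.0) ? 1.0 : std::exp(-dU);
  return eta < Delta;
}

// Empirical acceptance frequency of the production rule at fixed dU.
// [[Rcpp::export]]
double cpp_acceptance_frequency(double dU, int n_trials) {
  GetRNGstate();
  long acc = 0;
  for (int t = 0; t < n_trials; ++t)
    if (accept_move(dU, unif_rand())) ++acc;
  PutRNGstate();
  return (double)acc / n_trials;
}

// [[Rcpp::export]]
List cpp_run_mcs(const NumericMatrix& pos_in, const List& params,
                 double n_mcs, double max_disp, bool wall, double z_max) {
  MP m = parse_params(params);
  NumericMatrix pos = clone(pos_in);
  int n = pos.nrow();
  double* X = REAL(pos);
  long long trials = (long long)(n_mcs * n + 0.5);
  long long acc = 0;
  double du_sum = 0;
  GetRNGstate();
  for (long long t = 0; t < trials; ++t) {
    int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
    double nx = X[i]         + (unif_rand() * 2.0 - 1.0) * max_disp;
    double ny = X[i + n]     + (unif_rand() * 2.0 - 1.0) * max_disp;
    double nz = X[i + 2 * n] + (unif_rand() * 2.0 - 1.0) * max_disp;
    double eta = unif_rand();
    if ((wall && nz < 0.0) || nz > z_max) continue;
    double dU = delta_core(X, n, i, nx, ny, nz, m);
    if (accept_move(dU, eta)) {
      X[i] = nx; X[i + n] = ny; X[i + 2 * n] = nz;
      ++acc; du_sum += dU;
    }
  }
  PutRNGstate();
  return List::create(_["positions"] = pos, _["accepted"] = (double)acc,
                      _["trials"] = (double)trials, _["du_sum"] = du_sum);
}

// One trial move with full diagnostics; same deviate order as cpp_run_mcs.
// [[Rcpp::export]]
List cpp_trial_move(const NumericMatrix& pos_in, const List& params,
                    double max_disp, bool wall, double z_max) {
  MP m = parse_params(params);
  NumericMatrix pos = clone(pos_in);
  int n = pos.nrow();
  double* X = REAL(pos);
  GetRNGstate();
  int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
  double nx = X[i]         + (unif_rand() * 2.0 - 1.0) * max_disp;
  double ny = X[i + n]     + (unif_rand() * 2.0 - 1.0) * max_disp;
  double nz = X[i + 2 * n] + (unif_rand() * 2.0 - 1.0) * max_disp;
  double eta = unif_rand();
  PutRNGstate();
  bool constrained = (wall && nz < 0.0) || nz > z_max;
  double dU = constrained ? R_PosInf : delta_core(X, n, i, nx, ny, nz, m);
  bool ok = !constrained && accept_move(dU, eta);
  if (ok) { X[i] = nx; X[i + n] = ny; X[i + 2 * n] = nz; }
  return List::create(_["positions"] = pos, _["accepted"] = ok,
                      _["dU"] = dU, _["bead"] = i + 1);
}
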