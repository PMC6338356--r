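#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Crank-Nicolson march for the backward-in-initial-condition representation of
// the Wright-Fisher transition density action:
//   du/dt = x(1-x) u'' + gamma x(1-x) u',  u(t,0)=u(t,1)=0,  u(0,x)=f(x).
// Marches all columns of f0 simultaneously (the tridiagonal factor depends only
// on gamma and the grid) and records the solution at the requested step
// indices.  If flux_col >= 0 that column is taken to be the action of
// f(y) = s(y)/s(1); the limit phi(u) = lim_{x->0} u(u,x)/s(x) * s(1) is
// extrapolated linearly from the first two grid points at every step and its
// running trapezoid integral Phi(t) = int_0^t phi(u) du is recorded alongside.
//
// x must be a uniform interior grid (x_1 = h, ..., x_G = 1 - h); boundary
// values are identically zero and are not stored.
// [[Rcpp::export]]
List cn_march_cpp(double gamma, NumericVector x, NumericMatrix f0,
                  IntegerVector record_steps, double dt,
                  int flux_col, NumericVector flux_aux) {
  const int G = x.size();
  const int K = f0.ncol();
  const int R = record_steps.size();
  if (G < 3) stop("grid too small");
  const double h = x[1] - x[0];

  // operator A (tridiagonal): lo, di, up
  std::vector<double> lo(G), di(G), up(G);
  for (int i = 0; i < G; ++i) {
    const double a  = x[i] * (1.0 - x[i]);
    const double c2 = a / (h * h);
    const double c1 = gamma * a / (2.0 * h);
    lo[i] = c2 - c1;
    di[i] = -2.0 * c2;
    up[i] = c2 + c1;
  }

  // implicit matrix M = I - dt/2 A; Thomas factorization (M is constant)
  std::vector<double> ml(G), md(G), mu(G), cp(G), denom(G);
  for (int i = 0; i < G; ++i) {
    ml[i] = -0.5 * dt * lo[i];
    md[i] = 1.0 - 0.5 * dt * di[i];
    mu[i] = -0.5 * dt * up[i];
  }
  denom[0] = md[0];
  if (denom[0] == 0.0) stop("tridiagonal solve failed (zero pivot)");
  cp[0] = mu[0] / denom[0];
  for (int i = 1; i < G; ++i) {
    denom[i] = md[i] - ml[i] * cp[i - 1];
    if (denom[i] == 0.0) stop("tridiagonal solve failed (zero pivot)");
    cp[i] = mu[i] / denom[i];
  }

  std::vector<double> u(static_cast<size_t>(G) * K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < G; ++i) u[i + (size_t)G * k] = f0(i, k);

  int n_steps = 0;
  for (int r = 0; r < R; ++r) if (record_steps[r] > n_steps) n_steps = record_steps[r];

  NumericVector u_rec(static_cast<R_xlen_t>(G) * K * R);
  u_rec.attr("dim") = IntegerVector::create(G, K, R);
  NumericVector phi_rec(R);
  double* urp = REAL(u_rec);

  const bool do_flux = flux_col >= 0;
  double inv_s1 = 0.0, inv_s2 = 0.0, s1 = 1.0;
  double phi_prev = 1.0;  // phi(0) = 1 for a fresh start: u(0,x) = s(x)/s(1)
  double Phi = 0.0;
  if (do_flux) {
    if (flux_aux.size() != 5) stop("flux_aux must have length 5");
    inv_s1 = flux_aux[0]; inv_s2 = flux_aux[1]; s1 = flux_aux[2];
    Phi = flux_aux[3]; phi_prev = flux_aux[4];  // resuming a segmented march
  }

  std::vector<double> rhs(G);
  const double hdt = 0.5 * dt;
  const double* lop = lo.data(); const double* dip = di.data();
  const double* upp = up.data(); const double* mlp = ml.data();
  const double* cpp_ = cp.data(); const double* dnp = denom.data();

  int rec_idx = 0;
  // record step 0 if requested
  while (rec_idx < R && record_steps[rec_idx] == 0) {
    std::copy(u.begin(), u.end(), urp + (R_xlen_t)G * K * rec_idx);
    phi_rec[rec_idx] = Phi;
    ++rec_idx;
  }

  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < K; ++k) {
      double* uk = &u[(size_t)G * k];
      // explicit half: rhs = (I + dt/2 A) u
      rhs[0] = uk[0] + hdt * (dip[0] * uk[0] + upp[0] * uk[1]);
      for (int i = 1; i < G - 1; ++i)
        rhs[i] = uk[i] + hdt * (lop[i] * uk[i - 1] + dip[i] * uk[i] +
                                upp[i] * uk[i + 1]);
      rhs[G - 1] = uk[G - 1] + hdt * (lop[G - 1] * uk[G - 2] +
                                      dip[G - 1] * uk[G - 1]);
      // implicit half: Thomas solve (forward into uk as scratch)
      uk[0] = rhs[0] / dnp[0];
      for (int i = 1; i < G; ++i)
        uk[i] = (rhs[i] - mlp[i] * uk[i - 1]) / dnp[i];
      for (int i = G - 2; i >= 0; --i) uk[i] -= cpp_[i] * uk[i + 1];
    }
    if (do_flux) {
      const double* uf = &u[(size_t)G * flux_col];
      const double p1 = uf[0] * inv_s1 * s1;
      const double p2 = uf[1] * inv_s2 * s1;
      double phi_new = 2.0 * p1 - p2;  // linear extrapolation to x = 0
      if (phi_new < 0.0) phi_new = 0.0;
      Phi += 0.5 * dt * (phi_prev + phi_new);
      phi_prev = phi_new;
    }
    while (rec_idx < R && record_steps[rec_idx] == step) {
      std::copy(u.begin(), u.end(), urp + (R_xlen_t)G * K * rec_idx);
      phi_rec[rec_idx] = Phi;
      ++rec_idx;
    }
  }
  if (rec_idx != R) stop("record_steps must be sorted and <= total steps");

  return List::create(_["u"] = u_rec, _["Phi"] = phi_rec,
                      _["phi_state"] = NumericVector::create(Phi, phi_prev));
}

static inline void catmull_rom_w(double s, double* w) {
  // uniform Catmull-Rom weights for stencil (-1, 0, 1, 2), s in [0,1]
  const double s2 = s * s, s3 = s2 * s;
  w[0] = 0.5 * (-s3 + 2.0 * s2 - s);
  w[1] = 0.5 * (3.0 * s3 - 5.0 * s2 + 2.0);
  w[2] = 0.5 * (-3.0 * s3 + 4.0 * s2 + s);
  w[3] = 0.5 * (s3 - s2);
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// core: interpolate nu_j (j = 0,1,2) at (g, tq) for one pair, given
// precomputed t-stencil indices/weights; writes 3 values to out
static void nu_interp_one(const double* tbl, int ng, int nt, int np,
                          double g0, double dg, const int* it_idx,
                          const double* wt, double g, int pair, double* out) {
  const double gmax = g0 + dg * (ng - 1);
  double gshift = 0.0;
  const bool lo_ext = g < g0, hi_ext = g > gmax;
  if (lo_ext) { gshift = g - g0; g = g0; }
  if (hi_ext) { gshift = g - gmax; g = gmax; }
  double gs = (g - g0) / dg;
  int jg = (int)std::floor(gs);
  jg = clampi(jg, 0, ng - 2);
  double sg = gs - jg;
  if (sg < 0.0) sg = 0.0;
  if (sg > 1.0) sg = 1.0;
  double wg[4];
  catmull_rom_w(sg, wg);
  int ig_idx[4];
  for (int a = 0; a < 4; ++a) ig_idx[a] = clampi(jg - 1 + a, 0, ng - 1);
  const R_xlen_t strj = ng;
  const R_xlen_t strp = (R_xlen_t)ng * nt;
  const R_xlen_t strl = (R_xlen_t)ng * nt * np;
  for (int l = 0; l < 3; ++l) {
    const R_xlen_t base = strp * pair + strl * l;
    double v = 0.0;
    for (int a = 0; a < 4; ++a) {
      double vt = 0.0;
      for (int b = 0; b < 4; ++b)
        vt += wt[b] * tbl[ig_idx[a] + strj * it_idx[b] + base];
      v += wg[a] * vt;
    }
    if (lo_ext || hi_ext) {
      const int e0 = lo_ext ? 0 : ng - 1;
      const int e1 = lo_ext ? 1 : ng - 2;
      double v0 = 0.0, v1 = 0.0;
      for (int b = 0; b < 4; ++b) {
        v0 += wt[b] * tbl[e0 + strj * it_idx[b] + base];
        v1 += wt[b] * tbl[e1 + strj * it_idx[b] + base];
      }
      double slope = (lo_ext ? (v1 - v0) : (v0 - v1)) / dg;
      // the nu_j decay toward gamma -> -inf; a negative left-edge slope can
      // only come from noise-floor values, so force decay there
      if (lo_ext && slope < 0.0) slope = 0.0;
      v = v0 + slope * gshift;
    }
    // the table stores log(nu); linear extrapolation in log space decays
    // (or grows) exponentially beyond the gamma range.  Cap to avoid
    // overflow from extreme extrapolation.
    out[l] = std::exp(v < 700.0 ? v : 700.0);
  }
}

static void t_stencil(int nt, double t0, double dtg, double tq,
                      int* it_idx, double* wt) {
  double ts = (tq - t0) / dtg;
  int jt = (int)std::floor(ts);
  jt = clampi(jt, 0, nt - 2);
  double st = ts - jt;
  if (st < 0.0) st = 0.0;
  if (st > 1.0) st = 1.0;
  catmull_rom_w(st, wt);
  for (int a = 0; a < 4; ++a) it_idx[a] = clampi(jt - 1 + a, 0, nt - 1);
}

// Gauss-Hermite averaged nu for every locus in one call:
// gbar_i = sum_k ghw_k nu(gamma_i + sqrt(2) sigma_w z_k) / sqrt(pi).
// pair_idx is 0-based per locus.  Returns L x 3.
// [[Rcpp::export]]
NumericMatrix gbar_interp_cpp(NumericVector tbl, IntegerVector dims,
                              double g0, double dg, double t0, double dtg,
                              NumericVector gamma_i, double sigma_w, double tq,
                              IntegerVector pair_idx, NumericVector ghz,
                              NumericVector ghw) {
  const int ng = dims[0], nt = dims[1], np = dims[2];
  const int L = gamma_i.size();
  const int K = ghz.size();
  NumericMatrix out(L, 3);
  int it_idx[4];
  double wt[4];
  t_stencil(nt, t0, dtg, tq, it_idx, wt);
  const double rt2sw = std::sqrt(2.0) * sigma_w;
  const double inv_rtpi = 1.0 / std::sqrt(M_PI);
  double nu[3];
  for (int i = 0; i < L; ++i) {
    const int pair = pair_idx[i];
    if (pair < 0 || pair >= np) stop("pair index out of range");
    double acc[3] = {0.0, 0.0, 0.0};
    if (sigma_w == 0.0) {
      nu_interp_one(REAL(tbl), ng, nt, np, g0, dg, it_idx, wt,
                    gamma_i[i], pair, acc);
    } else {
      for (int k = 0; k < K; ++k) {
        nu_interp_one(REAL(tbl), ng, nt, np, g0, dg, it_idx, wt,
                      gamma_i[i] + rt2sw * ghz[k], pair, nu);
        for (int l = 0; l < 3; ++l) acc[l] += ghw[k] * nu[l];
      }
      for (int l = 0; l < 3; ++l) acc[l] *= inv_rtpi;
    }
    for (int l = 0; l < 3; ++l) out(i, l) = acc[l];
  }
  return out;
}

// Local-cubic (Catmull-Rom) interpolation of a cached table of
// log(nu_j) = log(Lambda_j / s(1)) values on a uniform (gamma, t) grid.
// tbl has dim (ng, nt, np, 3).  Queries outside the gamma range are linearly
// extrapolated in log space from the edge.  Returns nu (exponentiated).
// [[Rcpp::export]]
NumericMatrix nu_interp_cpp(NumericVector tbl, IntegerVector dims,
                            double g0, double dg, double t0, double dtg,
                            NumericVector gq, double tq, int pair) {
  const int ng = dims[0], nt = dims[1], np = dims[2];
  if (pair < 0 || pair >= np) stop("pair index out of range");
  const int nq = gq.size();
  NumericMatrix out(nq, 3);
  int it_idx[4];
  double wt[4];
  t_stencil(nt, t0, dtg, tq, it_idx, wt);
  double nu[3];
  for (int q = 0; q < nq; ++q) {
    nu_interp_one(REAL(tbl), ng, nt, np, g0, dg, it_idx, wt, gq[q], pair, nu);
    for (int l = 0; l < 3; ++l) out(q, l) = nu[l];
  }
  return out;
}
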