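// Two-pool Bloch-McConnell propagation for pulsed-saturation MRF schedules.
//
// State ordering: (Mxw, Myw, Mzw, Mxs, Mys, Mzs), water then solute, in
// units of the equilibrium water magnetization (M0w = 1, M0s = fs).
// Evolution over an interval with constant RF is dM/dt = A M + b, solved
// either exactly through the augmented 7x7 matrix exponential or by RK4
// time stepping (the independent numerical oracle).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the 6x6 coefficient matrix and constant term.
// Semisolid pools (rrfb >= 0 with semisolid flag) replace the transverse RF
// coupling of the solute pool by a lineshape-derived saturation rate on Mzs.
static void bm_system(const arma::vec& p, double w1, double dww, double dws,
                      double rrfb, bool semisolid,
                      arma::mat& A, arma::vec& b) {
  const double r1w = p[0], r2w = p[1], r1s = p[2], r2s = p[3];
  const double fs = p[4], ksw = p[5];
  const double kb = ksw;       // solute -> water
  const double ka = fs * ksw;  // water -> solute (detailed balance)
  const double w1s = semisolid ? 0.0 : w1;
  const double rsat = semisolid ? rrfb : 0.0;

  A.zeros(6, 6);
  b.zeros(6);

  A(0, 0) = -(r2w + ka); A(0, 1) = dww;          A(0, 3) = kb;
  A(1, 0) = -dww;        A(1, 1) = -(r2w + ka);  A(1, 2) = w1; A(1, 4) = kb;
  A(2, 1) = -w1;         A(2, 2) = -(r1w + ka);  A(2, 5) = kb;
  A(3, 3) = -(r2s + kb); A(3, 4) = dws;          A(3, 0) = ka;
  A(4, 3) = -dws;        A(4, 4) = -(r2s + kb);  A(4, 5) = w1s; A(4, 1) = ka;
  A(5, 4) = -w1s;        A(5, 5) = -(r1s + kb + rsat); A(5, 2) = ka;

  b[2] = r1w * 1.0;
  b[5] = r1s * fs;
}

static arma::mat augmented_propagator(const arma::mat& A, const arma::vec& b,
                                      double dt) {
  arma::mat G(7, 7, arma::fill::zeros);
  G.submat(0, 0, 5, 5) = A;
  G.col(6).head(6) = b;
  return arma::expmat(G * dt);
}

// [[Rcpp::export(name = ".bm_propagate_cpp")]]
arma::vec bm_propagate_cpp(const arma::vec& state, const arma::vec& pool,
                           double w1, double dww, double dws, double rrfb,
                           bool semisolid, double duration) {
  arma::mat A; arma::vec b;
  bm_system(pool, w1, dww, dws, rrfb, semisolid, A, b);
  arma::mat P = augmented_propagator(A, b, duration);
  arma::vec aug(7);
  aug.head(6) = state; aug[6] = 1.0;
  arma::vec out = P * aug;
  return out.head(6);
}

// One RK4 step of dM/dt = A M + b, hardcoded 6-dim.
static inline void rk4_step(const arma::mat& A, const arma::vec& b,
                            arma::vec& y, double h) {
  arma::vec k1 = A * y + b;
  arma::vec k2 = A * (y + 0.5 * h * k1) + b;
  arma::vec k3 = A * (y + 0.5 * h * k2) + b;
  arma::vec k4 = A * (y + h * k3) + b;
  y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

// RK4 time stepping over an interval. For the constant-coefficient linear
// system dM/dt = A M + b the classical RK4 update is exactly the affine map
//   y_{n+1} = R y_n + d,
//   R = I + hA + (hA)^2/2 + (hA)^3/6 + (hA)^4/24,
//   d = (hI + h^2 A/2 + h^3 A^2/6 + h^4 A^3/24) b,
// so R and d are precomputed once per interval and the map is iterated;
// the iterates are the RK4 iterates (global O(h^4) error, step <= dt).
static void rk4_interval(const arma::mat& A, const arma::vec& b,
                         arma::vec& y, double duration, double dt) {
  if (duration <= 0) return;
  int n = (int)std::ceil(duration / dt - 1e-12);
  if (n < 1) n = 1;
  const double h = duration / n;

  const arma::mat hA = h * A;
  const arma::mat hA2 = hA * hA;
  const arma::mat hA3 = hA2 * hA;
  const arma::mat I = arma::eye(6, 6);
  const arma::mat R = I + hA + hA2 / 2.0 + hA3 / 6.0 + hA3 * hA / 24.0;
  const arma::vec d = (h * I + h * hA / 2.0 + h * hA2 / 6.0 +
                       h * hA3 / 24.0) * b;

  const double* r = R.memptr();  // col-major 6x6
  const double* dd = d.memptr();
  double* yy = y.memptr();
  double acc[6];
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < 6; ++i) acc[i] = dd[i];
    for (int j = 0; j < 6; ++j) {
      const double yj = yy[j];
      const double* col = r + 6 * j;
      for (int i = 0; i < 6; ++i) acc[i] += col[i] * yj;
    }
    for (int i = 0; i < 6; ++i) yy[i] = acc[i];
  }
}

// [[Rcpp::export(name = ".bm_rk4_propagate_cpp")]]
arma::vec bm_rk4_propagate_cpp(const arma::vec& state, const arma::vec& pool,
                               double w1, double dww, double dws, double rrfb,
                               bool semisolid, double duration, double dt) {
  arma::mat A; arma::vec b;
  bm_system(pool, w1, dww, dws, rrfb, semisolid, A, b);
  arma::vec y = state;
  rk4_interval(A, b, y, duration, dt);
  return y;
}

// Schedule matrix columns (one row per entry):
//   0: w1 (rad/s)          1: dww (rad/s)   2: dws (rad/s)
//   3: rrfb (Hz)           4: n_pulses      5: pulse_duration (s)
//   6: interpulse_delay(s) 7: recovery (s)  8: flip (rad)  9: spoil factor
// Readout model: signal = Mzw * sin(flip); afterwards Mzw *= spoil
// (longitudinal scaling, default cos(flip) set by caller) and all
// transverse components are crushed to zero.
static arma::vec simulate_core(const arma::vec& pool, const arma::mat& sched,
                               bool semisolid, bool use_rk4, double dt) {
  const int m = sched.n_rows;
  arma::vec y(6, arma::fill::zeros);
  y[2] = 1.0;        // water Mz at thermal equilibrium
  y[5] = pool[4];    // solute Mz = fs
  arma::vec sig(m);

  arma::mat A_pulse, A_free;
  arma::vec b_pulse, b_free;

  for (int e = 0; e < m; ++e) {
    const double w1 = sched(e, 0), dww = sched(e, 1), dws = sched(e, 2);
    const double rrfb = sched(e, 3);
    const int np = (int)sched(e, 4);
    const double tp = sched(e, 5), tg = sched(e, 6), trec = sched(e, 7);
    const double flip = sched(e, 8);

    bm_system(pool, w1, dww, dws, rrfb, semisolid, A_pulse, b_pulse);
    bm_system(pool, 0.0, dww, dws, 0.0, semisolid, A_free, b_free);

    if (use_rk4) {
      for (int k = 0; k < np; ++k) {
        rk4_interval(A_pulse, b_pulse, y, tp, dt);
        if (k < np - 1) rk4_interval(A_free, b_free, y, tg, dt);
      }
    } else {
      arma::mat P = augmented_propagator(A_pulse, b_pulse, tp);
      arma::vec aug(7);
      aug.head(6) = y; aug[6] = 1.0;
      if (np > 0) {
        arma::mat G;
        if (np > 1 && tg > 0) G = augmented_propagator(A_free, b_free, tg);
        aug = P * aug;
        for (int k = 1; k < np; ++k) {
          if (tg > 0) aug = G * aug;
          aug = P * aug;
        }
      }
      y = aug.head(6);
    }

    sig[e] = y[2] * std::sin(flip);
    y[2] *= sched(e, 9);
    y[0] = y[1] = y[3] = y[4] = 0.0;  // crushers

    if (trec > 0) {
      if (use_rk4) {
        rk4_interval(A_free, b_free, y, trec, dt);
      } else {
        arma::vec aug(7);
        aug.head(6) = y; aug[6] = 1.0;
        aug = augmented_propagator(A_free, b_free, trec) * aug;
        y = aug.head(6);
      }
    }
  }
  return sig;
}

// [[Rcpp::export(name = ".bm_simulate_schedule_cpp")]]
arma::vec bm_simulate_schedule_cpp(const arma::vec& pool,
                                   const arma::mat& sched, bool semisolid) {
  return simulate_core(pool, sched, semisolid, false, 0.0);
}

// [[Rcpp::export(name = ".bm_rk4_schedule_cpp")]]
arma::vec bm_rk4_schedule_cpp(const arma::vec& pool, const arma::mat& sched,
                              bool semisolid, double dt) {
  return simulate_core(pool, sched, semisolid, true, dt);
}

// Batch simulation over a parameter matrix (rows: r1w r2w r1s r2s fs ksw)
// with a shared schedule; used for dictionary generation.
// [[Rcpp::export(name = ".bm_simulate_batch_cpp")]]
arma::mat bm_simulate_batch_cpp(const arma::mat& pools, const arma::mat& sched,
                                bool semisolid) {
  arma::mat out(pools.n_rows, sched.n_rows);
  for (arma::uword i = 0; i < pools.n_rows; ++i) {
    out.row(i) = simulate_core(pools.row(i).t(), sched, semisolid,
                               false, 0.0).t();
  }
  return out;
}
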