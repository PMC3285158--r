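// Fixed-step RK4 integration of the Balloon hemodynamic system and of the
// two-region DCM extension, plus matrix propagators that advance all UKF
// sigma points in one call (each column carries its own state and
// parameters).  State positivity is enforced by flooring f, v, q at
// STATE_FLOOR; every floor application is counted and reported.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double STATE_FLOOR = 1e-6;

// Boxcar (squarewave) stimulus over half-open blocks [onset, onset+duration).
struct Boxcar {
  const double* onsets;
  const double* durations;
  int n;
  double amplitude;
  double operator()(double t) const {
    for (int i = 0; i < n; ++i) {
      if (t < onsets[i]) break;  // onsets sorted ascending
      if (t < onsets[i] + durations[i]) return amplitude;
    }
    return 0.0;
  }
};

// dx for one Balloon region; x = (s, f, v, q).
inline void balloon_deriv(const double* x, double eps, double ts, double tf,
                          double t0, double E0, double alpha, double u,
                          double* dx, int& nclamp) {
  double s = x[0], f = x[1], v = x[2], q = x[3];
  if (f < STATE_FLOOR) { f = STATE_FLOOR; ++nclamp; }
  if (v < STATE_FLOOR) { v = STATE_FLOOR; ++nclamp; }
  if (q < STATE_FLOOR) { q = STATE_FLOOR; ++nclamp; }
  double fout = std::pow(v, 1.0 / alpha);  // outflow v^(1/alpha)
  // oxygen extraction; exact E0 at resting inflow
  double E = (f == 1.0) ? E0 : 1.0 - std::pow(1.0 - E0, 1.0 / f);
  dx[0] = eps * u - s / ts - (f - 1.0) / tf;
  dx[1] = s;
  dx[2] = (f - fout) / t0;
  dx[3] = (f * E / E0 - fout * q / v) / t0;
}

// The boxcar input is held constant over each step (sampled at the step
// midpoint): with block edges aligned to the step grid this treats the
// piecewise-constant input exactly and keeps full RK4 order, instead of
// smearing the jump through the k1/k4 stages.
inline void balloon_rk4(double* x, double t, double h, double eps, double ts,
                        double tf, double t0, double E0, double alpha,
                        const Boxcar& u, int& nclamp) {
  double k1[4], k2[4], k3[4], k4[4], xt[4];
  double um = u(t + 0.5 * h);
  balloon_deriv(x, eps, ts, tf, t0, E0, alpha, um, k1, nclamp);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + 0.5 * h * k1[i];
  balloon_deriv(xt, eps, ts, tf, t0, E0, alpha, um, k2, nclamp);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + 0.5 * h * k2[i];
  balloon_deriv(xt, eps, ts, tf, t0, E0, alpha, um, k3, nclamp);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + h * k3[i];
  balloon_deriv(xt, eps, ts, tf, t0, E0, alpha, um, k4, nclamp);
  for (int i = 0; i < 4; ++i)
    x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  for (int i = 1; i < 4; ++i)
    if (x[i] < STATE_FLOOR) { x[i] = STATE_FLOOR; ++nclamp; }
}

// Two-region DCM: x = (z1, z2, s1, f1, v1, q1, s2, f2, v2, q2);
// conn = (a11, a12, a21, a22, c1, c2); neuronal state z_i drives region i.
inline void dcm_deriv(const double* x, const double* eps2, double ts, double tf,
                      double t0, double E0, double alpha, const double* conn,
                      double u1, double u2, double* dx, int& nclamp) {
  dx[0] = conn[0] * x[0] + conn[1] * x[1] + conn[4] * u1;
  dx[1] = conn[2] * x[0] + conn[3] * x[1] + conn[5] * u2;
  balloon_deriv(x + 2, eps2[0], ts, tf, t0, E0, alpha, x[0], dx + 2, nclamp);
  balloon_deriv(x + 6, eps2[1], ts, tf, t0, E0, alpha, x[1], dx + 6, nclamp);
}

inline void dcm_rk4(double* x, double t, double h, const double* eps2,
                    double ts, double tf, double t0, double E0, double alpha,
                    const double* conn, const Boxcar& u1f, const Boxcar& u2f,
                    int& nclamp) {
  double k1[10], k2[10], k3[10], k4[10], xt[10];
  double u1m = u1f(t + 0.5 * h), u2m = u2f(t + 0.5 * h);
  dcm_deriv(x, eps2, ts, tf, t0, E0, alpha, conn, u1m, u2m, k1, nclamp);
  for (int i = 0; i < 10; ++i) xt[i] = x[i] + 0.5 * h * k1[i];
  dcm_deriv(xt, eps2, ts, tf, t0, E0, alpha, conn, u1m, u2m, k2, nclamp);
  for (int i = 0; i < 10; ++i) xt[i] = x[i] + 0.5 * h * k2[i];
  dcm_deriv(xt, eps2, ts, tf, t0, E0, alpha, conn, u1m, u2m, k3, nclamp);
  for (int i = 0; i < 10; ++i) xt[i] = x[i] + h * k3[i];
  dcm_deriv(xt, eps2, ts, tf, t0, E0, alpha, conn, u1m, u2m, k4, nclamp);
  for (int i = 0; i < 10; ++i)
    x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  for (int r = 0; r < 2; ++r)
    for (int i = 3; i < 6; ++i)
      if (x[2 + 4 * r + i - 2] < STATE_FLOOR) {
        x[2 + 4 * r + i - 2] = STATE_FLOOR;
        ++nclamp;
      }
}

}  // namespace

// [[Rcpp::export]]
List integrate_balloon_cpp(NumericVector init, NumericVector params,
                           double alpha, NumericVector onsets,
                           NumericVector durations, double amplitude,
                           double t_start, int n_steps, double dt) {
  Boxcar u{onsets.begin(), durations.begin(), (int)onsets.size(), amplitude};
  NumericMatrix out(n_steps + 1, 4);
  double x[4] = {init[0], init[1], init[2], init[3]};
  int nclamp = 0;
  for (int j = 0; j < 4; ++j) out(0, j) = x[j];
  for (int k = 0; k < n_steps; ++k) {
    double t = t_start + k * dt;
    balloon_rk4(x, t, dt, params[0], params[1], params[2], params[3],
                params[4], alpha, u, nclamp);
    for (int j = 0; j < 4; ++j) {
      if (!std::isfinite(x[j]))
        stop("state became non-finite at t = %f", t + dt);
      out(k + 1, j) = x[j];
    }
  }
  return List::create(_["states"] = out, _["n_clamped"] = nclamp);
}

// Advance every column of S (4 x m states) with its own parameter column of
// P (5 x m: eps, tau_s, tau_f, tau_0, E0) over n_sub RK4 substeps of size dt.
// [[Rcpp::export]]
List propagate_balloon_cols_cpp(NumericMatrix S, NumericMatrix P, double alpha,
                                NumericVector onsets, NumericVector durations,
                                double amplitude, double t_from, int n_sub,
                                double dt) {
  Boxcar u{onsets.begin(), durations.begin(), (int)onsets.size(), amplitude};
  int m = S.ncol();
  NumericMatrix out(4, m);
  int nclamp = 0;
  for (int c = 0; c < m; ++c) {
    double x[4] = {S(0, c), S(1, c), S(2, c), S(3, c)};
    for (int k = 0; k < n_sub; ++k)
      balloon_rk4(x, t_from + k * dt, dt, P(0, c), P(1, c), P(2, c), P(3, c),
                  P(4, c), alpha, u, nclamp);
    for (int j = 0; j < 4; ++j) {
      if (!std::isfinite(x[j]))
        stop("sigma-point state became non-finite during propagation");
      out(j, c) = x[j];
    }
  }
  return List::create(_["states"] = out, _["n_clamped"] = nclamp);
}

// [[Rcpp::export]]
List integrate_dcm_cpp(NumericVector init, NumericVector eps2,
                       NumericVector shared, double alpha, NumericVector conn,
                       NumericVector onsets1, NumericVector durations1,
                       double amplitude1, NumericVector onsets2,
                       NumericVector durations2, double amplitude2,
                       double t_start, int n_steps, double dt) {
  Boxcar u1{onsets1.begin(), durations1.begin(), (int)onsets1.size(),
            amplitude1};
  Boxcar u2{onsets2.begin(), durations2.begin(), (int)onsets2.size(),
            amplitude2};
  NumericMatrix out(n_steps + 1, 10);
  double x[10];
  for (int j = 0; j < 10; ++j) x[j] = init[j];
  int nclamp = 0;
  for (int j = 0; j < 10; ++j) out(0, j) = x[j];
  for (int k = 0; k < n_steps; ++k) {
    double t = t_start + k * dt;
    dcm_rk4(x, t, dt, eps2.begin(), shared[0], shared[1], shared[2], shared[3],
            alpha, conn.begin(), u1, u2, nclamp);
    for (int j = 0; j < 10; ++j) {
      if (!std::isfinite(x[j]) || std::fabs(x[j]) > 1e6)
        stop("DCM trajectory diverged at t = %f (unstable connectivity?)",
             t + dt);
      out(k + 1, j) = x[j];
    }
  }
  return List::create(_["states"] = out, _["n_clamped"] = nclamp);
}

// DCM sigma-point propagator: S is 10 x m (z1, z2, s1..q1, s2..q2); P is
// 6 x m (eps1, eps2, tau_s, tau_f, tau_0, E0); C is 6 x m connectivity
// columns (a11, a12, a21, a22, c1, c2).
// [[Rcpp::export]]
List propagate_dcm_cols_cpp(NumericMatrix S, NumericMatrix P, NumericMatrix C,
                            double alpha, NumericVector onsets1,
                            NumericVector durations1, double amplitude1,
                            NumericVector onsets2, NumericVector durations2,
                            double amplitude2, double t_from, int n_sub,
                            double dt) {
  Boxcar u1{onsets1.begin(), durations1.begin(), (int)onsets1.size(),
            amplitude1};
  Boxcar u2{onsets2.begin(), durations2.begin(), (int)onsets2.size(),
            amplitude2};
  int m = S.ncol();
  NumericMatrix out(10, m);
  int nclamp = 0;
  for (int c = 0; c < m; ++c) {
    double x[10], eps2[2], conn[6];
    for (int j = 0; j < 10; ++j) x[j] = S(j, c);
    eps2[0] = P(0, c);
    eps2[1] = P(1, c);
    for (int j = 0; j < 6; ++j) conn[j] = C(j, c);
    for (int k = 0; k < n_sub; ++k)
      dcm_rk4(x, t_from + k * dt, dt, eps2, P(2, c), P(3, c), P(4, c), P(5, c),
              alpha, conn, u1, u2, nclamp);
    for (int j = 0; j < 10; ++j) {
      if (!std::isfinite(x[j]))
        stop("sigma-point state became non-finite during DCM propagation");
      out(j, c) = x[j];
    }
  }
  return List::create(_["states"] = out, _["n_clamped"] = nclamp);
}
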