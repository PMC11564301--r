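#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dimensionless model constants: delta, a, b, kappa, gamma, lam.
struct Pars {
  double delta, a, b, kappa, gamma, lam;
};

static inline Pars unpack(const NumericVector& p) {
  Pars q;
  q.delta = p[0]; q.a = p[1]; q.b = p[2];
  q.kappa = p[3]; q.gamma = p[4]; q.lam = p[5];
  return q;
}

// D(m) = delta m^a / (1-m)^b, evaluated with m clamped into [0, 1-1e-9]
static inline double Dfun(double m, const Pars& P) {
  if (m <= 0.0) return 0.0;
  if (m > 1.0 - 1e-9) m = 1.0 - 1e-9;
  return P.delta * std::pow(m, P.a) / std::pow(1.0 - m, P.b);
}

static inline double ffun(double s, const Pars& P) {
  if (s <= 0.0) return 0.0;
  return s / (P.kappa + s);
}

// ell(s) = [(1-s) - lam * F(s)] / gamma with F(s) = 1 - s - kappa*log(s)
static inline double ellfun(double s, const Pars& P) {
  if (s < 1e-300) s = 1e-300;
  double F = 1.0 - s - P.kappa * std::log(s);
  return ((1.0 - s) - P.lam * F) / P.gamma;
}

// Base phase-plane field (scaled coordinate): (v[ell(s)-m], (gamma/v) f(s) m D(m)),
// multiplied by `sgn * scale`. sgn = -1 gives the negated field integrated by the
// wave-speed bisection; sgn = +1 with scale = T gives the rescaled boundary-value field.
static inline void deriv(double m, double s, double v, double sgn, double scale,
                         const Pars& P, double& dm, double& ds) {
  double mm = (m > 0.0) ? m : 0.0;
  dm = sgn * scale * v * (ellfun(s, P) - m);
  ds = sgn * scale * (P.gamma / v) * ffun(s, P) * mm * Dfun(mm, P);
}

static inline void rk4(double m, double s, double h, double v, double sgn,
                       double scale, const Pars& P, double& mo, double& so) {
  double k1m, k1s, k2m, k2s, k3m, k3s, k4m, k4s;
  deriv(m, s, v, sgn, scale, P, k1m, k1s);
  deriv(m + 0.5 * h * k1m, s + 0.5 * h * k1s, v, sgn, scale, P, k2m, k2s);
  deriv(m + 0.5 * h * k2m, s + 0.5 * h * k2s, v, sgn, scale, P, k3m, k3s);
  deriv(m + h * k3m, s + h * k3s, v, sgn, scale, P, k4m, k4s);
  mo = m + h / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
  so = s + h / 6.0 * (k1s + 2.0 * k2s + 2.0 * k3s + k4s);
}

// Exit codes: 0 tau cap reached, 1 substrate line, 2 biomass axis,
// 3 M reached 1-1e-9 (step failure per the phase-plane confinement result),
// 4 step budget exhausted, 5 step-size underflow.
// [[Rcpp::export]]
List integrate_orbit_cpp(double v, NumericVector pars, double m0, double s0,
                         double rel_tol, double step_cap, double max_tau,
                         double m_exit_tol, double s_exit_floor,
                         int max_steps, bool store) {
  Pars P = unpack(pars);
  double m = m0, s = s0, tau = 0.0;
  std::vector<double> Ts, Ms, Ss;
  if (store) { Ts.push_back(tau); Ms.push_back(m); Ss.push_back(s); }

  int code = 0;
  double max_m = m;
  double dm0, ds0;
  deriv(m, s, v, -1.0, 1.0, P, dm0, ds0);
  double dscale = std::max(std::fabs(dm0), std::fabs(ds0));
  double h = (dscale > 0.0) ? step_cap / dscale : 1.0;
  int steps = 0;

  for (;;) {
    if (++steps > max_steps) { code = 4; break; }
    double k1m, k1s;
    deriv(m, s, v, -1.0, 1.0, P, k1m, k1s);
    double dmax = std::max(std::fabs(k1m), std::fabs(k1s));
    if (dmax > 0.0 && h * dmax > step_cap) h = step_cap / dmax;
    if (tau + h > max_tau) h = max_tau - tau;
    if (h < 1e-13 * std::max(1.0, tau)) { code = 5; break; }

    double m1, s1, mh, sh, m2, s2;
    rk4(m, s, h, v, -1.0, 1.0, P, m1, s1);
    rk4(m, s, 0.5 * h, v, -1.0, 1.0, P, mh, sh);
    rk4(mh, sh, 0.5 * h, v, -1.0, 1.0, P, m2, s2);
    // component-wise error control: the substrate decays over many orders
    // of magnitude towards s_-inf, so its error must be kept relative
    double sc_m = std::max(std::fabs(m), 1e-4);
    double sc_s = std::max(std::fabs(s), 1e-280);
    double err = std::max(std::fabs(m2 - m1) / sc_m,
                          std::fabs(s2 - s1) / sc_s) / 15.0;
    double tol = rel_tol;
    if (err > tol) {
      double fac = 0.9 * std::pow(tol / err, 0.2);
      h *= std::max(0.1, std::min(fac, 1.0));
      continue;
    }
    // accept, with local extrapolation
    m = m2 + (m2 - m1) / 15.0;
    s = s2 + (s2 - s1) / 15.0;
    tau += h;
    if (!std::isfinite(m) || !std::isfinite(s)) { code = 5; break; }
    if (m > max_m) max_m = m;
    if (store) { Ts.push_back(tau); Ms.push_back(std::max(m, 0.0)); Ss.push_back(s); }
    if (m >= 1.0 - 1e-9) { code = 3; break; }
    if (m <= m_exit_tol) { code = 2; break; }
    if (s <= s_exit_floor) { code = 1; break; }
    if (tau >= max_tau) { code = 0; break; }
    double fac = (err > 0.0) ? 0.9 * std::pow(tol / err, 0.2) : 5.0;
    h *= std::max(0.5, std::min(fac, 5.0));
  }

  List out = List::create(
    _["code"] = code, _["tau_end"] = tau, _["m_end"] = m, _["s_end"] = s,
    _["max_m"] = max_m, _["n_steps"] = steps);
  if (store) {
    out["tau"] = NumericVector(Ts.begin(), Ts.end());
    out["M"] = NumericVector(Ms.begin(), Ms.end());
    out["S"] = NumericVector(Ss.begin(), Ss.end());
  }
  return out;
}

// Integrate the phase-plane field (un-rescaled, forward orientation)
// dM/dtau = v[ell(S)-M], dS/dtau = (gamma/v) f(S) M D(M) from a launch point
// until S reaches s_stop or M falls back to m_stop (the latter event is armed
// only once M has risen above 5*m_stop, so the launch offset does not trigger
// it); used by the boundary-value shooting and to measure the traversal time.
// flag: 0 reached s_stop, 1 M reached cap, 2 M fell to <= 0,
//       3 budget/underflow, 4 M fell back to m_stop before S reached s_stop.
// [[Rcpp::export]]
List integrate_phase_cpp(double v, NumericVector pars, double m0, double s0,
                         double s_stop, double m_stop, double rel_tol,
                         double step_cap, double max_time, int max_steps) {
  Pars P = unpack(pars);
  double m = m0, s = s0, tau = 0.0;
  bool armed = false;
  int flag = 3, steps = 0;
  double dm0, ds0;
  deriv(m, s, v, 1.0, 1.0, P, dm0, ds0);
  double dscale = std::max(std::fabs(dm0), std::fabs(ds0));
  double h = (dscale > 0.0) ? step_cap / dscale : 1.0;
  for (;;) {
    if (++steps > max_steps) { flag = 3; break; }
    double k1m, k1s;
    deriv(m, s, v, 1.0, 1.0, P, k1m, k1s);
    double dmax = std::max(std::fabs(k1m), std::fabs(k1s));
    if (dmax > 0.0 && h * dmax > step_cap) h = step_cap / dmax;
    if (tau + h > max_time) h = max_time - tau;
    if (h < 1e-13 * std::max(1.0, tau)) { flag = 3; break; }
    double m1, s1, mh, sh, m2, s2;
    rk4(m, s, h, v, 1.0, 1.0, P, m1, s1);
    rk4(m, s, 0.5 * h, v, 1.0, 1.0, P, mh, sh);
    rk4(mh, sh, 0.5 * h, v, 1.0, 1.0, P, m2, s2);
    double sc_m = std::max(std::fabs(m), 1e-4);
    double sc_s = std::max(std::fabs(s), 1e-280);
    double err = std::max(std::fabs(m2 - m1) / sc_m,
                          std::fabs(s2 - s1) / sc_s) / 15.0;
    if (err > rel_tol) {
      double fac = 0.9 * std::pow(rel_tol / err, 0.2);
      h *= std::max(0.1, std::min(fac, 1.0));
      continue;
    }
    m = m2 + (m2 - m1) / 15.0;
    s = s2 + (s2 - s1) / 15.0;
    tau += h;
    if (!std::isfinite(m) || !std::isfinite(s)) { flag = 3; break; }
    if (m > 5.0 * m_stop) armed = true;
    if (s >= s_stop) { flag = 0; break; }
    if (m >= 1.0 - 1e-9) { flag = 1; break; }
    if (m <= 0.0) { flag = 2; break; }
    if (armed && m <= m_stop) { flag = 4; break; }
    if (tau >= max_time) { flag = 3; break; }
    double fac = (err > 0.0) ? 0.9 * std::pow(rel_tol / err, 0.2) : 5.0;
    h *= std::max(0.5, std::min(fac, 5.0));
  }
  return List::create(_["flag"] = flag, _["tau_end"] = tau,
                      _["m_end"] = m, _["s_end"] = s,
                      _["armed"] = armed, _["n_steps"] = steps);
}

// Integrate the rescaled heteroclinic boundary-value field on tau in [0,1]:
// dM/dtau = v T [ell(S)-M], dS/dtau = (gamma/v) T f(S) M D(M).
// flag: 0 ok, 1 M reached 1-1e-9, 2 S exceeded 1+1e-8, 3 step failure/budget.
// [[Rcpp::export]]
List integrate_shooting_cpp(double v, double T, NumericVector pars,
                            double m0, double s0, double rel_tol,
                            double step_cap, int max_steps, bool store) {
  Pars P = unpack(pars);
  double m = m0, s = s0, tau = 0.0;
  int flag = 0, steps = 0;
  std::vector<double> Ts, Ms, Ss;
  if (store) { Ts.push_back(tau); Ms.push_back(m); Ss.push_back(s); }
  double dm0, ds0;
  deriv(m, s, v, 1.0, T, P, dm0, ds0);
  double dscale = std::max(std::fabs(dm0), std::fabs(ds0));
  double h = (dscale > 0.0) ? std::min(step_cap / dscale, 0.1) : 0.1;

  while (tau < 1.0) {
    if (++steps > max_steps) { flag = 3; break; }
    double k1m, k1s;
    deriv(m, s, v, 1.0, T, P, k1m, k1s);
    double dmax = std::max(std::fabs(k1m), std::fabs(k1s));
    if (dmax > 0.0 && h * dmax > step_cap) h = step_cap / dmax;
    if (tau + h > 1.0) h = 1.0 - tau;
    if (h < 1e-15) { flag = 3; break; }

    double m1, s1, mh, sh, m2, s2;
    rk4(m, s, h, v, 1.0, T, P, m1, s1);
    rk4(m, s, 0.5 * h, v, 1.0, T, P, mh, sh);
    rk4(mh, sh, 0.5 * h, v, 1.0, T, P, m2, s2);
    double sc_m = std::max(std::fabs(m), 1e-4);
    double sc_s = std::max(std::fabs(s), 1e-280);
    double err = std::max(std::fabs(m2 - m1) / sc_m,
                          std::fabs(s2 - s1) / sc_s) / 15.0;
    double tol = rel_tol;
    if (err > tol) {
      double fac = 0.9 * std::pow(tol / err, 0.2);
      h *= std::max(0.1, std::min(fac, 1.0));
      continue;
    }
    m = m2 + (m2 - m1) / 15.0;
    s = s2 + (s2 - s1) / 15.0;
    tau += h;
    if (!std::isfinite(m) || !std::isfinite(s)) { flag = 3; break; }
    if (store) { Ts.push_back(tau); Ms.push_back(m); Ss.push_back(s); }
    if (m >= 1.0 - 1e-9) { flag = 1; break; }
    if (s > 1.0 + 1e-8) { flag = 2; break; }
    double fac = (err > 0.0) ? 0.9 * std::pow(tol / err, 0.2) : 5.0;
    h *= std::max(0.5, std::min(fac, 5.0));
  }

  List out = List::create(
    _["flag"] = flag, _["tau_end"] = tau, _["m_end"] = m, _["s_end"] = s,
    _["n_steps"] = steps);
  if (store) {
    out["tau"] = NumericVector(Ts.begin(), Ts.end());
    out["M"] = NumericVector(Ms.begin(), Ms.end());
    out["S"] = NumericVector(Ss.begin(), Ss.end());
  }
  return out;
}
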