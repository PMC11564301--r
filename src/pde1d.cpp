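#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One-dimensional two-point flux-approximation finite-volume scheme for the
// coupled biomass/substrate system, advanced with the trapezoidal rule.
// Face diffusivities are arithmetic means of the cell-centred D(M); the
// coupled nonlinear update is solved by Picard (fixed-point) iteration with
// lagged diffusivity and lagged reaction factors; the biomass update is a
// tridiagonal linear solve (Thomas algorithm) per iteration.

static inline double Dfun(double m, double delta, double a, double b) {
  if (m <= 0.0) return 0.0;
  if (m > 1.0 - 1e-9) m = 1.0 - 1e-9;
  return delta * std::pow(m, a) / std::pow(1.0 - m, b);
}

static inline double ffun(double s, double kappa) {
  if (s <= 0.0) return 0.0;
  return s / (kappa + s);
}

static void thomas(const std::vector<double>& a, std::vector<double>& bdiag,
                   const std::vector<double>& c, std::vector<double>& d,
                   std::vector<double>& x) {
  int n = (int)bdiag.size();
  for (int i = 1; i < n; ++i) {
    double w = a[i] / bdiag[i - 1];
    bdiag[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  x[n - 1] = d[n - 1] / bdiag[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = (d[i] - c[i] * x[i + 1]) / bdiag[i];
}

// [[Rcpp::export]]
List run_pde1d_cpp(NumericVector M0, NumericVector S0, double dx, double dt,
                   NumericVector pars, double fp_tol, int fp_maxiter,
                   bool reactions, int nsteps, IntegerVector snap_steps) {
  const double delta = pars[0], a = pars[1], b = pars[2];
  const double kappa = pars[3], gamma = pars[4], lam = pars[5];
  const int n = M0.size();
  std::vector<double> M(M0.begin(), M0.end()), S(S0.begin(), S0.end());
  const double r = dt / (2.0 * dx * dx);

  const int nsnap = snap_steps.size();
  NumericMatrix Msnap(nsnap, n), Ssnap(nsnap, n);
  int isnap = 0;
  long total_iters = 0;
  int max_iters = 0;

  std::vector<double> Dc(n), Dface(n + 1, 0.0), expl(n), rhs(n);
  std::vector<double> sub(n), diag(n), sup(n), d(n), Mk(n), Sk(n), Mnew(n), Snew(n);

  // record step 0 snapshots if requested
  while (isnap < nsnap && snap_steps[isnap] == 0) {
    for (int i = 0; i < n; ++i) { Msnap(isnap, i) = M[i]; Ssnap(isnap, i) = S[i]; }
    ++isnap;
  }

  for (int step = 1; step <= nsteps; ++step) {
    // explicit half from the old time level
    for (int i = 0; i < n; ++i) Dc[i] = Dfun(M[i], delta, a, b);
    for (int i = 1; i < n; ++i) Dface[i] = 0.5 * (Dc[i - 1] + Dc[i]);
    for (int i = 0; i < n; ++i) {
      double flux = 0.0;
      if (i < n - 1) flux += Dface[i + 1] * (M[i + 1] - M[i]);
      if (i > 0) flux -= Dface[i] * (M[i] - M[i - 1]);
      double react = reactions ? (ffun(S[i], kappa) - lam) * M[i] : 0.0;
      expl[i] = flux / (dx * dx) + react;
      rhs[i] = M[i] + 0.5 * dt * expl[i];
    }

    Mk = M; Sk = S;
    int it = 0;
    for (;;) {
      if (++it > fp_maxiter)
        stop("fixed-point iteration failed to converge at step %d; reduce dt", step);
      for (int i = 0; i < n; ++i) Dc[i] = Dfun(Mk[i], delta, a, b);
      for (int i = 1; i < n; ++i) Dface[i] = 0.5 * (Dc[i - 1] + Dc[i]);
      for (int i = 0; i < n; ++i) {
        double Dw = (i > 0) ? Dface[i] : 0.0;
        double De = (i < n - 1) ? Dface[i + 1] : 0.0;
        double rk = reactions ? (ffun(Sk[i], kappa) - lam) : 0.0;
        sub[i] = -r * Dw;
        sup[i] = -r * De;
        diag[i] = 1.0 + r * (Dw + De) - 0.5 * dt * rk;
        d[i] = rhs[i];
      }
      {
        std::vector<double> bcopy(diag), dcopy(d);
        thomas(sub, bcopy, sup, dcopy, Mnew);
      }
      double inc = 0.0;
      if (reactions) {
        for (int i = 0; i < n; ++i) {
          double mn = std::max(Mnew[i], 0.0), mo = std::max(M[i], 0.0);
          Snew[i] = S[i] - 0.5 * dt * gamma *
            (ffun(Sk[i], kappa) * mn + ffun(S[i], kappa) * mo);
          if (Snew[i] < 0.0) Snew[i] = 0.0;
        }
      } else {
        Snew = S;
      }
      for (int i = 0; i < n; ++i) {
        inc = std::max(inc, std::fabs(Mnew[i] - Mk[i]));
        inc = std::max(inc, std::fabs(Snew[i] - Sk[i]));
      }
      Mk = Mnew; Sk = Snew;
      if (inc < fp_tol) break;
    }
    total_iters += it;
    if (it > max_iters) max_iters = it;
    M = Mk; S = Sk;
    for (int i = 0; i < n; ++i) {
      if (M[i] > 1.0 - 1e-6)
        stop("biomass density reached the singular value at step %d; refine the grid/time step", step);
    }
    while (isnap < nsnap && snap_steps[isnap] == step) {
      for (int i = 0; i < n; ++i) { Msnap(isnap, i) = M[i]; Ssnap(isnap, i) = S[i]; }
      ++isnap;
    }
  }

  return List::create(
    _["M"] = Msnap, _["S"] = Ssnap,
    _["M_final"] = NumericVector(M.begin(), M.end()),
    _["S_final"] = NumericVector(S.begin(), S.end()),
    _["total_fp_iters"] = (double)total_iters, _["max_fp_iters"] = max_iters);
}
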