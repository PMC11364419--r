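#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shifted Hill regulation factor: lam + (1 - lam) / (1 + (x/x0)^n).
static inline double hs(double x, double x0, double n, double lam) {
  double r = std::pow(x / x0, n);
  return lam + (1.0 - lam) / (1.0 + r);
}

struct Circuit {
  int N, E;
  const double *g, *k;
  const int *src, *tgt;        // 0-based node indices
  const double *n, *lam, *x0;  // per-edge Hill parameters

  // dx/dt_i = g_i * prod_{edges j->i} Hs(x_j) - k_i * x_i
  void deriv(const double* x, double* f) const {
    for (int i = 0; i < N; ++i) f[i] = g[i];
    for (int e = 0; e < E; ++e)
      f[tgt[e]] *= hs(x[src[e]], x0[e], n[e], lam[e]);
    for (int i = 0; i < N; ++i) f[i] -= k[i] * x[i];
  }

  // scale-free residual max_i |f_i| / (1 + |x_i|)
  double residual(const double* x, double* f) const {
    deriv(x, f);
    double r = 0.0;
    for (int i = 0; i < N; ++i) {
      double ri = std::fabs(f[i]) / (1.0 + std::fabs(x[i]));
      if (ri > r) r = ri;
    }
    return r;
  }
};

// Cash-Karp RK45 coefficients
static const double B21 = 0.2;
static const double B31 = 3.0 / 40.0, B32 = 9.0 / 40.0;
static const double B41 = 0.3, B42 = -0.9, B43 = 1.2;
static const double B51 = -11.0 / 54.0, B52 = 2.5, B53 = -70.0 / 27.0,
                    B54 = 35.0 / 27.0;
static const double B61 = 1631.0 / 55296.0, B62 = 175.0 / 512.0,
                    B63 = 575.0 / 13824.0, B64 = 44275.0 / 110592.0,
                    B65 = 253.0 / 4096.0;
static const double C1 = 37.0 / 378.0, C3 = 250.0 / 621.0, C4 = 125.0 / 594.0,
                    C6 = 512.0 / 1771.0;
static const double D1 = C1 - 2825.0 / 27648.0, D3 = C3 - 18575.0 / 48384.0,
                    D4 = C4 - 13525.0 / 55296.0, D5 = -277.0 / 14336.0,
                    D6 = C6 - 0.25;

// One adaptive Cash-Karp step starting from trial size h_try.
// On success x is advanced by h_taken and h_next proposes the next size.
// neg is set if the accepted state has a negative component.
static bool ck_step(const Circuit& c, std::vector<double>& x, double h_try,
                    double& h_taken, double& h_next, double rtol, double atol,
                    double hmax, bool& neg) {
  double h = h_try;
  int N = c.N;
  std::vector<double> k1(N), k2(N), k3(N), k4(N), k5(N), k6(N), xt(N),
      xout(N);
  c.deriv(x.data(), k1.data());
  for (int iter = 0; iter < 60; ++iter) {
    for (int i = 0; i < N; ++i) xt[i] = x[i] + h * B21 * k1[i];
    c.deriv(xt.data(), k2.data());
    for (int i = 0; i < N; ++i)
      xt[i] = x[i] + h * (B31 * k1[i] + B32 * k2[i]);
    c.deriv(xt.data(), k3.data());
    for (int i = 0; i < N; ++i)
      xt[i] = x[i] + h * (B41 * k1[i] + B42 * k2[i] + B43 * k3[i]);
    c.deriv(xt.data(), k4.data());
    for (int i = 0; i < N; ++i)
      xt[i] = x[i] + h * (B51 * k1[i] + B52 * k2[i] + B53 * k3[i] + B54 * k4[i]);
    c.deriv(xt.data(), k5.data());
    for (int i = 0; i < N; ++i)
      xt[i] = x[i] + h * (B61 * k1[i] + B62 * k2[i] + B63 * k3[i] +
                          B64 * k4[i] + B65 * k5[i]);
    c.deriv(xt.data(), k6.data());
    double errmax = 0.0;
    for (int i = 0; i < N; ++i) {
      xout[i] = x[i] + h * (C1 * k1[i] + C3 * k3[i] + C4 * k4[i] + C6 * k6[i]);
      double err = h * (D1 * k1[i] + D3 * k3[i] + D4 * k4[i] + D5 * k5[i] +
                        D6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xout[i]));
      errmax = std::max(errmax, std::fabs(err) / sc);
    }
    if (errmax <= 1.0 || h <= 1e-12) {
      x = xout;
      for (int i = 0; i < N; ++i)
        if (x[i] < 0.0) {
          // production is positive at the boundary; tiny overshoots are
          // numerical and clamped, large ones are integration failures
          if (x[i] < -1e-6) neg = true;
          x[i] = 0.0;
        }
      h_taken = h;
      double fac = (errmax > 0.0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      h_next = std::min(hmax, h * std::min(5.0, std::max(0.2, fac)));
      return true;
    }
    h = std::max(1e-12, h * std::max(0.1, 0.9 * std::pow(errmax, -0.25)));
  }
  return false;
}

// Forward-difference numerical Jacobian of the rate function at x.
static void numjac(const Circuit& c, const std::vector<double>& x,
                   std::vector<double>& J) {
  int N = c.N;
  std::vector<double> f0(N), f1(N), xp(x);
  c.deriv(x.data(), f0.data());
  for (int j = 0; j < N; ++j) {
    double h = 1e-7 * (1.0 + std::fabs(x[j]));
    xp[j] = x[j] + h;
    c.deriv(xp.data(), f1.data());
    for (int i = 0; i < N; ++i) J[i * N + j] = (f1[i] - f0[i]) / h;
    xp[j] = x[j];
  }
}

// Solve J d = b in place by Gaussian elimination with partial pivoting.
static bool lin_solve(std::vector<double> J, std::vector<double> b,
                      std::vector<double>& d, int N) {
  for (int col = 0; col < N; ++col) {
    int piv = col;
    for (int r = col + 1; r < N; ++r)
      if (std::fabs(J[r * N + col]) > std::fabs(J[piv * N + col])) piv = r;
    if (std::fabs(J[piv * N + col]) < 1e-14) return false;
    if (piv != col) {
      for (int cc = 0; cc < N; ++cc) std::swap(J[col * N + cc], J[piv * N + cc]);
      std::swap(b[col], b[piv]);
    }
    for (int r = col + 1; r < N; ++r) {
      double m = J[r * N + col] / J[col * N + col];
      for (int cc = col; cc < N; ++cc) J[r * N + cc] -= m * J[col * N + cc];
      b[r] -= m * b[col];
    }
  }
  d.assign(N, 0.0);
  for (int r = N - 1; r >= 0; --r) {
    double s = b[r];
    for (int cc = r + 1; cc < N; ++cc) s -= J[r * N + cc] * d[cc];
    d[r] = s / J[r * N + r];
  }
  return true;
}

// Newton refinement of a settled endpoint to a machine-precision fixed
// point. Rejects steps that leave the positive orthant or diverge.
static bool newton_polish(const Circuit& c, std::vector<double>& x,
                          double conv_tol, int maxit = 25) {
  int N = c.N;
  std::vector<double> f(N), J(N * N), d(N), xn(N);
  for (int it = 0; it < maxit; ++it) {
    double r = c.residual(x.data(), f.data());
    if (r < conv_tol) return true;
    numjac(c, x, J);
    std::vector<double> rhs(N);
    for (int i = 0; i < N; ++i) rhs[i] = -f[i];
    if (!lin_solve(J, rhs, d, N)) return false;
    double step = 1.0;
    bool ok = false;
    for (int half = 0; half < 8; ++half) {
      double rn = 0.0;
      bool neg = false;
      for (int i = 0; i < N; ++i) {
        xn[i] = x[i] + step * d[i];
        if (xn[i] < 0.0) neg = true;
      }
      if (!neg) {
        rn = c.residual(xn.data(), f.data());
        if (rn < r) { ok = true; break; }
      }
      step *= 0.5;
    }
    if (!ok) return false;
    x = xn;
  }
  std::vector<double> ftmp(N);
  return c.residual(x.data(), ftmp.data()) < conv_tol;
}

// Integrate one trajectory until the residual stays below settle_tol at
// two consecutive checkpoints spaced check_dt apart (or t_max is hit),
// then Newton-polish the endpoint to conv_tol.
static void run_traj(const Circuit& c, std::vector<double>& x, double t_max,
                     double check_dt, double settle_tol, double conv_tol,
                     double rtol, double atol, double& resid_out,
                     bool& converged, bool& neg) {
  int N = c.N;
  std::vector<double> f(N);
  double t = 0.0, h = 1e-3;
  neg = false;
  int ok_streak = 0;
  bool settled = false;
  double next_check = check_dt;
  while (t < t_max) {
    double h_try = std::min(h, next_check - t);
    double h_taken = 0.0, h_next = h;
    if (!ck_step(c, x, h_try, h_taken, h_next, rtol, atol, check_dt, neg))
      break;
    t += h_taken;
    h = h_next;
    if (t >= next_check - 1e-12) {
      next_check += check_dt;
      double r = c.residual(x.data(), f.data());
      if (r < settle_tol) {
        if (++ok_streak >= 2) { settled = true; break; }
      } else {
        ok_streak = 0;
      }
    }
  }
  if (settled || c.residual(x.data(), f.data()) < settle_tol) {
    std::vector<double> xp(x);
    if (newton_polish(c, xp, conv_tol)) x = xp;
  }
  resid_out = c.residual(x.data(), f.data());
  converged = (resid_out < conv_tol);
}

// [[Rcpp::export]]
List cpp_find_endpoints(NumericMatrix inits, NumericVector g, NumericVector k,
                        IntegerVector esrc, IntegerVector etgt,
                        NumericVector en, NumericVector elam,
                        NumericVector ex0, double t_max, double check_dt,
                        double settle_tol, double conv_tol, double rtol,
                        double atol) {
  int n_init = inits.nrow(), N = inits.ncol();
  if (g.size() != N || k.size() != N)
    stop("node parameter length does not match state dimension");
  int E = esrc.size();
  if (etgt.size() != E || en.size() != E || elam.size() != E ||
      ex0.size() != E)
    stop("edge parameter vectors have inconsistent lengths");
  Circuit c;
  c.N = N;
  c.E = E;
  c.g = REAL(g);
  c.k = REAL(k);
  c.src = INTEGER(esrc);
  c.tgt = INTEGER(etgt);
  c.n = REAL(en);
  c.lam = REAL(elam);
  c.x0 = REAL(ex0);

  NumericMatrix ends(n_init, N);
  NumericVector resid(n_init);
  LogicalVector conv(n_init), negative(n_init);
  std::vector<double> x(N);
  for (int s = 0; s < n_init; ++s) {
    for (int i = 0; i < N; ++i) x[i] = inits(s, i);
    double r = NA_REAL;
    bool cv = false, ng = false;
    run_traj(c, x, t_max, check_dt, settle_tol, conv_tol, rtol, atol, r, cv, ng);
    for (int i = 0; i < N; ++i) ends(s, i) = x[i];
    resid[s] = r;
    conv[s] = cv;
    negative[s] = ng;
  }
  return List::create(_["x"] = ends, _["residual"] = resid,
                      _["converged"] = conv, _["negative"] = negative);
}

// [[Rcpp::export]]
NumericVector cpp_dxdt(NumericVector x, NumericVector g, NumericVector k,
                       IntegerVector esrc, IntegerVector etgt, NumericVector en,
                       NumericVector elam, NumericVector ex0) {
  int N = x.size();
  Circuit c;
  c.N = N;
  c.E = esrc.size();
  c.g = REAL(g);
  c.k = REAL(k);
  c.src = INTEGER(esrc);
  c.tgt = INTEGER(etgt);
  c.n = REAL(en);
  c.lam = REAL(elam);
  c.x0 = REAL(ex0);
  NumericVector f(N);
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> fv(N);
  c.deriv(xv.data(), fv.data());
  for (int i = 0; i < N; ++i) f[i] = fv[i];
  return f;
}
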