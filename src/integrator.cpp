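#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Balloon model state order: (f, s, v, q).
// Parameter vector theta (Table-1 convention, reciprocals for alpha and tau):
//   theta[0] = alpha_inv (1/alpha), theta[1] = epsilon, theta[2] = kappa_s,
//   theta[3] = kappa_f,  theta[4] = tau_inv,  theta[5] = E0, theta[6] = V0.

static inline void rhs(const double *x, double u, const double *th, double *dx) {
  const double f = x[0], s = x[1], v = x[2], q = x[3];
  const double ainv = th[0], eps = th[1], ks = th[2], kf = th[3],
               tinv = th[4], E0 = th[5];
  dx[0] = s;
  dx[1] = eps * u - ks * s - kf * (f - 1.0);
  dx[2] = tinv * (f - std::pow(v, ainv));
  dx[3] = tinv * (f * (1.0 - std::pow(1.0 - E0, 1.0 / f)) / E0 -
                  std::pow(v, ainv - 1.0) * q);
}

static inline double observe(const double *x, const double *th) {
  const double v = x[2], q = x[3];
  const double E0 = th[5], V0 = th[6];
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  return V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
}

static inline bool bad_state(const double *x) {
  for (int i = 0; i < 4; ++i)
    if (!std::isfinite(x[i])) return true;
  // f, v, q must stay strictly positive for the fractional powers to exist
  return (x[0] <= 0.0 || x[2] <= 0.0 || x[3] <= 0.0);
}

// [[Rcpp::export]]
NumericVector balloon_rhs_cpp(NumericVector state, double u, NumericVector theta) {
  double dx[4];
  rhs(REAL(state), u, REAL(theta), dx);
  return NumericVector(dx, dx + 4);
}

// [[Rcpp::export]]
NumericVector balloon_observe_cpp(NumericMatrix states, NumericVector theta) {
  const int n = states.nrow();
  NumericVector y(n);
  double x[4];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 4; ++j) x[j] = states(i, j);
    y[i] = observe(x, REAL(theta));
  }
  return y;
}

// one classical RK4 step of size h at constant input u
static inline void rk4_step(double *x, double u, const double *th, double h) {
  double k1[4], k2[4], k3[4], k4[4], xt[4];
  rhs(x, u, th, k1);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + 0.5 * h * k1[i];
  rhs(xt, u, th, k2);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + 0.5 * h * k2[i];
  rhs(xt, u, th, k3);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + h * k3[i];
  rhs(xt, u, th, k4);
  for (int i = 0; i < 4; ++i)
    x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                    a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// one DOPRI5 trial step; returns scaled error estimate, fills xnew
static double dopri_step(const double *x, double u, const double *th, double h,
                         double rtol, double atol, double *xnew) {
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], xt[4];
  rhs(x, u, th, k1);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + h * a21 * k1[i];
  rhs(xt, u, th, k2);
  for (int i = 0; i < 4; ++i) xt[i] = x[i] + h * (a31 * k1[i] + a32 * k2[i]);
  rhs(xt, u, th, k3);
  for (int i = 0; i < 4; ++i)
    xt[i] = x[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  rhs(xt, u, th, k4);
  for (int i = 0; i < 4; ++i)
    xt[i] = x[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
  rhs(xt, u, th, k5);
  for (int i = 0; i < 4; ++i)
    xt[i] = x[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] +
                        a65 * k5[i]);
  rhs(xt, u, th, k6);
  for (int i = 0; i < 4; ++i)
    xnew[i] = x[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
  rhs(xnew, u, th, k7);
  double err = 0.0;
  for (int i = 0; i < 4; ++i) {
    const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                           e6 * k6[i] + e7 * k7[i]);
    const double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xnew[i]));
    const double r = ei / sc;
    err += r * r;
  }
  return std::sqrt(err / 4.0);
}

// integrate one zero-order-hold interval [0, te] at constant u, adaptively
static bool dopri_interval(double *x, double u, const double *th, double te,
                           double rtol, double atol, double *hguess) {
  double t = 0.0, h = std::min(*hguess, te);
  int iter = 0;
  while (t < te) {
    if (h > te - t) h = te - t;
    double xnew[4];
    const double err = dopri_step(x, u, th, h, rtol, atol, xnew);
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) x[i] = xnew[i];
      if (bad_state(x)) return false;
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
    }
    if (h < 1e-12 || ++iter > 100000) return false;
  }
  *hguess = h;
  return true;
}

// Integrate the Balloon model over a sampled stimulus held piecewise constant
// (u[k] on [k*te, (k+1)*te)). Returns states and BOLD on the stimulus grid,
// with states[0, ] = init.
// [[Rcpp::export]]
List balloon_integrate_cpp(NumericVector u, double te, NumericVector theta,
                           NumericVector init, std::string method,
                           double rtol, double atol, int substeps) {
  const int n = u.size();
  const double *th = REAL(theta);
  NumericMatrix states(n, 4);
  NumericVector y(n);
  double x[4] = {init[0], init[1], init[2], init[3]};
  if (bad_state(x)) stop("initial state violates positivity/finiteness");
  for (int j = 0; j < 4; ++j) states(0, j) = x[j];
  y[0] = observe(x, th);
  const bool fixed = (method == "rk4");
  double hguess = te;
  for (int k = 1; k < n; ++k) {
    const double uk = u[k - 1];
    if (fixed) {
      const double h = te / substeps;
      for (int m = 0; m < substeps; ++m) rk4_step(x, uk, th, h);
      if (bad_state(x))
        stop("state left the positive domain near t = %.4f s", k * te);
    } else {
      if (!dopri_interval(x, uk, th, te, rtol, atol, &hguess))
        stop("integration failed (positivity or step-size fault) near t = %.4f s",
             k * te);
    }
    for (int j = 0; j < 4; ++j) states(k, j) = x[j];
    y[k] = observe(x, th);
  }
  return List::create(_["states"] = states, _["y"] = y);
}
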