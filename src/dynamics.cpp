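// Planar two-segment moth body: equations of motion and a batch
// Dormand-Prince 5(4) integrator for 20 ms constant-control strokes.
//
// State layout (8): x, y, theta, phi, xdot, ydot, thetadot, phidot
// Controls (3):     F, alpha, tau
// Params (14):      m1, m2, L1, L2, I1, I2, K, C, beta0, cd1, cd2, g, rF,
//                   drag_law (0 = linear -cd*v, 1 = quadratic -cd*|v|*v)
//
// Generalized coordinates q = (x, y, theta, phi), joint at (x, y).
// Head-thorax centroid at q + (L1/2)(cos th, sin th); abdomen centroid at
// q - (L2/2)(cos ph, sin ph). Lagrange's equations give M(q) qdd = Q - h
// with a symmetric 4x4 mass matrix and centripetal terms h confined to the
// translational rows; Q collects thrust, gravity, drag, joint spring/damper
// and the abdominal control torque (with its reaction).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void moth_accel(const double* s, const double* u,
                              const double* p, double* ds) {
  const double m1 = p[0], m2 = p[1], L1 = p[2], L2 = p[3];
  const double I1 = p[4], I2 = p[5], K = p[6], C = p[7], beta0 = p[8];
  const double cd1 = p[9], cd2 = p[10], g = p[11], rF = p[12];
  const bool quad_drag = p[13] > 0.5;

  const double th = s[2], ph = s[3];
  const double xd = s[4], yd = s[5], thd = s[6], phd = s[7];
  const double F = u[0], alpha = u[1], tau = u[2];

  const double a = 0.5 * L1, b = 0.5 * L2;
  const double sth = std::sin(th), cth = std::cos(th);
  const double sph = std::sin(ph), cph = std::cos(ph);

  // centroid velocities
  const double v1x = xd - a * sth * thd, v1y = yd + a * cth * thd;
  const double v2x = xd + b * sph * phd, v2y = yd - b * cph * phd;

  // drag forces at the centroids
  double d1x = -cd1 * v1x, d1y = -cd1 * v1y;
  double d2x = -cd2 * v2x, d2y = -cd2 * v2y;
  if (quad_drag) {
    const double sp1 = std::hypot(v1x, v1y), sp2 = std::hypot(v2x, v2y);
    d1x *= sp1; d1y *= sp1;
    d2x *= sp2; d2y *= sp2;
  }

  // joint spring/damper torque (positive on the head-thorax segment)
  const double tj = K * ((ph - th) - beta0) + C * (phd - thd);

  const double fdir = th + alpha;
  const double Fx = F * std::cos(fdir), Fy = F * std::sin(fdir);

  arma::mat::fixed<4, 4> M;
  const double mt = m1 + m2;
  M.zeros();
  M(0, 0) = mt;            M(1, 1) = mt;
  M(0, 2) = -m1 * a * sth; M(2, 0) = M(0, 2);
  M(0, 3) =  m2 * b * sph; M(3, 0) = M(0, 3);
  M(1, 2) =  m1 * a * cth; M(2, 1) = M(1, 2);
  M(1, 3) = -m2 * b * cph; M(3, 1) = M(1, 3);
  M(2, 2) = m1 * a * a + I1;
  M(3, 3) = m2 * b * b + I2;

  arma::vec::fixed<4> rhs;
  // generalized forces minus centripetal terms
  rhs(0) = Fx + d1x + d2x
         - (-m1 * a * cth * thd * thd + m2 * b * cph * phd * phd);
  rhs(1) = Fy + d1y + d2y - mt * g
         - (-m1 * a * sth * thd * thd + m2 * b * sph * phd * phd);
  rhs(2) = F * rF * std::sin(alpha) + tj - tau
         - m1 * g * a * cth
         + a * (-d1x * sth + d1y * cth);
  rhs(3) = tau - tj + m2 * g * b * cph
         + b * (d2x * sph - d2y * cph);

  arma::vec::fixed<4> qdd = arma::solve(M, rhs, arma::solve_opts::fast);

  ds[0] = xd; ds[1] = yd; ds[2] = thd; ds[3] = phd;
  ds[4] = qdd(0); ds[5] = qdd(1); ds[6] = qdd(2); ds[7] = qdd(3);
}

//' @noRd
// [[Rcpp::export(name = ".moth_rhs_cpp")]]
NumericVector moth_rhs_cpp(NumericVector state, NumericVector controls,
                           NumericVector params) {
  if (state.size() != 8 || controls.size() != 3 || params.size() != 14)
    stop("bad argument lengths for the dynamics right-hand side");
  NumericVector ds(8);
  moth_accel(state.begin(), controls.begin(), params.begin(), ds.begin());
  return ds;
}

// Dormand-Prince 5(4) coefficients (RK45, FSAL)
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                    c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Integrate one segment with constant controls; returns false on step-size
// underflow. y is updated in place.
static bool dp45_segment(double* y, const double* u, const double* p,
                         double duration, double rtol, double atol) {
  const int n = 8;
  double t = 0.0;
  double h = duration / 50.0;
  const double hmin = duration * 1e-14;
  double k1[8], k2[8], k3[8], k4[8], k5[8], k6[8], k7[8], yt[8], y5[8];

  moth_accel(y, u, p, k1);
  int guard = 0;
  while (t < duration) {
    if (++guard > 1000000) return false;
    if (t + h > duration) h = duration - t;

    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    moth_accel(yt, u, p, k2);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    moth_accel(yt, u, p, k3);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    moth_accel(yt, u, p, k4);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    moth_accel(yt, u, p, k5);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    moth_accel(yt, u, p, k6);
    for (int i = 0; i < n; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    moth_accel(y5, u, p, k7);

    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      const double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                                    e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(y5[i]));
      const double d = (y5[i] - y4) / sc;
      err += d * d;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) return false;

    if (err <= 1.0) {  // accept (FSAL: k7 becomes next k1)
      t += h;
      for (int i = 0; i < n; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }
    }
    double fac = 0.9 * std::pow(err > 1e-300 ? err : 1e-300, -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < hmin && t < duration) return false;
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".integrate_segments_cpp")]]
List integrate_segments_cpp(NumericMatrix states0, NumericMatrix controls,
                            NumericVector params, double duration,
                            double rtol, double atol) {
  const int n = states0.nrow();
  if (states0.ncol() != 8 || controls.ncol() != 3 || controls.nrow() != n)
    stop("states0 must be n x 8 and controls n x 3");
  if (params.size() != 14) stop("params must have length 14");
  NumericMatrix out(n, 8);
  LogicalVector ok(n);
  double y[8], u[3];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 8; ++j) y[j] = states0(i, j);
    for (int j = 0; j < 3; ++j) u[j] = controls(i, j);
    ok[i] = dp45_segment(y, u, params.begin(), duration, rtol, atol);
    for (int j = 0; j < 8; ++j) out(i, j) = y[j];
  }
  return List::create(_["final"] = out, _["ok"] = ok);
}
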