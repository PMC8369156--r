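#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gradient-descent MARG correction shared by the single-step and the
// sequential entry points. Quaternions are scalar-first (w,x,y,z); q is the
// sensor attitude in the earth frame (v_earth = R(q) v_sensor). Gravity
// reference is (0,0,1); the magnetic reference b = (bx,0,bz) is rebuilt each
// sample from the measured field rotated into the earth frame with its
// horizontal component collapsed onto x (magnetic-distortion compensation).
//
// Writes the unnormalized objective gradient into grad[4]; returns the
// gradient norm. degenerate is set when accel or mag has zero norm.
static double marg_gradient(const double q[4], const double a_in[3],
                            const double m_in[3], double grad[4],
                            bool &degenerate) {
  const double an = std::sqrt(a_in[0] * a_in[0] + a_in[1] * a_in[1] +
                              a_in[2] * a_in[2]);
  const double mn = std::sqrt(m_in[0] * m_in[0] + m_in[1] * m_in[1] +
                              m_in[2] * m_in[2]);
  degenerate = (an <= 0.0) || (mn <= 0.0) || !std::isfinite(an) ||
               !std::isfinite(mn);
  if (degenerate) {
    grad[0] = grad[1] = grad[2] = grad[3] = 0.0;
    return 0.0;
  }
  const double ax = a_in[0] / an, ay = a_in[1] / an, az = a_in[2] / an;
  const double mx = m_in[0] / mn, my = m_in[1] / mn, mz = m_in[2] / mn;
  const double q1 = q[0], q2 = q[1], q3 = q[2], q4 = q[3];

  // h = q (x) (0,m) (x) q*  (measured field in the earth frame)
  const double hx =
      mx * (1 - 2 * (q3 * q3 + q4 * q4)) + my * 2 * (q2 * q3 - q1 * q4) +
      mz * 2 * (q2 * q4 + q1 * q3);
  const double hy =
      mx * 2 * (q2 * q3 + q1 * q4) + my * (1 - 2 * (q2 * q2 + q4 * q4)) +
      mz * 2 * (q3 * q4 - q1 * q2);
  const double hz =
      mx * 2 * (q2 * q4 - q1 * q3) + my * 2 * (q3 * q4 + q1 * q2) +
      mz * (1 - 2 * (q2 * q2 + q3 * q3));
  const double bx = std::sqrt(hx * hx + hy * hy);
  const double bz = hz;

  const double f1 = 2 * (q2 * q4 - q1 * q3) - ax;
  const double f2 = 2 * (q1 * q2 + q3 * q4) - ay;
  const double f3 = 2 * (0.5 - q2 * q2 - q3 * q3) - az;
  const double f4 =
      2 * bx * (0.5 - q3 * q3 - q4 * q4) + 2 * bz * (q2 * q4 - q1 * q3) - mx;
  const double f5 =
      2 * bx * (q2 * q3 - q1 * q4) + 2 * bz * (q1 * q2 + q3 * q4) - my;
  const double f6 =
      2 * bx * (q1 * q3 + q2 * q4) + 2 * bz * (0.5 - q2 * q2 - q3 * q3) - mz;

  grad[0] = -2 * q3 * f1 + 2 * q2 * f2 - 2 * bz * q3 * f4 +
            (-2 * bx * q4 + 2 * bz * q2) * f5 + 2 * bx * q3 * f6;
  grad[1] = 2 * q4 * f1 + 2 * q1 * f2 - 4 * q2 * f3 + 2 * bz * q4 * f4 +
            (2 * bx * q3 + 2 * bz * q1) * f5 +
            (2 * bx * q4 - 4 * bz * q2) * f6;
  grad[2] = -2 * q1 * f1 + 2 * q4 * f2 - 4 * q3 * f3 +
            (-4 * bx * q3 - 2 * bz * q1) * f4 +
            (2 * bx * q2 + 2 * bz * q4) * f5 +
            (2 * bx * q1 - 4 * bz * q3) * f6;
  grad[3] = 2 * q2 * f1 + 2 * q3 * f2 +
            (-4 * bx * q4 + 2 * bz * q2) * f4 +
            (-2 * bx * q1 + 2 * bz * q3) * f5 + 2 * bx * q2 * f6;

  return std::sqrt(grad[0] * grad[0] + grad[1] * grad[1] +
                   grad[2] * grad[2] + grad[3] * grad[3]);
}

static void mw_step(double q[4], const double g[3], const double a[3],
                    const double m[3], double beta, double dt,
                    bool &degenerate) {
  double grad[4];
  const double gnorm = marg_gradient(q, a, m, grad, degenerate);

  // gyroscope quaternion rate: 0.5 * q (x) (0, omega)
  const double q1 = q[0], q2 = q[1], q3 = q[2], q4 = q[3];
  double qd1 = 0.5 * (-q2 * g[0] - q3 * g[1] - q4 * g[2]);
  double qd2 = 0.5 * (q1 * g[0] + q3 * g[2] - q4 * g[1]);
  double qd3 = 0.5 * (q1 * g[1] - q2 * g[2] + q4 * g[0]);
  double qd4 = 0.5 * (q1 * g[2] + q2 * g[1] - q3 * g[0]);

  if (gnorm > 1e-12) { // correction normalized to unit magnitude, scaled by beta
    qd1 -= beta * grad[0] / gnorm;
    qd2 -= beta * grad[1] / gnorm;
    qd3 -= beta * grad[2] / gnorm;
    qd4 -= beta * grad[3] / gnorm;
  }

  q[0] += qd1 * dt;
  q[1] += qd2 * dt;
  q[2] += qd3 * dt;
  q[3] += qd4 * dt;
  const double n =
      std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  q[0] /= n; q[1] /= n; q[2] /= n; q[3] /= n;
}

// [[Rcpp::export]]
List mw_filter_cpp(NumericMatrix gyro, NumericMatrix accel, NumericMatrix mag,
                   NumericVector beta, NumericVector dt, NumericVector q0) {
  const int n = gyro.nrow();
  NumericMatrix Q(n, 4);
  LogicalVector degenerate(n);
  double q[4] = {q0[0], q0[1], q0[2], q0[3]};
  Q(0, 0) = q[0]; Q(0, 1) = q[1]; Q(0, 2) = q[2]; Q(0, 3) = q[3];
  for (int k = 1; k < n; ++k) {
    const double g[3] = {gyro(k, 0), gyro(k, 1), gyro(k, 2)};
    const double a[3] = {accel(k, 0), accel(k, 1), accel(k, 2)};
    const double m[3] = {mag(k, 0), mag(k, 1), mag(k, 2)};
    bool deg = false;
    mw_step(q, g, a, m, beta[k], dt[k], deg);
    degenerate[k] = deg;
    Q(k, 0) = q[0]; Q(k, 1) = q[1]; Q(k, 2) = q[2]; Q(k, 3) = q[3];
  }
  return List::create(_["q"] = Q, _["degenerate"] = degenerate);
}

// [[Rcpp::export]]
List mw_gradient_cpp(NumericVector q, NumericVector accel, NumericVector mag) {
  double qq[4] = {q[0], q[1], q[2], q[3]};
  const double a[3] = {accel[0], accel[1], accel[2]};
  const double m[3] = {mag[0], mag[1], mag[2]};
  double grad[4];
  bool degenerate = false;
  const double gnorm = marg_gradient(qq, a, m, grad, degenerate);
  NumericVector inc(4);
  bool converged = false;
  if (!degenerate && gnorm > 1e-12) {
    for (int i = 0; i < 4; ++i) inc[i] = grad[i] / gnorm;
  } else {
    converged = !degenerate; // zero gradient at a stationary point
  }
  return List::create(_["increment"] = inc, _["degenerate"] = degenerate,
                      _["converged"] = converged,
                      _["gradient_norm"] = gnorm);
}

// [[Rcpp::export]]
List mw_step_cpp(NumericVector q, NumericVector omega, NumericVector accel,
                 NumericVector mag, double beta, double dt) {
  double qq[4] = {q[0], q[1], q[2], q[3]};
  const double g[3] = {omega[0], omega[1], omega[2]};
  const double a[3] = {accel[0], accel[1], accel[2]};
  const double m[3] = {mag[0], mag[1], mag[2]};
  bool degenerate = false;
  mw_step(qq, g, a, m, beta, dt, degenerate);
  return List::create(_["q"] = NumericVector::create(qq[0], qq[1], qq[2], qq[3]),
                      _["degenerate"] = degenerate);
}
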