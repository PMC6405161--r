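#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Network Epileptor vector field (2D reduction, permittivity coupling):
//   dx_i/dt = -x_i^3 - 2 x_i^2 + 1 - z_i + I
//   dz_i/dt = (1/tau) * [ 4 (x_i - x0_i) - z_i - sum_j K_ij (x_j - x_i) ]
// State layout: y = (x_1..x_N, z_1..z_N). K column-major, symmetric.
static void epi_rhs(int n, const double* K, const double* srow, const double* x0,
                    double tau, double I, const double* y, double* dy) {
  const double* x = y;
  const double* z = y + n;
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    dy[i] = -xi * xi * xi - 2.0 * xi * xi + 1.0 - z[i] + I;
  }
  double* cx = dy + n;  // accumulate K x in the z-slot, column-major
  for (int i = 0; i < n; ++i) cx[i] = 0.0;
  for (int j = 0; j < n; ++j) {
    double xj = x[j];
    if (xj == 0.0) continue;
    const double* Kc = K + (size_t)n * j;
    for (int i = 0; i < n; ++i) cx[i] += Kc[i] * xj;
  }
  for (int i = 0; i < n; ++i)
    dy[n + i] = (4.0 * (x[i] - x0[i]) - z[i] - cx[i] + srow[i] * x[i]) / tau;
}

// Tangent dynamics along a trajectory (for Lyapunov computation):
//   dvx_i = (-3 x_i^2 - 4 x_i) vx_i - vz_i
//   dvz_i = ( (4 + s_i) vx_i - sum_j K_ij vx_j - vz_i ) / tau
static void epi_rhs_tan(int n, const double* K, const double* srow,
                        double tau, const double* y, const double* v, double* dv) {
  const double* x = y;
  const double* vx = v;
  const double* vz = v + n;
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    dv[i] = (-3.0 * xi * xi - 4.0 * xi) * vx[i] - vz[i];
  }
  for (int i = 0; i < n; ++i) {
    double cv = 0.0;
    for (int j = 0; j < n; ++j) cv += K[i + (size_t)n * j] * vx[j];
    dv[n + i] = ((4.0 + srow[i]) * vx[i] - cv - vz[i]) / tau;
  }
}

struct EpiSys {
  int n;
  const double* K;
  const double* s;
  const double* x0;
  double tau, I;
  bool tangent;  // state is (y, v) of length 4n when true
  void operator()(const double* y, double* dy) const {
    epi_rhs(n, K, s, x0, tau, I, y, dy);
    if (tangent) epi_rhs_tan(n, K, s, tau, y, y + 2 * n, dy + 2 * n);
  }
};

// Cash-Karp embedded Runge-Kutta 5(4) tableau
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0/5, 0, 0, 0, 0},
  {3.0/40, 9.0/40, 0, 0, 0},
  {3.0/10, -9.0/10, 6.0/5, 0, 0},
  {-11.0/54, 5.0/2, -70.0/27, 35.0/27, 0},
  {1631.0/55296, 175.0/512, 575.0/13824, 44275.0/110592, 253.0/4096}};
static const double CK_C[6]  = {37.0/378, 0, 250.0/621, 125.0/594, 0, 512.0/1771};
static const double CK_DC[6] = {37.0/378 - 2825.0/27648, 0, 250.0/621 - 18575.0/48384,
                                125.0/594 - 13525.0/55296, -277.0/14336, 512.0/1771 - 1.0/4};

static bool all_finite(const std::vector<double>& v) {
  for (double u : v) if (!std::isfinite(u)) return false;
  return true;
}

// One Cash-Karp step from y (dim m, derivative dy0) with step h; fills y5 (5th
// order solution) and err (embedded error estimate).
static void ck_step(const EpiSys& sys, int m, const std::vector<double>& y,
                    const std::vector<double>& dy0, double h,
                    std::vector<double>& y5, std::vector<double>& err,
                    std::vector<std::vector<double> >& k, std::vector<double>& ytmp) {
  k[0] = dy0;
  for (int s = 1; s < 6; ++s) {
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int q = 0; q < s; ++q) acc += CK_B[s][q] * k[q][i];
      ytmp[i] = y[i] + h * acc;
    }
    sys(ytmp.data(), k[s].data());
  }
  for (int i = 0; i < m; ++i) {
    double acc5 = 0.0, acce = 0.0;
    for (int s = 0; s < 6; ++s) {
      acc5 += CK_C[s] * k[s][i];
      acce += CK_DC[s] * k[s][i];
    }
    y5[i] = y[i] + h * acc5;
    err[i] = h * acce;
  }
}

// Take one adaptive Cash-Karp step; on entry h is the proposed step, on exit it
// is the next proposal. Returns the step size actually taken.
static double adaptive_step(const EpiSys& sys, int m, std::vector<double>& y,
                            std::vector<double>& dy, double& h, double t,
                            double t_end, double rtol, double atol, double h_max,
                            std::vector<double>& y5, std::vector<double>& err,
                            std::vector<std::vector<double> >& k,
                            std::vector<double>& ytmp) {
  const double h_min = 1e-10;
  for (;;) {
    double h_step = std::min(h, t_end - t);
    ck_step(sys, m, y, dy, h_step, y5, err, k, ytmp);
    // Hairer-style RMS error norm
    double emax = 0.0;
    bool finite = all_finite(y5);
    if (finite) {
      double acc = 0.0;
      for (int i = 0; i < m; ++i) {
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
        double e = err[i] / sc;
        acc += e * e;
      }
      emax = std::sqrt(acc / m);
    }
    if (!finite || !std::isfinite(emax) || emax > 1.0) {
      double fac = (!finite || !std::isfinite(emax)) ? 0.2
                   : std::max(0.2, 0.9 * std::pow(emax, -0.25));
      h = h_step * fac;
      if (h < h_min)
        stop("integration failure (step-size collapse) at t = %f", t);
    } else {
      double fac = (emax > 1e-12) ? 0.9 * std::pow(emax, -0.2) : 5.0;
      fac = std::min(5.0, std::max(0.2, fac));
      h = std::min(std::max(h_step * fac, h_min), h_max);
      return h_step;
    }
  }
}

// Integrate the network Epileptor. Output is sampled on a regular grid by cubic
// Hermite interpolation between accepted steps. If `watch` is non-empty the
// integration terminates as soon as any watched node's x exceeds theta
// (upward crossing), which makes failed-containment runs cheap.
// [[Rcpp::export]]
List cpp_integrate(NumericMatrix K, NumericVector x0, double tau, double I,
                   NumericVector y0, double t0, double t1, double dt_out,
                   double rtol, double atol, IntegerVector watch, double theta,
                   std::string method, double dt_fixed, double h_max) {
  int n = K.nrow();
  if (K.ncol() != n) stop("K must be square");
  int m = 2 * n;
  if ((int)y0.size() != m) stop("state length must be 2N");

  std::vector<double> srow(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) srow[i] += K(i, j);
  EpiSys sys{n, K.begin(), srow.data(), x0.begin(), tau, I, false};

  int nout = (int)std::floor((t1 - t0) / dt_out + 1e-9) + 1;
  NumericVector times(nout);
  NumericMatrix out(nout, m);
  for (int r = 0; r < nout; ++r) times[r] = t0 + r * dt_out;

  std::vector<double> y(y0.begin(), y0.end()), dy(m), y5(m), dy5(m), err(m), ytmp(m);
  std::vector<std::vector<double> > k(6, std::vector<double>(m));
  for (int i = 0; i < m; ++i) out(0, i) = y[i];

  bool rk4 = (method == "rk4");
  double t = t0, h = rk4 ? dt_fixed : std::min(0.1, h_max);
  int iout = 1;
  bool stopped = false;
  double t_stop = NA_REAL;
  long nsteps = 0;

  sys(y.data(), dy.data());
  while (t < t1 - 1e-9 * std::max(1.0, std::fabs(t1)) && iout < nout && !stopped) {
    double h_step;
    if (rk4) {
      h_step = std::min(dt_fixed, t1 - t);
      std::vector<double>& k1 = k[0]; std::vector<double>& k2 = k[1];
      std::vector<double>& k3 = k[2]; std::vector<double>& k4 = k[3];
      k1 = dy;
      for (int i = 0; i < m; ++i) ytmp[i] = y[i] + 0.5 * h_step * k1[i];
      sys(ytmp.data(), k2.data());
      for (int i = 0; i < m; ++i) ytmp[i] = y[i] + 0.5 * h_step * k2[i];
      sys(ytmp.data(), k3.data());
      for (int i = 0; i < m; ++i) ytmp[i] = y[i] + h_step * k3[i];
      sys(ytmp.data(), k4.data());
      for (int i = 0; i < m; ++i)
        y5[i] = y[i] + h_step / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      if (!all_finite(y5))
        stop("integration failure (non-finite state) at t = %f", t + h_step);
    } else {
      h_step = adaptive_step(sys, m, y, dy, h, t, t1, rtol, atol, h_max,
                             y5, err, k, ytmp);
    }
    ++nsteps;
    if (nsteps > 500000000L)
      stop("integration failure (step budget exhausted) at t = %f", t);

    double t_new = t + h_step;
    sys(y5.data(), dy5.data());

    // cubic Hermite output sampling on (t, t_new]
    while (iout < nout && times[iout] <= t_new + 1e-9) {
      double s = (times[iout] - t) / h_step;
      double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
      double h10 = s * (1 - s) * (1 - s);
      double h01 = s * s * (3 - 2 * s);
      double h11 = s * s * (s - 1);
      for (int i = 0; i < m; ++i)
        out(iout, i) = h00 * y[i] + h10 * h_step * dy[i] +
                       h01 * y5[i] + h11 * h_step * dy5[i];
      ++iout;
    }

    if (watch.size() > 0) {
      for (int w = 0; w < watch.size(); ++w) {
        int idx = watch[w] - 1;  // 1-based node indices
        if (idx >= 0 && idx < n && y5[idx] > theta) {
          stopped = true;
          t_stop = t_new;
          break;
        }
      }
    }

    y.swap(y5);
    dy.swap(dy5);
    t = t_new;
  }

  int kept = stopped ? iout : nout;
  NumericVector times_k(kept);
  NumericMatrix out_k(kept, m);
  for (int r = 0; r < kept; ++r) {
    times_k[r] = times[r];
    for (int i = 0; i < m; ++i) out_k(r, i) = out(r, i);
  }
  return List::create(_["times"] = times_k, _["y"] = out_k,
                      _["stopped"] = stopped, _["t_stop"] = t_stop,
                      _["n_steps"] = (double)nsteps);
}

// Tangent-space integration for the maximum Lyapunov exponent/vector.
// Renormalizes the tangent vector every renorm_interval time units; returns the
// average log growth rate and the time-averaged |v_x| localization profile.
// [[Rcpp::export]]
List cpp_lyapunov(NumericMatrix K, NumericVector x0, double tau, double I,
                  NumericVector y0, NumericVector v0, double horizon,
                  double renorm_interval, double rtol, double atol, double h_max) {
  int n = K.nrow();
  int m = 2 * n;
  if ((int)y0.size() != m || (int)v0.size() != m)
    stop("state/tangent length must be 2N");
  std::vector<double> srow(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) srow[i] += K(i, j);
  EpiSys sys{n, K.begin(), srow.data(), x0.begin(), tau, I, true};

  int M = 2 * m;  // augmented state (y, v)
  std::vector<double> y(M), dy(M), y5(M), err(M), ytmp(M);
  std::vector<std::vector<double> > k(6, std::vector<double>(M));
  for (int i = 0; i < m; ++i) { y[i] = y0[i]; y[m + i] = v0[i]; }
  {
    double nv = 0.0;
    for (int i = 0; i < m; ++i) nv += y[m + i] * y[m + i];
    nv = std::sqrt(nv);
    if (nv <= 0) stop("zero initial tangent vector");
    for (int i = 0; i < m; ++i) y[m + i] /= nv;
  }

  double t = 0.0, h = std::min(0.1, h_max);
  double log_sum = 0.0, t_last_renorm = 0.0;
  std::vector<double> profile(n, 0.0);
  double profile_w = 0.0;
  long nsteps = 0;

  sys(y.data(), dy.data());
  while (t < horizon - 1e-9 * std::max(1.0, horizon)) {
    double h_step = adaptive_step(sys, M, y, dy, h, t, horizon, rtol, atol,
                                  h_max, y5, err, k, ytmp);
    ++nsteps;
    if (nsteps > 500000000L) stop("integration failure (step budget exhausted)");
    y.swap(y5);
    sys(y.data(), dy.data());
    t += h_step;

    if (t - t_last_renorm >= renorm_interval ||
        t >= horizon - 1e-9 * std::max(1.0, horizon)) {
      double nv = 0.0;
      for (int i = 0; i < m; ++i) nv += y[m + i] * y[m + i];
      nv = std::sqrt(nv);
      if (nv <= 0 || !std::isfinite(nv))
        stop("integration failure (degenerate tangent vector) at t = %f", t);
      log_sum += std::log(nv);
      for (int i = 0; i < m; ++i) y[m + i] /= nv;
      for (int i = 0; i < n; ++i) profile[i] += std::fabs(y[m + i]);
      profile_w += 1.0;
      t_last_renorm = t;
      sys(y.data(), dy.data());
    }
  }
  NumericVector prof(n);
  double ps = 0.0;
  for (int i = 0; i < n; ++i) ps += profile[i];
  for (int i = 0; i < n; ++i) prof[i] = (ps > 0) ? profile[i] / ps : 0.0;
  return List::create(_["exponent"] = log_sum / t, _["profile"] = prof,
                      _["n_renorm"] = profile_w, _["n_steps"] = (double)nsteps);
}
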