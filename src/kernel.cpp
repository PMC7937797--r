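#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All kernels work in the package's internal dimensionless units
// (lengths in L, times in L^2/D, energies in kBT, forces in kBT/L),
// but gamma/kBT/mass are passed explicitly so the diagnostics can vary them.

namespace {

struct Channel {
  double hmax, hmin, L, omega, phase0;
  int aexp;  // 1: slit (A ~ h), 2: cone (A ~ h^2)
};

inline double chan_radius(const Channel& ch, double x, double t) {
  return (ch.hmax - ch.hmin) * (x / ch.L - 0.5) * std::sin(ch.omega * t + ch.phase0) +
         0.5 * (ch.hmax + ch.hmin);
}

// F = kBT * d/dx ln A + f_mu * kBT / L, with d/dx ln A = aexp * h' / h
inline double chan_force(const Channel& ch, double x, double t, double fmu,
                         double kBT) {
  double s = std::sin(ch.omega * t + ch.phase0);
  double h = (ch.hmax - ch.hmin) * (x / ch.L - 0.5) * s + 0.5 * (ch.hmax + ch.hmin);
  double dh = (ch.hmax - ch.hmin) * s / ch.L;
  return kBT * (ch.aexp * dh / h + fmu / ch.L);
}

}  // namespace

// Integrate one translocation trajectory.
//
// boundary: 0 = reflecting entrance / absorbing exit, 1 = absorbing both.
// backend:  0 = GJF stochastic Velocity-Verlet, 1 = overdamped Euler-Maruyama.
// draw_phase: if true the oscillation phase is drawn uniform on [0, 2pi)
//   from R's RNG (so set.seed() controls it); otherwise phase0 is used as is.
// Draw order is fixed (phase, initial velocity, one Gaussian per step) so
// that ensembles under different f_mu share noise streams seed-for-seed.
//
// Returns tau (first-passage time, NA on timeout), exit_side
// (1 exit, 0 entrance, -1 timeout), n_steps, phase0, v0, and optional
// strided (t, x) path samples.
// [[Rcpp::export]]
List cpp_translocate(double hmax, double hmin, double L, double omega,
                     int aexp, double fmu, double mass, double gamma,
                     double kBT, double dt, double max_time, double x0,
                     bool draw_phase, double phase0, int boundary,
                     int backend, int record_stride) {
  Channel ch{hmax, hmin, L, omega, 0.0, aexp};
  ch.phase0 = draw_phase ? unif_rand() * 2.0 * M_PI : phase0;
  double v0 = norm_rand() * std::sqrt(kBT / mass);

  const double c = gamma * dt / (2.0 * mass);
  const double b = 1.0 / (1.0 + c);
  const double a = (1.0 - c) / (1.0 + c);
  const double sig = std::sqrt(2.0 * gamma * kBT * dt);
  const double sig_em = std::sqrt(2.0 * kBT * dt / gamma);

  double x = x0, v = v0, t = 0.0;
  double f = chan_force(ch, x, 0.0, fmu, kBT);
  double tau = NA_REAL;
  int exit_side = -1;
  long n_steps = 0;

  std::vector<double> rec_t, rec_x;
  if (record_stride > 0) {
    rec_t.push_back(0.0);
    rec_x.push_back(x);
  }

  while (t < max_time) {
    double xn;
    double beta = 0.0;
    if (backend == 0) {
      beta = sig * norm_rand();
      xn = x + b * dt * v + b * dt * dt / (2.0 * mass) * f +
           b * dt / (2.0 * mass) * beta;
    } else {
      xn = x + (f / gamma) * dt + sig_em * norm_rand();
    }
    double tn = t + dt;
    ++n_steps;
    // Drawn every step so that all backends and force settings consume
    // the RNG stream identically (common random numbers across sweeps).
    double u_bridge = unif_rand();

    if (xn >= L) {  // absorbing exit: linear crossing-time interpolation
      tau = t + dt * (L - x) / (xn - x);
      exit_side = 1;
      break;
    }
    bool flip = false;
    if (xn < 0.0) {
      if (boundary == 1) {
        tau = t + dt * (0.0 - x) / (xn - x);
        exit_side = 0;
        break;
      }
      xn = -xn;  // mirror reflection at the entrance
      if (xn >= L) xn = L * (1.0 - 1e-12);  // pathological huge step
      flip = true;
    }
    // Brownian-bridge test for an unobserved excursion across the
    // absorbing exit within the step (removes the sqrt(dt) bias of
    // discretely observed first passages); D = kBT/gamma.
    double p_exit = std::exp(-(L - x) * (L - xn) * gamma / (kBT * dt));
    if (u_bridge < p_exit) {
      tau = t + 0.5 * dt;
      exit_side = 1;
      break;
    }
    if (boundary == 1) {  // same test at an absorbing entrance
      double p_in = std::exp(-x * xn * gamma / (kBT * dt));
      if (u_bridge < p_in) {  // reuse: disjoint-in-practice events
        tau = t + 0.5 * dt;
        exit_side = 0;
        break;
      }
    }

    double fn = chan_force(ch, xn, tn, fmu, kBT);
    if (backend == 0) {
      double vn = a * v + dt / (2.0 * mass) * (a * f + fn) + b / mass * beta;
      v = flip ? -vn : vn;
    }
    x = xn;
    f = fn;
    t = tn;
    if (!std::isfinite(x) || !std::isfinite(f))
      stop("non-finite state during integration (x=%g, f=%g, t=%g)", x, f, t);
    if (record_stride > 0 && (n_steps % record_stride == 0)) {
      rec_t.push_back(t);
      rec_x.push_back(x);
    }
  }

  List out = List::create(
      _["tau"] = tau, _["exit_side"] = exit_side,
      _["n_steps"] = (double)n_steps, _["phase0"] = ch.phase0, _["v0"] = v0);
  if (record_stride > 0) {
    out["path_t"] = NumericVector(rec_t.begin(), rec_t.end());
    out["path_x"] = NumericVector(rec_x.begin(), rec_x.end());
  }
  return out;
}

// Free-particle ensemble (no forces, no boundaries) for integrator
// diagnostics: returns the ensemble mean of x(t)^2 and v(t)^2 at strided
// times. Particles start at x = 0 with Boltzmann velocities.
// [[Rcpp::export]]
List cpp_free_ensemble(int n, int n_steps, int stride, double mass,
                       double gamma, double kBT, double dt) {
  const double c = gamma * dt / (2.0 * mass);
  const double b = 1.0 / (1.0 + c);
  const double a = (1.0 - c) / (1.0 + c);
  const double sig = std::sqrt(2.0 * gamma * kBT * dt);

  int nt = n_steps / stride;
  NumericVector times(nt), x2(nt), v2(nt);
  for (int k = 0; k < nt; ++k) times[k] = (k + 1) * stride * dt;

  for (int i = 0; i < n; ++i) {
    double x = 0.0, v = norm_rand() * std::sqrt(kBT / mass);
    for (int k = 0; k < nt; ++k) {
      for (int s = 0; s < stride; ++s) {
        double beta = sig * norm_rand();
        x += b * dt * v + b * dt / (2.0 * mass) * beta;
        v = a * v + b / mass * beta;
      }
      x2[k] += x * x;
      v2[k] += v * v;
    }
  }
  for (int k = 0; k < nt; ++k) {
    x2[k] /= n;
    v2[k] /= n;
  }
  return List::create(_["t"] = times, _["msd"] = x2, _["v2"] = v2);
}

// Long GJF trajectory in a static harmonic well U = k x^2 / 2: strided
// position samples after burn-in, for configurational-sampling checks.
// [[Rcpp::export]]
NumericVector cpp_harmonic_track(int n_samples, int stride, int burn_in,
                                 double k, double mass, double gamma,
                                 double kBT, double dt) {
  const double c = gamma * dt / (2.0 * mass);
  const double b = 1.0 / (1.0 + c);
  const double a = (1.0 - c) / (1.0 + c);
  const double sig = std::sqrt(2.0 * gamma * kBT * dt);

  double x = 0.0, v = norm_rand() * std::sqrt(kBT / mass);
  double f = -k * x;
  NumericVector out(n_samples);
  long total = (long)burn_in + (long)n_samples * stride;
  int filled = 0;
  for (long s = 1; s <= total; ++s) {
    double beta = sig * norm_rand();
    double xn = x + b * dt * v + b * dt * dt / (2.0 * mass) * f +
                b * dt / (2.0 * mass) * beta;
    double fn = -k * xn;
    v = a * v + dt / (2.0 * mass) * (a * f + fn) + b / mass * beta;
    x = xn;
    f = fn;
    if (s > burn_in && ((s - burn_in) % stride == 0)) out[filled++] = x;
  }
  return out;
}
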