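// Neural-mass network dynamics: three subpopulations per source (spiny
// stellate, pyramidal, inhibitory interneurons), second-order synaptic
// kernels, four intrinsic connections and forward/backward/lateral
// extrinsic connections.  Time unit throughout is milliseconds.
//
// State layout, 9 states per source, source-major:
//   [x0, x1, x2, x3, x4, x5, x6, x7, x8]
//   x0 : pyramidal depolarization (observation target), dx0 = x5 - x6
//   x1/x4 : spiny stellate potential / derivative
//   x2/x5 : pyramidal excitatory PSP pair
//   x3/x6 : pyramidal inhibitory PSP pair
//   x7/x8 : inhibitory interneuron pair
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int NS = 9; // states per source

// Baseline-centred sigmoid gain: S(0) = 0, bounded, monotone.
// linear_gain replaces S by the identity (slope-1 test hook) so the
// whole network becomes a linear system with a closed-form solution.
static inline double gain(double v, double r1, double r2, bool linear) {
  if (linear) return v;
  return 1.0 / (1.0 + std::exp(-r1 * (v - r2))) -
         1.0 / (1.0 + std::exp(r1 * r2));
}

struct NMPar {
  double He, Hi, ke, ki, g1, g2, g3, g4, r1, r2;
  bool linear;
};

// dx for the whole network. x: 9n vector; drive: per-source exogenous
// drive (already C*u, adaptation-filtered and gamma5-scaled upstream);
// AF/AB/AL: receiver-row extrinsic gain matrices.
static void nm_deriv(const vec &x, const vec &drive, const NMPar &p,
                     const mat &AF, const mat &AB, const mat &AL, vec &dx) {
  const uword n = AF.n_rows;
  vec s0(n);
  for (uword i = 0; i < n; ++i)
    s0(i) = gain(x(NS * i), p.r1, p.r2, p.linear);
  vec aF = AF * s0, aB = AB * s0, aL = AL * s0;
  const double ke2 = p.ke * p.ke, ki2 = p.ki * p.ki;
  for (uword i = 0; i < n; ++i) {
    const uword o = NS * i;
    const double x0 = x(o), x1 = x(o + 1), x2 = x(o + 2), x3 = x(o + 3),
                 x4 = x(o + 4), x5 = x(o + 5), x6 = x(o + 6), x7 = x(o + 7),
                 x8 = x(o + 8);
    const double s0i = s0(i);
    const double s1i = gain(x1, p.r1, p.r2, p.linear);
    const double s7i = gain(x7, p.r1, p.r2, p.linear);
    dx(o)     = x5 - x6;
    dx(o + 1) = x4;
    dx(o + 4) = p.ke * p.He * (aF(i) + aL(i) + p.g1 * s0i + drive(i)) -
                2.0 * p.ke * x4 - ke2 * x1;
    dx(o + 2) = x5;
    dx(o + 5) = p.ke * p.He * (aB(i) + aL(i) + p.g2 * s1i) -
                2.0 * p.ke * x5 - ke2 * x2;
    dx(o + 3) = x6;
    dx(o + 6) = p.ki * p.Hi * p.g4 * s7i - 2.0 * p.ki * x6 - ki2 * x3;
    dx(o + 7) = x8;
    dx(o + 8) = p.ke * p.He * (aB(i) + aL(i) + p.g3 * s0i) -
                2.0 * p.ke * x8 - ke2 * x7;
  }
}

static NMPar unpack(const Rcpp::List &params, bool linear_gain) {
  NMPar p;
  p.He = Rcpp::as<double>(params["H_e"]);
  p.Hi = Rcpp::as<double>(params["H_i"]);
  // tau given in ms; dynamics run in seconds, so kappa = 1000/tau (1/s)
  p.ke = 1000.0 / Rcpp::as<double>(params["tau_e"]);
  p.ki = 1000.0 / Rcpp::as<double>(params["tau_i"]);
  p.g1 = Rcpp::as<double>(params["gamma1"]);
  p.g2 = Rcpp::as<double>(params["gamma2"]);
  p.g3 = Rcpp::as<double>(params["gamma3"]);
  p.g4 = Rcpp::as<double>(params["gamma4"]);
  p.r1 = Rcpp::as<double>(params["rho1"]);
  p.r2 = Rcpp::as<double>(params["rho2"]);
  p.linear = linear_gain;
  return p;
}

// [[Rcpp::export(name = ".nm_deriv_cpp")]]
arma::vec nm_deriv_cpp(const arma::vec &state, const arma::vec &drive,
                       const Rcpp::List &params, const arma::mat &AF,
                       const arma::mat &AB, const arma::mat &AL,
                       bool linear_gain = false) {
  NMPar p = unpack(params, linear_gain);
  vec dx(state.n_elem, fill::zeros);
  nm_deriv(state, drive, p, AF, AB, AL, dx);
  return dx;
}

// Fixed-step classic RK4.  drive: n_sources x (n_steps+1), sampled on the
// integration grid (linear interpolation supplies midpoints).  Returns the
// state sampled every `sample_every` steps after the initial condition:
// either the full 9n-state or just the per-source x0 rows.
// [[Rcpp::export(name = ".nm_integrate_cpp")]]
arma::mat nm_integrate_cpp(const arma::vec &init, const arma::mat &drive,
                           const Rcpp::List &params, const arma::mat &AF,
                           const arma::mat &AB, const arma::mat &AL,
                           double dt, int sample_every,
                           bool linear_gain = false, bool full_state = false) {
  NMPar p = unpack(params, linear_gain);
  const uword n = AF.n_rows;
  const int n_steps = drive.n_cols - 1;
  const int n_out = n_steps / sample_every;
  mat out(full_state ? NS * n : n, n_out);
  vec x = init, k1(NS * n), k2(NS * n), k3(NS * n), k4(NS * n), tmp(NS * n);
  int oi = 0;
  for (int s = 0; s < n_steps; ++s) {
    vec u0 = drive.col(s), u1 = drive.col(s + 1);
    vec um = 0.5 * (u0 + u1);
    nm_deriv(x, u0, p, AF, AB, AL, k1);
    tmp = x + 0.5 * dt * k1;
    nm_deriv(tmp, um, p, AF, AB, AL, k2);
    tmp = x + 0.5 * dt * k2;
    nm_deriv(tmp, um, p, AF, AB, AL, k3);
    tmp = x + dt * k3;
    nm_deriv(tmp, u1, p, AF, AB, AL, k4);
    x += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if ((s + 1) % sample_every == 0) {
      if (!x.is_finite())
        Rcpp::stop("neural-mass integration diverged at t = %.4f s",
                   (s + 1) * dt);
      if (full_state) {
        out.col(oi) = x;
      } else {
        for (uword i = 0; i < n; ++i) out(i, oi) = x(NS * i);
      }
      ++oi;
    }
  }
  return out;
}
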