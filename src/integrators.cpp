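// Fixed-step RK4 integrators for the Sprott A-D flows and the two reservoir
// node families, plus tangent-space (Gram-Schmidt) Lyapunov machinery.
// All randomness lives on the R side; these routines are deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec::fixed<3> sprott_rhs(int sys, const arma::vec::fixed<3>& s) {
  const double x = s[0], y = s[1], z = s[2];
  arma::vec::fixed<3> d;
  switch (sys) {
  case 0: d[0] = y;     d[1] = -x + y * z; d[2] = 1.0 - y * y;       break; // A
  case 1: d[0] = y * z; d[1] = x - y;      d[2] = 1.0 - x * y;       break; // B
  case 2: d[0] = y * z; d[1] = x - y;      d[2] = 1.0 - x * x;       break; // C
  case 3: d[0] = -y;    d[1] = x + z;      d[2] = x * z + 3.0 * y * y; break; // D
  default: stop("unknown Sprott system code");
  }
  return d;
}

static inline arma::mat::fixed<3, 3> sprott_jac(int sys, const arma::vec::fixed<3>& s) {
  const double x = s[0], y = s[1], z = s[2];
  arma::mat::fixed<3, 3> J;
  J.zeros();
  switch (sys) {
  case 0: J(0, 1) = 1;  J(1, 0) = -1; J(1, 1) = z;  J(1, 2) = y; J(2, 1) = -2 * y; break;
  case 1: J(0, 1) = z;  J(0, 2) = y;  J(1, 0) = 1;  J(1, 1) = -1; J(2, 0) = -y; J(2, 1) = -x; break;
  case 2: J(0, 1) = z;  J(0, 2) = y;  J(1, 0) = 1;  J(1, 1) = -1; J(2, 0) = -2 * x; break;
  case 3: J(0, 1) = -1; J(1, 0) = 1;  J(1, 2) = 1;  J(2, 0) = z;  J(2, 1) = 6 * y; J(2, 2) = x; break;
  }
  return J;
}

static inline void rk4_sprott_step(int sys, arma::vec::fixed<3>& s, double h) {
  arma::vec::fixed<3> k1 = sprott_rhs(sys, s);
  arma::vec::fixed<3> k2 = sprott_rhs(sys, arma::vec::fixed<3>(s + 0.5 * h * k1));
  arma::vec::fixed<3> k3 = sprott_rhs(sys, arma::vec::fixed<3>(s + 0.5 * h * k2));
  arma::vec::fixed<3> k4 = sprott_rhs(sys, arma::vec::fixed<3>(s + h * k3));
  s += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

// Integrate a Sprott flow; sample every `stride` internal steps of size h.
// Returns (n_out x 3); the first transient_out output samples are dropped.
// [[Rcpp::export]]
arma::mat sprott_rk4_cpp(int sys, arma::vec state0, double h, int stride,
                         int n_out, int transient_out, double guard) {
  arma::vec::fixed<3> s;
  s = state0.subvec(0, 2);
  arma::mat out(n_out, 3);
  const long total = (long)n_out + transient_out;
  for (long i = 0; i < total; ++i) {
    if (i >= transient_out) out.row(i - transient_out) = s.t();
    for (int k = 0; k < stride; ++k) rk4_sprott_step(sys, s, h);
    if (!s.is_finite() || arma::abs(s).max() > guard)
      stop("trajectory diverged at output step %ld (|state| > %g)", i + 1, guard);
  }
  return out;
}

// Gram-Schmidt Lyapunov spectrum for a Sprott flow.  Co-integrates the state
// and three tangent vectors (RK4 on the combined 12-dim system with the
// analytic Jacobian evaluated at the RK4 stage states), re-orthonormalizing
// every renorm_every steps.  Returns the per-renormalization log norms.
// [[Rcpp::export]]
arma::mat sprott_lyap_cpp(int sys, arma::vec state0, double h, double n_steps,
                          int renorm_every, double guard) {
  arma::vec::fixed<3> s;
  s = state0.subvec(0, 2);
  arma::mat Q(3, 3, arma::fill::eye);
  const long nsteps = (long)n_steps;
  const long n_renorm = nsteps / renorm_every;
  arma::mat logs(n_renorm, 3, arma::fill::zeros);
  long ir = 0;
  for (long i = 0; i < nsteps; ++i) {
    // combined RK4: stage derivatives for tangents use J at the stage states
    arma::vec::fixed<3> k1 = sprott_rhs(sys, s);
    arma::mat::fixed<3, 3> K1 = sprott_jac(sys, s) * Q;
    arma::vec::fixed<3> s2 = s + 0.5 * h * k1;
    arma::vec::fixed<3> k2 = sprott_rhs(sys, s2);
    arma::mat::fixed<3, 3> K2 = sprott_jac(sys, s2) * arma::mat::fixed<3, 3>(Q + 0.5 * h * K1);
    arma::vec::fixed<3> s3 = s + 0.5 * h * k2;
    arma::vec::fixed<3> k3 = sprott_rhs(sys, s3);
    arma::mat::fixed<3, 3> K3 = sprott_jac(sys, s3) * arma::mat::fixed<3, 3>(Q + 0.5 * h * K2);
    arma::vec::fixed<3> s4 = s + h * k3;
    arma::vec::fixed<3> k4 = sprott_rhs(sys, s4);
    arma::mat::fixed<3, 3> K4 = sprott_jac(sys, s4) * arma::mat::fixed<3, 3>(Q + h * K3);
    s += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    Q += (h / 6.0) * (K1 + 2.0 * K2 + 2.0 * K3 + K4);
    if ((i + 1) % renorm_every == 0 && ir < n_renorm) {
      // modified Gram-Schmidt
      for (int c = 0; c < 3; ++c) {
        for (int p = 0; p < c; ++p)
          Q.col(c) -= arma::dot(Q.col(p), Q.col(c)) * Q.col(p);
        double nrm = arma::norm(Q.col(c));
        logs(ir, c) = std::log(nrm);
        Q.col(c) /= nrm;
      }
      ++ir;
      if (!s.is_finite() || arma::abs(s).max() > guard)
        stop("base trajectory diverged at step %ld", i + 1);
    }
  }
  return logs;
}

// ---------------- spiking reservoir (two-variable relaxation nodes) --------

static inline arma::vec g_thresh(const arma::vec& v, const arma::vec& phi) {
  // threshold nonlinearity: 0 below (or at) threshold, 1 above
  return arma::conv_to<arma::vec>::from(v > phi);
}

struct SpikDeriv {
  const arma::mat& A; const arma::vec& W; const arma::vec& phi;
  double TC, Rr, gamma;
  void operator()(const arma::vec& u, const arma::vec& v, double s,
                  arma::vec& du, arma::vec& dv) const {
    du = TC * (-arma::pow(u, 3) + u % g_thresh(v, phi));
    dv = (TC / Rr) * (W * s - gamma * v + A * u);
  }
};

// Simulate the spiking reservoir over the spike drive (one output step per
// drive sample, `substeps` internal RK4 steps, drive held constant within a
// step).  The reset u_i > 0.5 => v_i = 0 is applied after every internal step.
// [[Rcpp::export]]
List spiking_sim_cpp(const arma::mat& A, const arma::vec& W, const arma::vec& phi,
                     double TC, double Rtau, double gamma,
                     const arma::vec& drive, int substeps,
                     arma::vec u, arma::vec v, double guard) {
  const int M = A.n_rows, N = drive.n_elem;
  const double h = 1.0 / substeps;
  SpikDeriv f{A, W, phi, TC, Rtau, gamma};
  arma::mat U(N, M), V(N, M);
  arma::vec k1u(M), k1v(M), k2u(M), k2v(M), k3u(M), k3v(M), k4u(M), k4v(M);
  for (int t = 0; t < N; ++t) {
    const double s = drive[t];
    for (int k = 0; k < substeps; ++k) {
      f(u, v, s, k1u, k1v);
      f(u + 0.5 * h * k1u, v + 0.5 * h * k1v, s, k2u, k2v);
      f(u + 0.5 * h * k2u, v + 0.5 * h * k2v, s, k3u, k3v);
      f(u + h * k3u, v + h * k3v, s, k4u, k4v);
      u += (h / 6.0) * (k1u + 2.0 * k2u + 2.0 * k3u + k4u);
      v += (h / 6.0) * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      v.elem(arma::find(u > 0.5)).zeros();
    }
    if (!u.is_finite() || !v.is_finite() ||
        std::max(arma::abs(u).max(), arma::abs(v).max()) > guard)
      stop("spiking reservoir diverged at step %d", t + 1);
    U.row(t) = u.t();
    V.row(t) = v.t();
  }
  return List::create(_["u"] = U, _["v"] = V);
}

// ---------------- polynomial ODE reservoir --------------------------------

// [[Rcpp::export]]
arma::mat poly_sim_cpp(const arma::mat& A, const arma::vec& W,
                       double alpha, double p1, double p2, double p3,
                       const arma::vec& drive, int substeps,
                       arma::vec r, double guard) {
  const int M = A.n_rows, N = drive.n_elem;
  const double h = 1.0 / substeps;
  arma::mat R(N, M);
  arma::vec k1(M), k2(M), k3(M), k4(M), tmp(M);
  auto f = [&](const arma::vec& x, double s, arma::vec& dx) {
    dx = alpha * (p1 * x + p2 * arma::square(x) + p3 * arma::pow(x, 3) + A * x + W * s);
  };
  for (int t = 0; t < N; ++t) {
    const double s = drive[t];
    for (int k = 0; k < substeps; ++k) {
      f(r, s, k1);
      f(r + 0.5 * h * k1, s, k2);
      f(r + 0.5 * h * k2, s, k3);
      f(r + h * k3, s, k4);
      r += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    }
    if (!r.is_finite() || arma::abs(r).max() > guard)
      stop("polynomial reservoir diverged at step %d", t + 1);
    R.row(t) = r.t();
  }
  return R;
}

// ---------------- conditional Lyapunov exponents ---------------------------

// Largest conditional exponent of the driven spiking reservoir: one tangent
// vector (du, dv) evolved along the trajectory.  The threshold nonlinearity g
// is treated as piecewise constant (zero derivative with respect to v); the
// reset zeroes both v_i and its tangent component.
// [[Rcpp::export]]
arma::vec spiking_cle_cpp(const arma::mat& A, const arma::vec& W, const arma::vec& phi,
                          double TC, double Rtau, double gamma,
                          const arma::vec& drive, int substeps, int renorm_every,
                          arma::vec u, arma::vec v,
                          arma::vec du, arma::vec dv, bool reset_tangent,
                          double guard) {
  const int M = A.n_rows, N = drive.n_elem;
  const double h = 1.0 / substeps;
  SpikDeriv f{A, W, phi, TC, Rtau, gamma};
  const int n_renorm = N / renorm_every;
  arma::vec logs(n_renorm, arma::fill::zeros);
  // normalize the initial tangent
  double nrm0 = std::sqrt(arma::dot(du, du) + arma::dot(dv, dv));
  du /= nrm0; dv /= nrm0;
  arma::vec k1u(M), k1v(M), k2u(M), k2v(M), k3u(M), k3v(M), k4u(M), k4v(M);
  auto tf = [&](const arma::vec& uu, const arma::vec& vv,
                const arma::vec& tu, const arma::vec& tv,
                arma::vec& dtu, arma::vec& dtv) {
    dtu = TC * ((-3.0 * arma::square(uu) + g_thresh(vv, phi)) % tu);
    dtv = (TC / Rtau) * (A * tu - gamma * tv);
  };
  int ir = 0;
  arma::vec t1u(M), t1v(M), t2u(M), t2v(M), t3u(M), t3v(M), t4u(M), t4v(M);
  for (int t = 0; t < N; ++t) {
    const double s = drive[t];
    for (int k = 0; k < substeps; ++k) {
      f(u, v, s, k1u, k1v);
      tf(u, v, du, dv, t1u, t1v);
      arma::vec u2 = u + 0.5 * h * k1u, v2 = v + 0.5 * h * k1v;
      f(u2, v2, s, k2u, k2v);
      tf(u2, v2, du + 0.5 * h * t1u, dv + 0.5 * h * t1v, t2u, t2v);
      arma::vec u3 = u + 0.5 * h * k2u, v3 = v + 0.5 * h * k2v;
      f(u3, v3, s, k3u, k3v);
      tf(u3, v3, du + 0.5 * h * t2u, dv + 0.5 * h * t2v, t3u, t3v);
      arma::vec u4 = u + h * k3u, v4 = v + h * k3v;
      f(u4, v4, s, k4u, k4v);
      tf(u4, v4, du + h * t3u, dv + h * t3v, t4u, t4v);
      u += (h / 6.0) * (k1u + 2.0 * k2u + 2.0 * k3u + k4u);
      v += (h / 6.0) * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      du += (h / 6.0) * (t1u + 2.0 * t2u + 2.0 * t3u + t4u);
      dv += (h / 6.0) * (t1v + 2.0 * t2v + 2.0 * t3v + t4v);
      arma::uvec fired = arma::find(u > 0.5);
      v.elem(fired).zeros();
      if (reset_tangent) dv.elem(fired).zeros();
    }
    if (!u.is_finite() || !v.is_finite())
      stop("spiking reservoir diverged at step %d", t + 1);
    if ((t + 1) % renorm_every == 0 && ir < n_renorm) {
      double nrm = std::sqrt(arma::dot(du, du) + arma::dot(dv, dv));
      logs[ir++] = std::log(nrm);
      du /= nrm; dv /= nrm;
    }
  }
  (void)guard;
  return logs;
}

// Largest conditional exponent of the driven polynomial reservoir.
// [[Rcpp::export]]
arma::vec poly_cle_cpp(const arma::mat& A, const arma::vec& W,
                       double alpha, double p1, double p2, double p3,
                       const arma::vec& drive, int substeps, int renorm_every,
                       arma::vec r, arma::vec dr, double guard) {
  const int M = A.n_rows, N = drive.n_elem;
  const double h = 1.0 / substeps;
  const int n_renorm = N / renorm_every;
  arma::vec logs(n_renorm, arma::fill::zeros);
  dr /= arma::norm(dr);
  auto f = [&](const arma::vec& x, double s, arma::vec& dx) {
    dx = alpha * (p1 * x + p2 * arma::square(x) + p3 * arma::pow(x, 3) + A * x + W * s);
  };
  auto tf = [&](const arma::vec& x, const arma::vec& tx, arma::vec& dtx) {
    dtx = alpha * ((p1 + 2.0 * p2 * x + 3.0 * p3 * arma::square(x)) % tx + A * tx);
  };
  arma::vec k1(M), k2(M), k3(M), k4(M), t1(M), t2(M), t3(M), t4(M);
  int ir = 0;
  for (int t = 0; t < N; ++t) {
    const double s = drive[t];
    for (int k = 0; k < substeps; ++k) {
      f(r, s, k1); tf(r, dr, t1);
      arma::vec r2 = r + 0.5 * h * k1;
      f(r2, s, k2); tf(r2, dr + 0.5 * h * t1, t2);
      arma::vec r3 = r + 0.5 * h * k2;
      f(r3, s, k3); tf(r3, dr + 0.5 * h * t2, t3);
      arma::vec r4 = r + h * k3;
      f(r4, s, k4); tf(r4, dr + h * t3, t4);
      r += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      dr += (h / 6.0) * (t1 + 2.0 * t2 + 2.0 * t3 + t4);
    }
    if (!r.is_finite() || arma::abs(r).max() > guard)
      stop("polynomial reservoir diverged at step %d", t + 1);
    if ((t + 1) % renorm_every == 0 && ir < n_renorm) {
      double nrm = arma::norm(dr);
      logs[ir++] = std::log(nrm);
      dr /= nrm;
    }
  }
  return logs;
}
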