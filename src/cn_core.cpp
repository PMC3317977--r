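#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Crank-Nicolson time stepping for the backward Kolmogorov equation
// u_t = L u on a fixed (possibly non-uniform) frequency grid, with the
// degenerate endpoints held at their payoff values (both diffusion and
// drift coefficients vanish there, so u(t, 0) and u(t, 1) never move).
//
// Evolves K independent payoff systems under the same generator in one
// call: the tridiagonal factorisation is shared and the systems sit in the
// fast (contiguous) dimension, so the per-node Thomas recurrences pipeline
// across systems.
//
// lo, di, up : tridiagonal rows of the discrete generator L at the J
//              interior nodes (lo[0] couples to the left boundary value,
//              up[J-1] to the right boundary value).
// u0         : J x K matrix of initial interior values (payoffs).
// bc_left, bc_right : length-K boundary (= payoff endpoint) values.
// n_euler    : number of initial backward-Euler steps (Rannacher start-up
//              for non-smooth payoffs); remaining steps are Crank-Nicolson.
// probe_left, probe_w : linear interpolation stencils on the full grid
//              (0-based; full index 0 is the left boundary, J+1 the right):
//              probe value = (1-w) * u[i] + w * u[i+1].
//
// Returns "probes": (n_steps+1) x (P*K) matrix, row s = time s*dt, columns
// blocked by system (system k occupies columns k*P .. k*P+P-1); and
// "final": J x K interior values for restarting / horizon extension.
// [[Rcpp::export]]
List cn_evolve(NumericVector lo, NumericVector di, NumericVector up,
               NumericMatrix u0, NumericVector bc_left, NumericVector bc_right,
               double dt, int n_steps, int n_euler,
               IntegerVector probe_left, NumericVector probe_w) {
  const int J = di.size();
  const int K = u0.ncol();
  const int P = probe_left.size();
  if (J < 3) stop("need at least 3 interior grid nodes");
  if (u0.nrow() != J) stop("u0 must have one row per interior node");
  if (bc_left.size() != K || bc_right.size() != K)
    stop("boundary values must have one entry per system");
  if (n_steps < 0) stop("n_steps must be >= 0");

  std::vector<double> clo(lo.begin(), lo.end()), cdi(di.begin(), di.end()),
      cup(up.begin(), up.end());
  // extended solution array, node-major with the K systems contiguous:
  // ue[(i)*K + k] for full-grid node i in 0..J+1
  std::vector<double> ue((J + 2) * K), rhs(J * K);
  for (int k = 0; k < K; ++k) {
    ue[k] = bc_left[k];
    ue[(J + 1) * K + k] = bc_right[k];
    for (int i = 0; i < J; ++i) ue[(i + 1) * K + k] = u0(i, k);
  }

  NumericMatrix probes(n_steps + 1, P * K);
  auto do_probe = [&](int row) {
    for (int p = 0; p < P; ++p) {
      const int i = probe_left[p];
      const double w = probe_w[p];
      for (int k = 0; k < K; ++k) {
        probes(row, k * P + p) = (1.0 - w) * ue[i * K + k] + w * ue[(i + 1) * K + k];
      }
    }
  };

  // Thomas factorisation of (I - a*dt*L) for a = 1 (Euler) and 1/2 (CN)
  struct Fac { std::vector<double> al, cp, inv_de; };
  auto factor = [&](double a, Fac& f) {
    f.al.resize(J); f.cp.resize(J); f.inv_de.resize(J);
    std::vector<double> ad(J), au(J);
    for (int i = 0; i < J; ++i) {
      f.al[i] = -a * dt * clo[i];
      ad[i] = 1.0 - a * dt * cdi[i];
      au[i] = -a * dt * cup[i];
    }
    f.inv_de[0] = 1.0 / ad[0];
    f.cp[0] = au[0] * f.inv_de[0];
    for (int i = 1; i < J; ++i) {
      f.inv_de[i] = 1.0 / (ad[i] - f.al[i] * f.cp[i - 1]);
      f.cp[i] = au[i] * f.inv_de[i];
    }
  };
  Fac cn, eu;
  factor(0.5, cn);
  if (n_euler > 0) factor(1.0, eu);

  do_probe(0);
  for (int s = 1; s <= n_steps; ++s) {
    const bool euler = (s <= n_euler);
    const double b = euler ? 0.0 : 0.5;   // explicit weight
    const Fac& f = euler ? eu : cn;
    // rhs = (I + b*dt*L) u, plus the full-step boundary coupling
    for (int i = 0; i < J; ++i) {
      const double wl = b * dt * clo[i], wc = b * dt * cdi[i], wu = b * dt * cup[i];
      const double* um = &ue[i * K];        // node i-1 in full indexing
      const double* uc = &ue[(i + 1) * K];
      const double* upn = &ue[(i + 2) * K];
      double* r = &rhs[i * K];
      for (int k = 0; k < K; ++k) {
        r[k] = uc[k] + wl * um[k] + wc * uc[k] + wu * upn[k];
      }
    }
    for (int k = 0; k < K; ++k) {
      rhs[k] += (1.0 - b) * dt * clo[0] * bc_left[k];
      rhs[(J - 1) * K + k] += (1.0 - b) * dt * cup[J - 1] * bc_right[k];
    }
    // forward sweep
    for (int k = 0; k < K; ++k) rhs[k] *= f.inv_de[0];
    for (int i = 1; i < J; ++i) {
      const double ali = f.al[i], inv = f.inv_de[i];
      double* r = &rhs[i * K];
      const double* rp = &rhs[(i - 1) * K];
      for (int k = 0; k < K; ++k) r[k] = (r[k] - ali * rp[k]) * inv;
    }
    // back substitution into ue
    for (int k = 0; k < K; ++k) ue[J * K + k] = rhs[(J - 1) * K + k];
    for (int i = J - 2; i >= 0; --i) {
      const double cpi = f.cp[i];
      double* u = &ue[(i + 1) * K];
      const double* un = &ue[(i + 2) * K];
      const double* r = &rhs[i * K];
      for (int k = 0; k < K; ++k) u[k] = r[k] - cpi * un[k];
    }
    do_probe(s);
    if (!std::isfinite(ue[(J / 2 + 1) * K])) {
      stop("Crank-Nicolson step %d produced non-finite values; reduce dt", s);
    }
  }

  NumericMatrix fin(J, K);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < J; ++i) fin(i, k) = ue[(i + 1) * K + k];
  }
  return List::create(_["probes"] = probes, _["final"] = fin);
}
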