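#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Codon-level ribosome-traffic model with an L-codon footprint.
// p[i] (1-based in docs, 0-based here) is the probability that the decoded
// codon (front) of a ribosome sits on codon i. A ribosome with front at i
// covers codons [i, min(i+L-1, n)]. Initiation needs codons 1..L empty;
// the step i -> i+1 needs codon i+L empty (no condition once i+L > n);
// termination fires at i = n.
//
// Refined mean-field closure for the conditional vacancy L codons ahead:
//   q_i = (1 - sum_{j=i+1}^{i+L} p_j) / (1 - sum_{j=i+1}^{i+L-1} p_j)

// Build the stationary profile implied by a trial flux J by backward
// recursion from the termination end. Sites i in (n-L, n) carry no vacancy
// condition, so p_i = J/kE_i there and p_n = J/kT; further back
// p_i = J * B_i / (kE_i * A_i). Returns false when J is infeasible
// (negative vacancies or footprint-overlapping occupancies).
static bool profile_given_J(int n, int L, const std::vector<double>& kE,
                            double kT, double J, std::vector<double>& p) {
  const double slack = 1e-12;
  p.assign(n, 0.0);
  double pn = J / kT;
  if (pn > 1.0 + slack) return false;
  p[n - 1] = pn;
  for (int i = n - 1; i >= std::max(0, n - L + 1); --i) {
    if (i == n - 1) continue;
    double v = J / kE[i];
    if (v > 1.0 + slack) return false;
    p[i] = v;
  }
  // running window sums over p[i+1 .. i+L-1] (0-based: p[i+1..i+L-1])
  for (int i = n - L - 1; i >= 0; --i) {
    // A = 1 - sum_{j=i+1}^{i+L} p_j ; B = 1 - sum_{j=i+1}^{i+L-1} p_j
    double sB = 0.0;
    for (int j = i + 1; j <= i + L - 1; ++j) sB += p[j];
    double sA = sB + p[i + L];
    double A = 1.0 - sA, B = 1.0 - sB;
    if (A <= slack || B <= slack) return false;
    double v = J * B / (kE[i] * A);
    if (v < 0.0 || v > 1.0 + slack) return false;
    // footprint exclusion: window starting at i must not exceed 1
    if (v + sB > 1.0 + slack) return false;
    p[i] = v;
  }
  return true;
}

// O(n) variant keeping running sums (the loop above is O(nL); this is the
// one actually used -- the explicit-sum version documents the algebra).
static bool profile_given_J_fast(int n, int L, const std::vector<double>& kE,
                                 double kT, double J, std::vector<double>& p) {
  const double slack = 1e-12;
  p.assign(n, 0.0);
  if (J / kT > 1.0 + slack) return false;
  p[n - 1] = J / kT;
  for (int i = n - 2; i >= std::max(0, n - L + 1); --i) {
    double v = J / kE[i];
    if (v > 1.0 + slack) return false;
    p[i] = v;
  }
  if (n - L - 1 < 0) return true;
  double sB = 0.0;  // sum p[i+1 .. i+L-1]
  {
    int i = n - L - 1;
    for (int j = i + 1; j <= i + L - 1; ++j) sB += p[j];
  }
  for (int i = n - L - 1; i >= 0; --i) {
    double sA = sB + p[i + L];
    double A = 1.0 - sA, B = 1.0 - sB;
    if (A <= slack || B <= slack) return false;
    double v = J * B / (kE[i] * A);
    if (v < 0.0 || v > 1.0 + slack || v + sB > 1.0 + slack) return false;
    p[i] = v;
    if (i > 0) sB += p[i] - p[i + L - 1];  // shift window left
  }
  return true;
}

// Initiation-balance residual f(J) = kappa * (1 - sum_{1..L} p_j) - J.
// f is positive at J = 0 and decreases through the physical root; an
// infeasible profile means J overshoots the carrying capacity.
static bool init_residual(int n, int L, const std::vector<double>& kE,
                          double kappa, double kT, double J,
                          std::vector<double>& p, double& f) {
  if (!profile_given_J_fast(n, L, kE, kT, J, p)) return false;
  double sL = 0.0;
  for (int j = 0; j < L && j < n; ++j) sL += p[j];
  if (sL > 1.0 + 1e-12) return false;
  f = kappa * std::max(1.0 - sL, 0.0) - J;
  return true;
}

// Bisection on J using the backward recursion. Exact (to rounding) in the
// initiation-limited and maximal-current regimes; in the termination-
// limited regime the backward recursion is numerically unstable, so the
// result there only serves as an initial guess for the relaxation solver.
static bool recursion_solve(int n, int L, const std::vector<double>& kE,
                            double kappa, double kT,
                            std::vector<double>& p, double& J) {
  double kEmin = *std::min_element(kE.begin(), kE.end());
  double hi = std::min(kappa, std::min(kT, kEmin));
  if (hi <= 0.0) { p.assign(n, 0.0); J = 0.0; return true; }
  double lo = 0.0, f;
  std::vector<double> ptmp;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (init_residual(n, L, kE, kappa, kT, mid, ptmp, f) && f >= 0.0)
      lo = mid;
    else
      hi = mid;
    if (hi - lo <= 1e-15 * std::max(hi, 1e-30)) break;
  }
  if (lo <= 0.0) { p.assign(n, 0.0); J = 0.0; return true; }
  if (!init_residual(n, L, kE, kappa, kT, lo, p, f)) return false;
  J = lo;
  return true;
}

struct FluxStats { double jmin, jmax, jbar; };

// All n+1 transition fluxes for the current profile.
static FluxStats fluxes(int n, int L, const std::vector<double>& kE,
                        double kappa, double kT,
                        const std::vector<double>& p,
                        std::vector<double>& Jb) {
  Jb.assign(n + 1, 0.0);
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + p[i];
  double pe = 1.0 - (S[std::min(L, n)] - S[0]);
  Jb[0] = kappa * std::max(pe, 0.0);
  for (int i = 1; i <= n - 1; ++i) {  // bond i: site i -> i+1 (1-based)
    double q = 1.0;
    if (i + L <= n) {
      double A = 1.0 - (S[i + L] - S[i]);
      double B = 1.0 - (S[i + L - 1] - S[i]);
      q = (B > 1e-300) ? std::max(0.0, std::min(1.0, A / B)) : 0.0;
    }
    Jb[i] = kE[i - 1] * p[i - 1] * q;
  }
  Jb[n] = kT * p[n - 1];
  FluxStats fs;
  fs.jmin = fs.jmax = Jb[0];
  double s = 0.0;
  for (int i = 0; i <= n; ++i) {
    s += Jb[i];
    if (Jb[i] < fs.jmin) fs.jmin = Jb[i];
    if (Jb[i] > fs.jmax) fs.jmax = Jb[i];
  }
  fs.jbar = s / (n + 1);
  return fs;
}

// [[Rcpp::export(rng = false)]]
List rt_steady_state(int n, int L, NumericVector kE_in, double kappa,
                     double kT, double tol, double max_steps,
                     NumericVector p0, double dt_in) {
  std::vector<double> kE(kE_in.begin(), kE_in.end());
  if ((int)kE.size() == 1) kE.assign(n, kE[0]);
  std::vector<double> p;
  double J = 0.0;
  bool warm = (p0.size() == (R_xlen_t)n);
  if (warm) {
    p.assign(p0.begin(), p0.end());
  } else if (!recursion_solve(n, L, kE, kappa, kT, p, J)) {
    p.assign(n, 0.0);
  }

  double kEmax = *std::max_element(kE.begin(), kE.end());
  double scale = std::max(kEmax, kappa);
  // dt only sets the relaxation pace, not the fixed point (the Patankar
  // update's stationary point is the steady state for any dt); 2/kE is
  // the largest factor found stable across all traffic regimes.
  double dt = dt_in > 0 ? dt_in : 2.0 / std::max(kEmax, 1e-12);

  std::vector<double> Jb;
  double res = R_PosInf;
  double steps = 0;
  int check_every = 4;
  bool converged = false;

  // vacancy factor of the bond leaving site i (1-based), current values
  auto q_at = [&](int i) -> double {
    if (i + L > n) return 1.0;
    double sB = 0.0;
    for (int j = i + 1; j <= i + L - 1; ++j) sB += p[j - 1];
    double A = 1.0 - sB - p[i + L - 1], B = 1.0 - sB;
    return (B > 1e-300) ? std::max(0.0, std::min(1.0, A / B)) : 0.0;
  };
  auto update_site = [&](int i) {
    // Patankar-type update: dp_i/dt = a - b p_i, advanced implicitly as
    // p <- (p + a dt) / (1 + b dt); positivity-preserving and stable for
    // the stiff initiation/termination rate constants.
    double a, b;
    if (i == 1) {
      double rest = 0.0;
      for (int j = 2; j <= std::min(L, n); ++j) rest += p[j - 1];
      a = kappa * std::max(1.0 - rest, 0.0);
      b = kappa;
    } else {
      a = kE[i - 2] * p[i - 2] * q_at(i - 1);
      b = 0.0;
    }
    if (i == n) b += kT; else b += kE[i - 1] * q_at(i);
    double v = (p[i - 1] + a * dt) / (1.0 + b * dt);
    // never let a footprint window overfill: transiently overfull states
    // are unphysical and drain only at the (possibly tiny) termination
    // rate, stalling deeply jammed lattices
    double Sr = 0.0, Sl = 0.0;
    for (int j = i + 1; j <= std::min(i + L - 1, n); ++j) Sr += p[j - 1];
    for (int j = std::max(1, i - L + 1); j < i; ++j) Sl += p[j - 1];
    double cap = std::min(1.0 - Sr, 1.0 - Sl);
    p[i - 1] = std::max(0.0, std::min(cap, v));
  };

  // Stagnation guard: a dt too aggressive for the current traffic regime
  // shows up as a residual that stops shrinking (bounded odd-even
  // oscillation); halve dt when no progress is made for a while.
  double best_res = R_PosInf;
  double last_improve = 0;
  const double dt_floor = 0.1 / std::max(kEmax, 1e-12);

  while (steps < max_steps) {
    // Alternating-direction Gauss-Seidel sweeps: updated values are used
    // immediately, so density changes propagate a full lattice length per
    // sweep in the sweep direction (transport-limited convergence would
    // otherwise need ~n iterations per e-fold).
    if (((long long)steps) % 2 == 0) {
      for (int i = 1; i <= n; ++i) update_site(i);
    } else {
      for (int i = n; i >= 1; --i) update_site(i);
    }
    steps += 1;
    if (((long long)steps) % check_every == 0 || steps >= max_steps) {
      FluxStats fs = fluxes(n, L, kE, kappa, kT, p, Jb);
      if (fs.jmax <= 1e-13 * std::max(scale, 1e-12)) {  // empty lattice
        res = 0.0; J = fs.jbar; converged = true; break;
      }
      res = (fs.jmax - fs.jmin) / std::max(fs.jbar, 1e-300);
      J = fs.jbar;
      // absolute spread floor: in deeply jammed lattices (k_T tiny) all
      // fluxes are ~k_T and the relative spread bottoms out at rounding
      // noise of order n * k_E * eps / J
      double atol_spread = n * kEmax * 4e-15;
      if (res <= tol || fs.jmax - fs.jmin <= atol_spread) {
        converged = true; break;
      }
      if (res < best_res) { best_res = res; last_improve = steps; }
      else if (steps - last_improve > 2000 && dt > dt_floor * 1.0001) {
        dt = std::max(dt / 2.0, dt_floor);
        best_res = res;
        last_improve = steps;
      }
    }
  }
  if (!converged) {
    FluxStats fs = fluxes(n, L, kE, kappa, kT, p, Jb);
    J = fs.jbar;
    res = (fs.jmax - fs.jmin) / std::max(fs.jbar, 1e-300);
    if (fs.jmax <= 1e-13 * std::max(scale, 1e-12)) { res = 0.0; converged = true; }
  }
  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["J"] = J, _["residual"] = res,
                      _["steps"] = steps, _["converged"] = converged);
}

// Exposed for unit tests of the recursion branch in isolation.
// [[Rcpp::export(rng = false)]]
List rt_profile_for_flux(int n, int L, NumericVector kE_in, double kT,
                         double J) {
  std::vector<double> kE(kE_in.begin(), kE_in.end());
  if ((int)kE.size() == 1) kE.assign(n, kE[0]);
  std::vector<double> p, pref;
  bool ok = profile_given_J_fast(n, L, kE, kT, J, p);
  bool ok2 = profile_given_J(n, L, kE, kT, J, pref);
  double dmax = 0.0;
  if (ok && ok2)
    for (int i = 0; i < n; ++i) dmax = std::max(dmax, std::fabs(p[i] - pref[i]));
  return List::create(_["feasible"] = ok,
                      _["p"] = NumericVector(p.begin(), p.end()),
                      _["agree"] = (ok == ok2), _["max_diff"] = dmax);
}
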