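// Generic biochemical-network ODE engine.
//
// The network is passed from R in a flattened form (see flatten_network() in
// R/engine.R): per-reaction rate-law codes, resolved rate constants, Hill
// parameters, regulator indices, and reactant/product incidence in CSR
// layout. Rate-law codes:
//   0 mass_action        k * prod(reactant^stoich)
//   1 hill_activation    k * A^n / (K^n + A^n)
//   2 hill_inhibition    k * K^n / (K^n + A^n)
//   3 synthesis          k
//   4 first_order_decay  k * substrate (first reactant)
//   5 michaelis_menten   k * A / (K + A)
//
// Integration uses the Rosenbrock(2,3) pair of Shampine & Reichelt (the
// "ode23s" method): L-stable, one Jacobian + one LU per step, suited to the
// stiff, wide-timescale systems produced by receptor/transcription networks.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct FlatNet {
  int n_species = 0;
  int n_reactions = 0;
  IntegerVector law;        // rate-law code per reaction
  NumericVector rate;       // resolved rate constant per reaction
  NumericVector K;          // Hill/MM half-saturation (NA if unused)
  NumericVector nh;         // Hill exponent (NA if unused)
  IntegerVector reg;        // 0-based regulator species index, -1 if none
  IntegerVector re_ptr, re_idx;  // reactant CSR
  NumericVector re_st;
  IntegerVector pr_ptr, pr_idx;  // product CSR
  NumericVector pr_st;
  IntegerVector is_const;   // per species: clamped input (zero derivative)

  explicit FlatNet(const List& spec) {
    n_species   = as<int>(spec["n_species"]);
    law         = spec["law"];
    rate        = spec["rate"];
    K           = spec["K"];
    nh          = spec["n_hill"];
    reg         = spec["regulator"];
    re_ptr      = spec["re_ptr"];
    re_idx      = spec["re_idx"];
    re_st       = spec["re_st"];
    pr_ptr      = spec["pr_ptr"];
    pr_idx      = spec["pr_idx"];
    pr_st       = spec["pr_st"];
    is_const    = spec["is_const"];
    n_reactions = law.size();
  }
};

inline double law_rate(const FlatNet& net, int r, const arma::vec& y) {
  const int code = net.law[r];
  double v = net.rate[r];
  switch (code) {
  case 0: {  // mass action over reactants
    for (int p = net.re_ptr[r]; p < net.re_ptr[r + 1]; ++p) {
      const double amt = std::max(y[net.re_idx[p]], 0.0);
      const double st = net.re_st[p];
      v *= (st == 1.0) ? amt : std::pow(amt, st);
    }
    return v;
  }
  case 1: {  // hill activation
    const double a = std::max(y[net.reg[r]], 0.0);
    const double n = net.nh[r];
    const double an = std::pow(a, n), kn = std::pow(net.K[r], n);
    return v * an / (kn + an);
  }
  case 2: {  // hill inhibition
    const double a = std::max(y[net.reg[r]], 0.0);
    const double n = net.nh[r];
    const double an = std::pow(a, n), kn = std::pow(net.K[r], n);
    return v * kn / (kn + an);
  }
  case 3:    // constitutive synthesis
    return v;
  case 4: {  // first-order decay of the first reactant
    const double amt = std::max(y[net.re_idx[net.re_ptr[r]]], 0.0);
    return v * amt;
  }
  case 5: {  // Michaelis-Menten in the regulator
    const double a = std::max(y[net.reg[r]], 0.0);
    return v * a / (net.K[r] + a);
  }
  default:
    stop("unknown rate-law code %d", code);
  }
  return 0.0;  // unreachable
}

void reaction_rates(const FlatNet& net, const arma::vec& y, arma::vec& out) {
  for (int r = 0; r < net.n_reactions; ++r) out[r] = law_rate(net, r, y);
}

void rhs(const FlatNet& net, const arma::vec& y, arma::vec& dy,
         arma::vec& scratch_rates) {
  reaction_rates(net, y, scratch_rates);
  dy.zeros();
  for (int r = 0; r < net.n_reactions; ++r) {
    const double v = scratch_rates[r];
    for (int p = net.re_ptr[r]; p < net.re_ptr[r + 1]; ++p)
      dy[net.re_idx[p]] -= net.re_st[p] * v;
    for (int p = net.pr_ptr[r]; p < net.pr_ptr[r + 1]; ++p)
      dy[net.pr_idx[p]] += net.pr_st[p] * v;
  }
  for (int i = 0; i < net.n_species; ++i)
    if (net.is_const[i]) dy[i] = 0.0;
}

// Forward-difference Jacobian of the RHS.
void jacobian(const FlatNet& net, const arma::vec& y, const arma::vec& f0,
              arma::mat& J, arma::vec& scratch_y, arma::vec& scratch_f,
              arma::vec& scratch_rates) {
  const int n = net.n_species;
  for (int j = 0; j < n; ++j) {
    const double yj = y[j];
    double h = 1e-7 * std::max(std::abs(yj), 1e-4);
    scratch_y = y;
    scratch_y[j] = yj + h;
    rhs(net, scratch_y, scratch_f, scratch_rates);
    J.col(j) = (scratch_f - f0) / h;
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_reaction_rates")]]
NumericVector cpp_reaction_rates(List spec, NumericVector state) {
  FlatNet net(spec);
  arma::vec y(state.begin(), state.size());
  arma::vec out(net.n_reactions);
  reaction_rates(net, y, out);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".cpp_rhs")]]
NumericVector cpp_rhs(List spec, NumericVector state) {
  FlatNet net(spec);
  arma::vec y(state.begin(), state.size());
  arma::vec dy(net.n_species), rates(net.n_reactions);
  rhs(net, y, dy, rates);
  return NumericVector(dy.begin(), dy.end());
}

// Integrate from times[0] to times[end], returning the state at every
// requested time (rows). Adaptive ode23s; steps are capped so every output
// time is hit exactly.
// [[Rcpp::export(name = ".cpp_integrate")]]
List cpp_integrate(List spec, NumericVector state, NumericVector times,
                   double rel_tol, double abs_tol, double max_step,
                   int max_steps) {
  FlatNet net(spec);
  const int n = net.n_species;
  const int nt = times.size();
  if (nt < 1) stop("empty time grid");

  arma::vec y(state.begin(), n);
  arma::mat out(nt, n);
  out.row(0) = y.t();

  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);

  arma::vec f0(n), f1(n), f2(n), k1(n), k2(n), k3(n), ynew(n), err(n);
  arma::vec sy(n), sf(n), rates(net.n_reactions);
  arma::mat J(n, n), W(n, n);
  arma::mat L, U, P;

  double t = times[0];
  double tend = times[nt - 1];
  double h = std::min(max_step, (tend - t) / 100.0);
  if (h <= 0) h = 1e-3;
  int out_i = 1;
  int steps = 0;
  bool need_jac = true;

  rhs(net, y, f0, rates);

  while (out_i < nt) {
    const double t_target = times[out_i];
    if (h > t_target - t) h = t_target - t;
    if (h < 1e-12 * std::max(1.0, std::abs(t))) {
      // degenerate interval; copy state
      out.row(out_i) = y.t();
      ++out_i;
      h = std::min(max_step, std::max(1e-6, (tend - t) / 100.0));
      continue;
    }
    if (++steps > max_steps)
      stop("ODE integration exceeded %d steps at t=%g (h=%g); "
           "the system may be too stiff for the tolerances requested",
           max_steps, t, h);

    if (need_jac) {
      jacobian(net, y, f0, J, sy, sf, rates);
      need_jac = false;
    }
    W = arma::eye(n, n) - (h * d) * J;
    bool ok = arma::lu(L, U, P, W);
    if (!ok) stop("singular iteration matrix at t=%g", t);

    auto solveW = [&](const arma::vec& b) -> arma::vec {
      return arma::solve(arma::trimatu(U),
                         arma::solve(arma::trimatl(L), P * b,
                                     arma::solve_opts::fast),
                         arma::solve_opts::fast);
    };

    k1 = solveW(f0);
    rhs(net, y + 0.5 * h * k1, f1, rates);
    k2 = solveW(f1 - k1) + k1;
    ynew = y + h * k2;
    rhs(net, ynew, f2, rates);
    k3 = solveW(f2 - e32 * (k2 - f1) - 2.0 * (k1 - f0));
    err = (h / 6.0) * (k1 - 2.0 * k2 + k3);

    double enorm = 0.0;
    for (int i = 0; i < n; ++i) {
      const double sc = abs_tol + rel_tol * std::max(std::abs(y[i]),
                                                     std::abs(ynew[i]));
      enorm = std::max(enorm, std::abs(err[i]) / sc);
    }

    if (enorm <= 1.0) {
      t += h;
      y = ynew;
      f0 = f2;
      need_jac = true;
      if (std::abs(t - t_target) < 1e-9 * std::max(1.0, std::abs(t_target))) {
        out.row(out_i) = y.t();
        ++out_i;
      }
      double fac = 0.8 * std::pow(std::max(enorm, 1e-10), -1.0 / 3.0);
      h = std::min(max_step, h * std::min(5.0, std::max(0.2, fac)));
    } else {
      double fac = 0.8 * std::pow(enorm, -1.0 / 3.0);
      h *= std::min(0.9, std::max(0.1, fac));
      if (h < 1e-12)
        stop("step size underflow at t=%g; integration failed", t);
    }
  }

  return List::create(_["times"] = times, _["states"] = out,
                      _["steps"] = steps);
}
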