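#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the method-of-lines reaction-diffusion system.
//
// State layout follows deSolve::ode.1D: all nodes of species 1, then all
// nodes of species 2, ... (species-major). Mass-action velocities support
// zeroth-, first- and second-order reactions (at most two distinct
// reactant species; stoichiometry > 1 handled through the exponent e1).
//
// Reactions flagged in `capmod` (synthesis/turnover/proteasomal
// degradation) are scaled by the remaining uncleaved substrate fraction:
// effector-caspase activity shuts protein synthesis and degradation down
// linearly as the model substrate is consumed.
//
// Inputs are travelling-wave pseudo-reactions: node p of input m switches
// on at t_on(p, m) with a first-order exponential saturation profile. A
// softplus ramp of width tau mollifies the onset so the RHS stays C1 in
// time (tau = 0 gives the sharp switch).
//
// [[Rcpp::export]]
NumericVector rd_network_rhs(double t, NumericVector y,
                             NumericMatrix S,        // ns x nr net stoichiometry
                             NumericVector k,        // nr rate constants
                             IntegerVector i1,       // first reactant (1-based, 0 none)
                             NumericVector e1,       // its stoichiometric exponent
                             IntegerVector i2,       // second reactant (1-based, 0 none)
                             LogicalVector capmod,   // capacity-modified reactions
                             int isub, int icle,     // substrate / cleaved indices (1-based)
                             NumericVector D,        // ns diffusivities (um^2/s)
                             double dx, int nx,
                             IntegerVector in_target,
                             NumericVector in_cmax, NumericVector in_k,
                             NumericMatrix t_on,     // nx x n_inputs onset times
                             double tau) {
  const int ns = S.nrow(), nr = S.ncol();
  const int neq = ns * nx;

  // clipped concentrations, node-major for cache friendliness: C[p + nx*i]
  std::vector<double> C(neq);
  for (int i = 0; i < ns; ++i)
    for (int p = 0; p < nx; ++p) {
      double v = y[i * nx + p];
      C[p + nx * i] = v > 0.0 ? v : 0.0;
    }

  // capacity factor: uncleaved fraction of the reporter substrate
  std::vector<double> w(nx, 1.0);
  for (int p = 0; p < nx; ++p) {
    double tot = C[p + nx * (isub - 1)] + C[p + nx * (icle - 1)];
    if (tot > 0.0) {
      double f = C[p + nx * (isub - 1)] / tot;
      w[p] = f < 0.0 ? 0.0 : (f > 1.0 ? 1.0 : f);
    }
  }

  std::vector<double> dC(neq, 0.0);

  // reaction velocities, accumulated straight into dC through S
  std::vector<double> v(nx);
  for (int j = 0; j < nr; ++j) {
    const double kj = k[j];
    const int a = i1[j] - 1, b = i2[j] - 1;
    const double ea = e1[j];
    for (int p = 0; p < nx; ++p) {
      double vv = kj;
      if (a >= 0) {
        double ca = C[p + nx * a];
        vv *= (ea == 1.0) ? ca : std::pow(ca, ea);
      }
      if (b >= 0) vv *= C[p + nx * b];
      v[p] = vv;
    }
    if (capmod[j])
      for (int p = 0; p < nx; ++p) v[p] *= w[p];
    for (int i = 0; i < ns; ++i) {
      const double s = S(i, j);
      if (s == 0.0) continue;
      double* d = &dC[nx * i];
      for (int p = 0; p < nx; ++p) d[p] += s * v[p];
    }
  }

  // conservative flux-form diffusion with zero-flux boundaries
  if (nx > 1) {
    const double idx2 = 1.0 / (dx * dx);
    for (int i = 0; i < ns; ++i) {
      const double Di = D[i];
      if (Di <= 0.0) continue;
      const double* c = &C[nx * i];
      double* d = &dC[nx * i];
      for (int p = 0; p < nx; ++p) {
        double lap = 0.0;
        if (p > 0) lap += c[p - 1] - c[p];
        if (p < nx - 1) lap += c[p + 1] - c[p];
        d[p] += Di * idx2 * lap;
      }
    }
  }

  // travelling-wave inputs
  for (int m = 0; m < in_target.size(); ++m) {
    const int tg = in_target[m] - 1;
    const double cm = in_cmax[m], km = in_k[m];
    double* d = &dC[nx * tg];
    for (int p = 0; p < nx; ++p) {
      const double u = t - t_on(p, m);
      if (tau > 0.0) {
        const double z = u / tau;
        double s, ds;
        if (z > 30.0) { s = u; ds = 1.0; }
        else if (z < -30.0) { continue; }
        else { s = tau * std::log1p(std::exp(z)); ds = 1.0 / (1.0 + std::exp(-z)); }
        d[p] += cm * km * std::exp(-km * s) * ds;
      } else if (u > 0.0) {
        d[p] += cm * km * std::exp(-km * u);
      }
    }
  }

  NumericVector dy(neq);
  for (int i = 0; i < neq; ++i) dy[i] = dC[i];
  return dy;
}
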