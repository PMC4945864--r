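// Fast evaluation of QSSA rate laws and damped (chord) Newton steady-state
// solves for ensemble particles. Mirrors the reference R implementation in
// R/ratelaw.R and R/simulate.R; the R path remains the oracle in tests.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Plan {
  int nrx, nsteps_total, nmet;
  const int *ns, *m, *cyc, *ori, *step_off;
  const int *from, *to, *is_cat;
  const int *bind_off, *bind_idx;   // ragged over steps (1-based metabolites)
  const int *rel_off, *rel_idx;
  const int *allo_n;                // 0 = no allosteric spec
  const int *act_off, *act_idx, *inh_off, *inh_idx; // ragged over reactions
};

struct Particle {
  const double *kf, *kr;            // aligned with global step index
  const double *L, *Qref;           // per reaction (NA when none)
  const double *K;                  // aligned with act_idx then inh_idx blocks
  const int *K_act_off, *K_inh_off; // offsets into K per reaction
};

// Gaussian elimination with partial pivoting; a (n x n, col-major), b length n.
bool gauss_solve(std::vector<double> &a, std::vector<double> &b, int n) {
  for (int c = 0; c < n; ++c) {
    int piv = c;
    double best = std::fabs(a[c + c * n]);
    for (int r = c + 1; r < n; ++r) {
      double v = std::fabs(a[r + c * n]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-300) return false;
    if (piv != c) {
      for (int k = c; k < n; ++k) std::swap(a[c + k * n], a[piv + k * n]);
      std::swap(b[c], b[piv]);
    }
    double d = a[c + c * n];
    for (int r = c + 1; r < n; ++r) {
      double f = a[r + c * n] / d;
      if (f == 0.0) continue;
      for (int k = c; k < n; ++k) a[r + k * n] -= f * a[c + k * n];
      b[r] -= f * b[c];
    }
  }
  for (int c = n - 1; c >= 0; --c) {
    double s = b[c];
    for (int k = c + 1; k < n; ++k) s -= a[c + k * n] * b[k];
    b[c] = s / a[c + c * n];
  }
  return true;
}

// Net flux of reaction j at metabolite vector x (full, 0-based array).
double reaction_flux(const Plan &P, const Particle &pk, int j,
                     const double *x, double e) {
  int s0 = P.step_off[j], m = P.m[j];
  double wf[8], wr[8];
  for (int i = 0; i < m; ++i) {
    int g = s0 + i;
    double f = pk.kf[g], b = pk.kr[g];
    for (int q = P.bind_off[g]; q < P.bind_off[g + 1]; ++q)
      f *= x[P.bind_idx[q] - 1];
    for (int q = P.rel_off[g]; q < P.rel_off[g + 1]; ++q)
      b *= x[P.rel_idx[q] - 1];
    wf[i] = f; wr[i] = b;
  }
  double v;
  if (P.cyc[j]) {
    // single catalytic cycle: (prod f - prod b) / sum of rooted trees
    double num_f = 1.0, num_b = 1.0, den = 0.0;
    for (int i = 0; i < m; ++i) { num_f *= wf[i]; num_b *= wr[i]; }
    for (int s = 0; s < m; ++s) {
      // rooted at state s+1: terms t = 0..m-1
      for (int t = 0; t < m; ++t) {
        double term = 1.0;
        for (int k = 0; k < m; ++k) {
          int rel = (k - s + m) % m;     // position relative to root
          if (rel < t) term *= wr[(s + rel) % m];
          else if (rel > t) term *= wf[(s + rel) % m];
          // rel == t: removed edge
        }
        den += term;
      }
    }
    v = (num_f - num_b) / den;
  } else {
    int ns = P.ns[j];
    std::vector<double> A(ns * ns, 0.0), rhs(ns, 0.0);
    for (int i = 0; i < m; ++i) {
      int fr = P.from[s0 + i] - 1, to = P.to[s0 + i] - 1;
      A[to + fr * ns] += wf[i];
      A[fr + fr * ns] -= wf[i];
      A[fr + to * ns] += wr[i];
      A[to + to * ns] -= wr[i];
    }
    for (int c = 0; c < ns; ++c) A[(ns - 1) + c * ns] = 1.0;
    rhs[ns - 1] = 1.0;
    if (!gauss_solve(A, rhs, ns)) return NA_REAL;
    v = 0.0;
    for (int i = 0; i < m; ++i) {
      if (P.is_cat[s0 + i]) {
        v += wf[i] * rhs[P.from[s0 + i] - 1] - wr[i] * rhs[P.to[s0 + i] - 1];
      }
    }
  }
  if (P.allo_n[j] > 0) {
    double ti = 1.0, ta = 1.0;
    int ka = pk.K_act_off[j], ki = pk.K_inh_off[j];
    for (int q = P.act_off[j]; q < P.act_off[j + 1]; ++q)
      ta += x[P.act_idx[q] - 1] / pk.K[ka++];
    for (int q = P.inh_off[j]; q < P.inh_off[j + 1]; ++q)
      ti += x[P.inh_idx[q] - 1] / pk.K[ki++];
    double Q = pk.L[j] * std::pow(ti / ta, (double)P.allo_n[j]);
    v *= (1.0 + pk.Qref[j]) / (1.0 + Q);
  }
  return e * v * P.ori[j];
}

Plan unpack_plan(const List &pl) {
  Plan P;
  P.nrx = as<int>(pl["nrx"]);
  P.nmet = as<int>(pl["nmet"]);
  P.nsteps_total = as<int>(pl["nsteps"]);
  P.ns = INTEGER(pl["ns"]); P.m = INTEGER(pl["m"]);
  P.cyc = INTEGER(pl["cyc"]); P.ori = INTEGER(pl["ori"]);
  P.step_off = INTEGER(pl["step_off"]);
  P.from = INTEGER(pl["from"]); P.to = INTEGER(pl["to"]);
  P.is_cat = INTEGER(pl["is_cat"]);
  P.bind_off = INTEGER(pl["bind_off"]); P.bind_idx = INTEGER(pl["bind_idx"]);
  P.rel_off = INTEGER(pl["rel_off"]); P.rel_idx = INTEGER(pl["rel_idx"]);
  P.allo_n = INTEGER(pl["allo_n"]);
  P.act_off = INTEGER(pl["act_off"]); P.act_idx = INTEGER(pl["act_idx"]);
  P.inh_off = INTEGER(pl["inh_off"]); P.inh_idx = INTEGER(pl["inh_idx"]);
  return P;
}

Particle unpack_particle(const List &pk) {
  Particle K;
  K.kf = REAL(pk["kf"]); K.kr = REAL(pk["kr"]);
  K.L = REAL(pk["L"]); K.Qref = REAL(pk["Qref"]); K.K = REAL(pk["K"]);
  K.K_act_off = INTEGER(pk["K_act_off"]);
  K.K_inh_off = INTEGER(pk["K_inh_off"]);
  return K;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_network_fluxes(List plan_packed, List particle_packed,
                                 NumericVector x_full, NumericVector e_mult) {
  Plan P = unpack_plan(plan_packed);
  Particle pk = unpack_particle(particle_packed);
  NumericVector v(P.nrx);
  for (int j = 0; j < P.nrx; ++j)
    v[j] = reaction_flux(P, pk, j, REAL(x_full), e_mult[j]);
  return v;
}

// Damped chord-Newton solve of the reduced steady-state system for an
// ensemble particle. S_dyn: (ndyn x nrx) stoichiometry rows of the dynamic
// metabolites; cvec: constant boundary contribution to those rows;
// pools eliminate one balanced metabolite each.
// [[Rcpp::export]]
List cpp_solve_steady(List plan_packed, List particle_packed,
                      NumericVector x_template, IntegerVector bal_idx,
                      NumericMatrix S_dyn, NumericVector cvec,
                      IntegerVector dyn_pos, List pools,
                      NumericVector e_mult, NumericVector x0_dyn,
                      double atol, int max_iter, double x_divergence) {
  Plan P = unpack_plan(plan_packed);
  Particle pk = unpack_particle(particle_packed);
  int ndyn = x0_dyn.size(), nrx = P.nrx, nbal = bal_idx.size();
  int npool = pools.size();
  std::vector<int> p_elim(npool);
  std::vector<std::vector<int> > p_keep(npool);
  std::vector<std::vector<double> > p_w(npool);
  std::vector<double> p_tot(npool), p_welim(npool);
  for (int p = 0; p < npool; ++p) {
    List pl = pools[p];
    p_elim[p] = as<int>(pl["elim"]) - 1;        // position within bal
    IntegerVector kp = pl["keep"];
    NumericVector w = pl["w"];                   // weights for keep, then elim
    for (int q = 0; q < kp.size(); ++q) p_keep[p].push_back(kp[q] - 1);
    for (int q = 0; q < kp.size(); ++q) p_w[p].push_back(w[q]);
    p_welim[p] = w[kp.size()];
    p_tot[p] = as<double>(pl["total"]);
  }
  std::vector<double> xfull(x_template.begin(), x_template.end());
  std::vector<double> xbal(nbal);
  std::vector<double> v(nrx);

  // residual of the dynamic rows at x_dyn; returns false if state invalid
  auto residual = [&](const double *xd, double *g) -> bool {
    for (int i = 0; i < ndyn; ++i) xbal[dyn_pos[i] - 1] = xd[i];
    for (int p = 0; p < npool; ++p) {
      double rest = p_tot[p];
      for (size_t q = 0; q < p_keep[p].size(); ++q)
        rest -= p_w[p][q] * xbal[p_keep[p][q]];
      xbal[p_elim[p]] = rest / p_welim[p];
    }
    for (int i = 0; i < nbal; ++i) {
      if (!(xbal[i] > 0.0)) return false;
      xfull[bal_idx[i] - 1] = xbal[i];
    }
    for (int j = 0; j < nrx; ++j) {
      v[j] = reaction_flux(P, pk, j, xfull.data(), e_mult[j]);
      if (!R_finite(v[j])) return false;
    }
    for (int i = 0; i < ndyn; ++i) {
      double s = cvec[i];
      for (int j = 0; j < nrx; ++j) s += S_dyn(i, j) * v[j];
      g[i] = s;
    }
    return true;
  };

  std::vector<double> x(x0_dyn.begin(), x0_dyn.end());
  std::vector<double> g(ndyn), gn(ndyn), xn(ndyn), dx(ndyn), gp(ndyn);
  std::vector<double> J(ndyn * ndyn), A(ndyn * ndyn), b(ndyn);
  bool okg = residual(x.data(), g.data());
  double nrm = 0.0;
  if (okg) for (int i = 0; i < ndyn; ++i) nrm = std::max(nrm, std::fabs(g[i]));
  else nrm = R_PosInf;
  int iter = 0, fails = 0;
  bool stale = true, diverged = false;
  bool converged = okg && nrm <= atol;

  while (okg && nrm > atol && iter < max_iter) {
    ++iter;
    if (stale) {
      bool jac_ok = true;
      for (int c = 0; c < ndyn && jac_ok; ++c) {
        double h = 1e-7 * std::max(std::fabs(x[c]), 1e-3);
        std::vector<double> xp(x); xp[c] += h;
        if (!residual(xp.data(), gp.data())) { xp[c] = x[c] - h; h = -h;
          if (!residual(xp.data(), gp.data())) { jac_ok = false; break; } }
        for (int r = 0; r < ndyn; ++r) J[r + c * ndyn] = (gp[r] - g[r]) / h;
      }
      if (!jac_ok) break;
      stale = false;
    }
    A = J;
    for (int i = 0; i < ndyn; ++i) b[i] = -g[i];
    if (!gauss_solve(A, b, ndyn)) {
      if (stale) break;
      stale = true; continue;
    }
    dx = b;
    double lambda = 1.0;
    bool ok = false;
    while (lambda >= 1e-4) {
      bool pos = true;
      for (int i = 0; i < ndyn; ++i) {
        xn[i] = x[i] + lambda * dx[i];
        if (!(xn[i] > 0.0)) { pos = false; break; }
      }
      if (pos && residual(xn.data(), gn.data())) {
        double nn = 0.0;
        for (int i = 0; i < ndyn; ++i) nn = std::max(nn, std::fabs(gn[i]));
        if (nn < nrm * (1.0 - 0.25 * lambda) + atol) {
          x = xn; g = gn;
          stale = (lambda < 1.0) || (nn > 0.2 * nrm);
          nrm = nn; ok = true; fails = 0;
          break;
        }
      }
      lambda *= 0.5;
    }
    if (!ok) {
      if (++fails >= 2) break;
      stale = true;
    }
    double xmax = 0.0;
    for (int i = 0; i < ndyn; ++i) xmax = std::max(xmax, std::fabs(x[i]));
    if (xmax > x_divergence) { diverged = true; break; }
  }
  converged = okg && nrm <= atol;
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["converged"] = converged, _["resid"] = nrm,
                      _["iter"] = iter, _["diverged"] = diverged);
}
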