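// Branched cable equation on a tree of cylindrical compartments.
//
// Implicit (backward Euler) update per fixed time step: gating variables are
// advanced first with the exponential integrator at the current voltage, the
// resulting linear tree system for the next voltage is then solved in one
// O(n) Hines pass. Compartments are required in Hines order (parent index <
// child index, root = -1), which the R-side graph compiler guarantees.
//
// Units: mV, ms, nA, uS, nF. Conductances and capacitances arrive already
// multiplied by compartment membrane area.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1) with the removable singularity at x = 0 filled in
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / (2.0 * y));
  return x / (std::exp(x / y) - 1.0);
}

struct Rates {
  double am, bm, ah, bh, an, bn;
};

// Traub-style Na/K kinetics with an adjustable voltage origin vT.
static inline void hh_rates(double v, double vT, Rates &r) {
  double u = v - vT;
  r.am = 0.32 * vtrap(13.0 - u, 4.0);
  r.bm = 0.28 * vtrap(u - 40.0, 5.0);
  r.ah = 0.128 * std::exp((17.0 - u) / 18.0);
  r.bh = 4.0 / (1.0 + std::exp((40.0 - u) / 5.0));
  r.an = 0.032 * vtrap(15.0 - u, 5.0);
  r.bn = 0.5 * std::exp((10.0 - u) / 40.0);
}

static inline void gate_update(double &x, double a, double b, double dt,
                               double rate_scale) {
  double s = (a + b) * rate_scale;
  double xinf = a / (a + b);
  x += (xinf - x) * (1.0 - std::exp(-dt * s));
}

// [[Rcpp::export]]
List cable_simulate(IntegerVector parent, NumericVector g_axial,
                    NumericVector cm, NumericVector g_pas,
                    NumericVector e_pas, NumericVector gna, NumericVector gk,
                    NumericVector na_shift, double ena, double ek, double vT,
                    bool shift_h, double rate_scale, double dt, int nsteps,
                    double v_init, IntegerVector rec,
                    IntegerVector step_comp, NumericVector step_amp,
                    NumericVector step_t0, NumericVector step_t1,
                    IntegerVector syn_comp, NumericVector syn_w,
                    NumericVector syn_onset, double tau_on, double tau_off,
                    double e_syn) {
  const int n = parent.size();
  const int nrec = rec.size();
  std::vector<double> v(n, v_init), m(n), h(n), nn(n);
  std::vector<double> d(n), rhs(n);

  // gating steady state at v_init
  for (int i = 0; i < n; ++i) {
    if (gna[i] > 0 || gk[i] > 0) {
      Rates r;
      hh_rates(v_init - na_shift[i], vT, r);
      m[i] = r.am / (r.am + r.bm);
      double vh = shift_h ? v_init - na_shift[i] : v_init;
      hh_rates(vh, vT, r);
      h[i] = r.ah / (r.ah + r.bh);
      hh_rates(v_init, vT, r);
      nn[i] = r.an / (r.an + r.bn);
    }
  }

  // synapse bookkeeping: double-exponential conductance advanced by exact
  // per-step decay of its two states; onsets snap to the step grid
  const int nsyn = syn_comp.size();
  std::vector<double> syn_off(n, 0.0), syn_on(n, 0.0);
  std::vector<std::vector<std::pair<int, double> > > syn_events(nsteps + 1);
  double norm = 1.0;
  if (nsyn > 0) {
    double tp = tau_on * tau_off / (tau_off - tau_on) *
                std::log(tau_off / tau_on);
    norm = std::exp(-tp / tau_off) - std::exp(-tp / tau_on);
    for (int s = 0; s < nsyn; ++s) {
      int step = (int)std::lround(syn_onset[s] / dt);
      if (step < 0) step = 0;
      if (step <= nsteps)
        syn_events[step].push_back(std::make_pair(syn_comp[s],
                                                  syn_w[s] / norm));
    }
  }
  const double doff = std::exp(-dt / tau_off);
  const double don = std::exp(-dt / tau_on);

  NumericMatrix traces(nsteps + 1, nrec);
  NumericVector times(nsteps + 1);
  for (int j = 0; j < nrec; ++j) traces(0, j) = v[rec[j]];

  const int nstep_inj = step_comp.size();

  for (int it = 1; it <= nsteps; ++it) {
    const double t = it * dt;

    // 1) gating advance at v(t - dt)
    for (int i = 0; i < n; ++i) {
      if (gna[i] > 0 || gk[i] > 0) {
        Rates r;
        hh_rates(v[i] - na_shift[i], vT, r);
        gate_update(m[i], r.am, r.bm, dt, rate_scale);
        double vh = shift_h ? v[i] - na_shift[i] : v[i];
        hh_rates(vh, vT, r);
        gate_update(h[i], r.ah, r.bh, dt, rate_scale);
        hh_rates(v[i], vT, r);
        gate_update(nn[i], r.an, r.bn, dt, rate_scale);
      }
    }

    // 2) assemble diagonal and right-hand side
    for (int i = 0; i < n; ++i) {
      double cdt = cm[i] / dt;
      double di = cdt + g_pas[i];
      double ri = cdt * v[i] + g_pas[i] * e_pas[i];
      if (gna[i] > 0) {
        double g = gna[i] * m[i] * m[i] * m[i] * h[i];
        di += g;
        ri += g * ena;
      }
      if (gk[i] > 0) {
        double g = gk[i] * nn[i] * nn[i] * nn[i] * nn[i];
        di += g;
        ri += g * ek;
      }
      d[i] = di;
      rhs[i] = ri;
    }
    // axial couplings on both sides of each parent-child edge
    for (int i = 1; i < n; ++i) {
      d[i] += g_axial[i];
      d[parent[i]] += g_axial[i];
    }

    // 3) synaptic conductances (implicit in V)
    if (nsyn > 0) {
      for (int i = 0; i < n; ++i) {
        if (syn_off[i] != 0.0 || syn_on[i] != 0.0) {
          syn_off[i] *= doff;
          syn_on[i] *= don;
        }
      }
      const std::vector<std::pair<int, double> > &ev = syn_events[it];
      for (size_t s = 0; s < ev.size(); ++s) {
        syn_off[ev[s].first] += ev[s].second;
        syn_on[ev[s].first] += ev[s].second;
      }
      for (int i = 0; i < n; ++i) {
        double g = syn_off[i] - syn_on[i];
        if (g > 0) {
          d[i] += g;
          rhs[i] += g * e_syn;
        }
      }
    }

    // 4) current steps (active on (t0, t1])
    for (int s = 0; s < nstep_inj; ++s) {
      if (t > step_t0[s] + 1e-12 && t <= step_t1[s] + 1e-12)
        rhs[step_comp[s]] += step_amp[s];
    }

    // 5) Hines solve: eliminate leaves-to-root, back-substitute
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = g_axial[i] / d[i];
      d[p] -= f * g_axial[i];
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + g_axial[i] * v[parent[i]]) / d[i];

    if (!std::isfinite(v[0]) || v[0] < -200.0 || v[0] > 200.0)
      stop("cable solver diverged at step %d (t = %.4f ms)", it, t);

    times[it] = t;
    for (int j = 0; j < nrec; ++j) traces(it, j) = v[rec[j]];
  }

  return List::create(Named("t") = times, Named("v") = traces);
}
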