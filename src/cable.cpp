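// Branched-cable Hodgkin-Huxley integrator.
//
// Compartments are Hines-ordered (parent index < child index) so the
// symmetric quasi-tridiagonal system of the implicit voltage update is
// solved exactly in O(n) per step. Gating variables follow first-order
// Hodgkin-Huxley kinetics advanced with the Rush-Larsen exponential update
// (steady states and update factors pretabulated on a 0.05 mV grid and
// linearly interpolated); the voltage step is backward Euler or staggered
// Crank-Nicolson. Units: mV, ms, uS, nF, nA, mM; geometry enters only
// through the precomputed absolute capacitances/conductances.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double V_LO = -130.0, V_HI = 70.0, V_STEP = 0.05;
static const int N_TAB = (int)((V_HI - V_LO) / V_STEP) + 2;

struct GateTab {
  bool ca_gate = false;
  int expo = 1;
  std::vector<double> inf, fac;          // voltage tables
  double ca_kd = 3.5e-4, ca_hill = 4, ca_fac = 0;  // calcium gate
  inline void build(const List& g, double dt) {
    expo = as<int>(g["expo"]);
    std::string type = as<std::string>(g["type"]);
    if (type == "calcium") {
      ca_gate = true;
      ca_kd = as<double>(g["kd"]);
      ca_hill = as<double>(g["hill"]);
      ca_fac = -std::expm1(-dt / as<double>(g["tau"]));
      return;
    }
    const double vhalf = as<double>(g["vhalf"]), k = as<double>(g["k"]);
    const double tb = as<double>(g["tau_base"]), ta = as<double>(g["tau_amp"]);
    const double tv = as<double>(g["tau_vmax"]);
    const double s1 = as<double>(g["tau_sig1"]), s2 = as<double>(g["tau_sig2"]);
    inf.resize(N_TAB); fac.resize(N_TAB);
    for (int j = 0; j < N_TAB; ++j) {
      const double v = V_LO + j * V_STEP;
      inf[j] = 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
      double tau = tb + ta / (std::exp((v - tv) / s1) +
                              std::exp(-(v - tv) / s2));
      if (tau < 1e-4) tau = 1e-4;
      fac[j] = -std::expm1(-dt / tau);
    }
  }
  inline double inf_ca(double ca) const {
    const double c = std::pow(ca / ca_kd, ca_hill);
    return c / (1.0 + c);
  }
};

static inline double tab_at(const std::vector<double>& t, double v) {
  double x = (v - V_LO) / V_STEP;
  if (x < 0) x = 0;
  if (x > N_TAB - 2) x = N_TAB - 2;
  const int j = (int)x;
  const double f = x - j;
  return t[j] + f * (t[j + 1] - t[j]);
}

static inline double gpow(double a, int expo) {
  switch (expo) {
    case 1: return a;
    case 2: return a * a;
    case 3: return a * a * a;
    case 4: { const double a2 = a * a; return a2 * a2; }
    default: return std::pow(a, expo);
  }
}

// [[Rcpp::export(name = ".cable_integrate")]]
List cable_integrate(IntegerVector parent,      // 0-based, -1 root
                     NumericVector c_nF,
                     NumericVector g_axial_uS,  // to parent; 0 for root
                     NumericMatrix g_chan_uS,   // ncomp x nchan, absolute
                     List channels,             // channel kinetic specs
                     NumericVector volume_um3,
                     List config) {
  const int n = parent.size();
  const int nc = channels.size();
  const double dt = as<double>(config["dt"]);
  const double duration = as<double>(config["duration"]);
  const double v_init = as<double>(config["v_init"]);
  const double ca_rest = as<double>(config["ca_rest"]);
  const double ca_tau = as<double>(config["ca_tau"]);
  const double ca_influx = as<double>(config["ca_influx_scale"]);
  const bool cn = as<std::string>(config["method"]) == "cn";
  IntegerVector record_idx = config["record_idx"];   // 0-based
  const int rec_every = as<int>(config["record_every"]);
  const bool record_ca = as<bool>(config["record_ca"]);

  std::vector<int> stim_comp; std::vector<double> stim_amp, stim_t0, stim_t1;
  if (config.containsElementNamed("stimuli")) {
    List st = config["stimuli"];
    for (int i = 0; i < st.size(); ++i) {
      List s = st[i];
      stim_comp.push_back(as<int>(s["comp"]));
      stim_amp.push_back(as<double>(s["amp_nA"]));
      stim_t0.push_back(as<double>(s["t0"]));
      stim_t1.push_back(as<double>(s["t1"]));
    }
  }

  // channel tables + active-compartment lists (conductances are constant)
  struct Chan {
    double erev = 0; bool ca_source = false;
    bool has_act = false, has_inact = false;
    GateTab act, inact;
    std::vector<int> idx;        // compartments with nonzero density
    std::vector<double> g;       // absolute conductance there, uS
    std::vector<double> a, h;    // gate states on idx
  };
  std::vector<Chan> ch(nc);
  double eca = 60.0;
  for (int c = 0; c < nc; ++c) {
    List spec = channels[c];
    ch[c].erev = as<double>(spec["erev"]);
    ch[c].ca_source = as<bool>(spec["ca_source"]);
    if (ch[c].ca_source) eca = ch[c].erev;
    if (spec.containsElementNamed("act") && !Rf_isNull(spec["act"])) {
      ch[c].has_act = true;
      ch[c].act.build(spec["act"], dt);
    }
    if (spec.containsElementNamed("inact") && !Rf_isNull(spec["inact"])) {
      ch[c].has_inact = true;
      ch[c].inact.build(spec["inact"], dt);
    }
    for (int i = 0; i < n; ++i) {
      if (g_chan_uS(i, c) > 0) {
        ch[c].idx.push_back(i);
        ch[c].g.push_back(g_chan_uS(i, c));
      }
    }
  }

  const int n_steps = (int)std::llround(duration / dt);
  const int n_rec = n_steps / rec_every + 1;
  const int n_sites = record_idx.size();
  NumericMatrix v_out(n_rec, n_sites);
  NumericMatrix ca_out(record_ca ? n_rec : 1, record_ca ? n_sites : 1);

  std::vector<double> v(n, v_init), ca(n, ca_rest);
  for (int c = 0; c < nc; ++c) {
    const size_t m = ch[c].idx.size();
    if (ch[c].has_act) {
      ch[c].a.resize(m);
      for (size_t j = 0; j < m; ++j)
        ch[c].a[j] = ch[c].act.ca_gate
          ? ch[c].act.inf_ca(ca[ch[c].idx[j]])
          : tab_at(ch[c].act.inf, v_init);
    }
    if (ch[c].has_inact)
      ch[c].h.assign(m, tab_at(ch[c].inact.inf, v_init));
  }

  std::vector<double> diag(n), rhs(n), off(n, 0.0), gsum(n), gesum(n),
      gca(n), vtmp(n);
  const double ca_f = -std::expm1(-dt / ca_tau);

  for (int s = 0; s < n_sites; ++s) v_out(0, s) = v[record_idx[s]];
  if (record_ca)
    for (int s = 0; s < n_sites; ++s) ca_out(0, s) = ca[record_idx[s]];

  for (int step = 1; step <= n_steps; ++step) {
    const double t = step * dt;
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);
    std::fill(gca.begin(), gca.end(), 0.0);

    // 1. advance gates (Rush-Larsen; staggered half-step states under CN)
    //    and accumulate membrane conductances
    for (int c = 0; c < nc; ++c) {
      Chan& C = ch[c];
      const size_t m = C.idx.size();
      if (!m) continue;
      if (C.has_act) {
        if (C.act.ca_gate) {
          for (size_t j = 0; j < m; ++j)
            C.a[j] += C.act.ca_fac * (C.act.inf_ca(ca[C.idx[j]]) - C.a[j]);
        } else {
          for (size_t j = 0; j < m; ++j) {
            const double vi = v[C.idx[j]];
            C.a[j] += tab_at(C.act.fac, vi) *
              (tab_at(C.act.inf, vi) - C.a[j]);
          }
        }
      }
      if (C.has_inact) {
        for (size_t j = 0; j < m; ++j) {
          const double vi = v[C.idx[j]];
          C.h[j] += tab_at(C.inact.fac, vi) *
            (tab_at(C.inact.inf, vi) - C.h[j]);
        }
      }
      for (size_t j = 0; j < m; ++j) {
        double gabs = C.g[j];
        if (C.has_act) gabs *= gpow(C.a[j], C.act.expo);
        if (C.has_inact) gabs *= C.h[j];
        const int i = C.idx[j];
        gsum[i] += gabs;
        gesum[i] += gabs * C.erev;
        if (C.ca_source) gca[i] += gabs;
      }
    }

    // 2. implicit voltage solve on the tree
    for (int i = 0; i < n; ++i) {
      const double cdt = c_nF[i] / dt;
      if (cn) {
        diag[i] = cdt + 0.5 * gsum[i];
        rhs[i] = (cdt - 0.5 * gsum[i]) * v[i] + gesum[i];
      } else {
        diag[i] = cdt + gsum[i];
        rhs[i] = cdt * v[i] + gesum[i];
      }
    }
    for (size_t s = 0; s < stim_comp.size(); ++s)
      if (t > stim_t0[s] && t <= stim_t1[s]) rhs[stim_comp[s]] += stim_amp[s];
    for (int i = 1; i < n; ++i) {
      const double gax = g_axial_uS[i];
      if (gax <= 0) continue;
      const int p = parent[i];
      if (cn) {
        diag[i] += 0.5 * gax; diag[p] += 0.5 * gax;
        rhs[i] += 0.5 * gax * (v[p] - v[i]);
        rhs[p] += 0.5 * gax * (v[i] - v[p]);
        off[i] = -0.5 * gax;
      } else {
        diag[i] += gax; diag[p] += gax;
        off[i] = -gax;
      }
    }
    for (int i = n - 1; i >= 1; --i) {
      if (g_axial_uS[i] <= 0) continue;
      const double f = off[i] / diag[i];
      diag[parent[i]] -= f * off[i];
      rhs[parent[i]] -= f * rhs[i];
    }
    vtmp[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      vtmp[i] = g_axial_uS[i] > 0
        ? (rhs[i] - off[i] * vtmp[parent[i]]) / diag[i]
        : rhs[i] / diag[i];
    std::copy(vtmp.begin(), vtmp.end(), v.begin());

    // 3. calcium update (exponential relaxation toward influx-shifted rest)
    for (int i = 0; i < n; ++i) {
      double target = ca_rest;
      if (gca[i] > 0 && volume_um3[i] > 0)
        target -= ca_influx * 5.1821 * gca[i] * (v[i] - eca) * ca_tau /
          volume_um3[i];
      ca[i] += ca_f * (target - ca[i]);
      if (ca[i] < 1e-9) ca[i] = 1e-9;
    }

    if (!std::isfinite(v[0]))
      stop("numerical failure at t = %.3f ms (compartment 1)", t);

    if (step % rec_every == 0) {
      const int r = step / rec_every;
      for (int s = 0; s < n_sites; ++s) {
        v_out(r, s) = v[record_idx[s]];
        if (!std::isfinite(v_out(r, s)))
          stop("numerical failure at t = %.3f ms (compartment %d)",
               t, record_idx[s] + 1);
      }
      if (record_ca)
        for (int s = 0; s < n_sites; ++s) ca_out(r, s) = ca[record_idx[s]];
    }
  }

  List out = List::create(_["v"] = v_out,
                          _["dt"] = dt * rec_every,
                          _["duration"] = duration);
  if (record_ca) out["ca"] = ca_out;
  return out;
}
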