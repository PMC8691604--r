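// Multicompartment membrane integrator.
//
// Backward-Euler tree solve (Hines ordering) for the voltages, Rush-Larsen
// exponential updates for gating states, event-driven difference-of-
// exponentials synapses, per-compartment extracellular potential offsets for
// quasi-uniform field coupling, and selective membrane-bias manipulations.
//
// Units: mV, ms, nA, uS, uF, cm^2. Extracellular offsets arrive precomputed
// in mV. Conductances arrive as total uS per compartment (densities are
// resolved on the R side).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>
using namespace Rcpp;

namespace {

struct Gate {
  int type;      // 0 = voltage gate, 1 = calcium gate
  double p;      // power
  double vh, k;  // Boltzmann midpoint/slope, or (Kd, hill) for Ca gates
  int tauform;   // 0 constant, 1 bell
  double tau0, amp, vd, s1, s2;
};

struct Chan {
  double erev;
  int ion;              // 0 none, 1/2 -> Ca pool index
  int capool;           // pool whose concentration Ca gates read (1-based, 0 none)
  std::vector<int> comps;      // active compartments (0-based)
  std::vector<double> gbar;    // uS, aligned with comps
  std::vector<Gate> gates;
  std::vector<double> state;   // gate-major: state[g * ncomp + i]
  double gate_bias;            // channel-scope bias (mV), gating argument only
  double qt;                   // rate scale: tau / qt
};

struct SynGroup {
  int comp;
  double g;     // uS per event unit (already includes per-synapse gmax)
  double e;     // reversal (mV)
  double tau1, tau2, A;
  double da, db;                 // per-step decay factors
  std::vector<int> ev_steps;     // sorted event step indices
  size_t ptr;
  double a, b;
};

inline double gate_inf(const Gate& g, double v) {
  return 1.0 / (1.0 + std::exp(-(v - g.vh) / g.k));
}

inline double gate_tau(const Gate& g, double v) {
  if (g.tauform == 0) return g.tau0;
  return g.tau0 + g.amp / (std::exp((v - g.vd) / g.s1) + std::exp(-(v - g.vd) / g.s2));
}

inline double ca_inf(const Gate& g, double c) {
  double num = std::pow(c, g.k);
  return num / (num + std::pow(g.vh, g.k));
}

} // namespace

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(List net, List stimuli, double duration, double dt,
                NumericVector v_init, double field_onset, double field_offset,
                IntegerVector record_comps, int record_every,
                bool record_currents, int current_comp,
                bool record_pools) {
  const int n = as<int>(net["n"]);
  IntegerVector parent = net["parent"];           // -1 for root, 0-based
  NumericVector ga = net["g_axial"];              // uS to parent
  NumericVector cm = net["cm"];                   // nF total per comp (nF/ms = uS)
  NumericVector gl = net["g_leak"];               // uS total per comp
  NumericVector el = net["e_leak"];
  NumericVector ve = net["ve"];                   // mV offset per comp (field on)
  NumericVector bias_comp = net["bias_comp"];     // mV compartment-scope bias

  // --- channels ---------------------------------------------------------
  List chlist = net["channels"];
  const int nch = chlist.size();
  std::vector<Chan> chans(nch);
  for (int c = 0; c < nch; ++c) {
    List cl = chlist[c];
    Chan& ch = chans[c];
    ch.erev = as<double>(cl["erev"]);
    ch.ion = as<int>(cl["ion"]);
    ch.capool = as<int>(cl["capool"]);
    ch.gate_bias = as<double>(cl["gate_bias"]);
    ch.qt = as<double>(cl["qt"]);
    IntegerVector cc = cl["comps"];
    NumericVector gb = cl["gbar"];
    ch.comps.assign(cc.begin(), cc.end());
    ch.gbar.assign(gb.begin(), gb.end());
    List gts = cl["gates"];
    for (int g = 0; g < gts.size(); ++g) {
      List gl2 = gts[g];
      Gate gt;
      gt.type = as<int>(gl2["type"]);
      gt.p = as<double>(gl2["p"]);
      gt.vh = as<double>(gl2["vh"]);
      gt.k = as<double>(gl2["k"]);
      gt.tauform = as<int>(gl2["tauform"]);
      gt.tau0 = as<double>(gl2["tau0"]);
      gt.amp = as<double>(gl2["amp"]);
      gt.vd = as<double>(gl2["vd"]);
      gt.s1 = as<double>(gl2["s1"]);
      gt.s2 = as<double>(gl2["s2"]);
      ch.gates.push_back(gt);
    }
    ch.state.resize(ch.gates.size() * ch.comps.size());
  }

  // --- calcium pools ----------------------------------------------------
  List pools = net["pools"];
  const int npool = pools.size();
  std::vector<double> pool_tau(npool), pool_k(npool), pool_c0(npool);
  for (int p = 0; p < npool; ++p) {
    List pl = pools[p];
    pool_tau[p] = as<double>(pl["tau"]);
    pool_k[p] = as<double>(pl["k"]);
    pool_c0[p] = as<double>(pl["c0"]);
  }
  NumericVector area = net["area"]; // cm^2
  std::vector< std::vector<double> > ca(npool, std::vector<double>(n));
  for (int p = 0; p < npool; ++p)
    std::fill(ca[p].begin(), ca[p].end(), pool_c0[p]);
  std::vector< std::vector<double> > ica(npool, std::vector<double>(n, 0.0));

  // --- synapse groups ---------------------------------------------------
  List syl = stimuli["synapses"];
  const int nsy = syl.size();
  std::vector<SynGroup> syn(nsy);
  for (int s = 0; s < nsy; ++s) {
    List sl = syl[s];
    SynGroup& sg = syn[s];
    sg.comp = as<int>(sl["comp"]);
    sg.g = as<double>(sl["g"]);
    sg.e = as<double>(sl["e"]);
    sg.tau1 = as<double>(sl["tau1"]);
    sg.tau2 = as<double>(sl["tau2"]);
    sg.A = as<double>(sl["A"]);
    IntegerVector ev = sl["ev_steps"];
    sg.ev_steps.assign(ev.begin(), ev.end());
    sg.ptr = 0;
    sg.a = sg.b = 0.0;
    sg.da = std::exp(-dt / sg.tau1);
    sg.db = std::exp(-dt / sg.tau2);
  }

  // --- current injections ----------------------------------------------
  NumericMatrix inj = stimuli["injections"]; // comp(0-based), t0, t1, amp
  const int ninj = inj.nrow();

  // --- recording --------------------------------------------------------
  const int nsteps = (int) std::lround(duration / dt);
  const int nrec = (nsteps / record_every) + 1;
  const int nrc = record_comps.size();
  NumericMatrix vout(nrec, nrc);
  NumericVector tout(nrec);
  NumericMatrix iout;  // per-channel currents (densities mA/cm^2) at one comp
  if (record_currents) iout = NumericMatrix(nrec, nch + 1); // + leak
  NumericMatrix pout;
  if (record_pools) pout = NumericMatrix(nrec, npool);

  // --- state ------------------------------------------------------------
  std::vector<double> v(n);
  for (int i = 0; i < n; ++i)
    v[i] = (v_init.size() == 1) ? v_init[0] : v_init[i];

  // initialise gates at v_init (+bias), pools at c0
  for (auto& ch : chans) {
    const size_t m = ch.comps.size();
    for (size_t i = 0; i < m; ++i) {
      double vv = v[ch.comps[i]] + bias_comp[ch.comps[i]] + ch.gate_bias;
      for (size_t g = 0; g < ch.gates.size(); ++g) {
        const Gate& gt = ch.gates[g];
        ch.state[g * m + i] = (gt.type == 0) ? gate_inf(gt, vv)
                                             : ca_inf(gt, pool_c0[ch.capool - 1]);
      }
    }
  }

  std::vector<double> gsum(n), gesum(n), rhs(n), diag(n), vprev(n);
  std::vector<double> gchan_now; // per active comp scratch

  int rec_i = 0;
  // record initial state
  tout[0] = 0.0;
  for (int j = 0; j < nrc; ++j) vout(0, j) = v[record_comps[j]];
  if (record_currents) for (int c = 0; c <= nch; ++c) iout(0, c) = 0.0;
  if (record_pools) for (int p = 0; p < npool; ++p) pout(0, p) = ca[p][current_comp];
  rec_i = 1;

  const int check_every = std::max(1, (int) std::lround(1.0 / dt));

  for (int s = 0; s < nsteps; ++s) {
    const double tnew = (s + 1) * dt;
    const bool field_on = (tnew >= field_onset && tnew < field_offset);

    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);
    for (int p = 0; p < npool; ++p)
      std::fill(ica[p].begin(), ica[p].end(), 0.0);

    // synapses: decay + events landing on this step
    for (auto& sg : syn) {
      sg.a *= sg.da;
      sg.b *= sg.db;
      while (sg.ptr < sg.ev_steps.size() && sg.ev_steps[sg.ptr] == s + 1) {
        sg.a += 1.0; sg.b += 1.0; ++sg.ptr;
      }
      double gs = sg.g * sg.A * (sg.b - sg.a);
      if (gs > 1e-14) {
        gsum[sg.comp] += gs;
        gesum[sg.comp] += gs * sg.e;
      }
    }

    // gating update + conductance accumulation
    for (int c = 0; c < nch; ++c) {
      Chan& ch = chans[c];
      const size_t m = ch.comps.size();
      const size_t ng = ch.gates.size();
      double icur_rec = 0.0;
      for (size_t i = 0; i < m; ++i) {
        const int cp = ch.comps[i];
        const double vg = v[cp] + bias_comp[cp] + ch.gate_bias;
        double gprod = ch.gbar[i];
        for (size_t g = 0; g < ng; ++g) {
          const Gate& gt = ch.gates[g];
          double x = ch.state[g * m + i];
          if (gt.type == 0) {
            const double xi = gate_inf(gt, vg);
            const double tau = gate_tau(gt, vg) / ch.qt;
            x += (xi - x) * (1.0 - std::exp(-dt / tau));
          } else {
            const double xi = ca_inf(gt, ca[ch.capool - 1][cp]);
            const double tau = gt.tau0 / ch.qt;
            x += (xi - x) * (1.0 - std::exp(-dt / tau));
          }
          ch.state[g * m + i] = x;
          if (gt.p == 1.0) gprod *= x;
          else if (gt.p == 2.0) gprod *= x * x;
          else if (gt.p == 3.0) gprod *= x * x * x;
          else if (gt.p == 4.0) gprod *= x * x * x * x;
          else gprod *= std::pow(x, gt.p);
        }
        gsum[cp] += gprod;
        gesum[cp] += gprod * (ch.erev - bias_comp[cp]);
        // Ca influx bookkeeping uses the pre-solve voltage (explicit)
        if (ch.ion > 0) {
          double icur = gprod * (v[cp] + bias_comp[cp] - ch.erev); // nA
          ica[ch.ion - 1][cp] += icur;
        }
      }
      (void) icur_rec;
    }

    // assemble
    for (int i = 0; i < n; ++i) {
      const double cdt = cm[i] / dt;
      diag[i] = cdt + gl[i] + gsum[i];
      rhs[i] = cdt * v[i] + gl[i] * (el[i] - bias_comp[i]) + gesum[i];
    }
    for (int i = 1; i < n; ++i) {
      const int p = parent[i];
      diag[i] += ga[i];
      diag[p] += ga[i];
      if (field_on) {
        const double dve = ve[p] - ve[i];
        rhs[i] += ga[i] * dve;
        rhs[p] -= ga[i] * dve;
      }
    }
    for (int k = 0; k < ninj; ++k) {
      if (tnew >= inj(k, 1) && tnew < inj(k, 2)) rhs[(int) inj(k, 0)] += inj(k, 3);
    }

    // Hines solve (parent[i] < i guaranteed)
    for (int i = n - 1; i >= 1; --i) {
      const int p = parent[i];
      const double f = ga[i] / diag[i];
      diag[p] -= f * ga[i];
      rhs[p] += f * rhs[i];
    }
    vprev.swap(v);
    v.resize(n);
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + ga[i] * v[parent[i]]) / diag[i];

    // pools (explicit ICa from pre-solve voltage)
    for (int p = 0; p < npool; ++p) {
      const double tau = pool_tau[p];
      for (int i = 0; i < n; ++i) {
        if (ica[p][i] != 0.0 || ca[p][i] != pool_c0[p]) {
          double dc = -pool_k[p] * ica[p][i] / area[i] * 1e-6 // mA/cm^2 drive
                      - (ca[p][i] - pool_c0[p]) / tau;
          ca[p][i] += dt * dc;
          if (ca[p][i] < 0.0) ca[p][i] = 0.0;
        }
      }
    }

    // divergence check
    if ((s + 1) % check_every == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(v[i]) || std::fabs(v[i]) > 200.0) {
          stop("integration failure: |V| > 200 mV at t = %.3f ms (compartment %d)",
               tnew, i + 1);
        }
      }
    }

    // record
    if ((s + 1) % record_every == 0) {
      tout[rec_i] = tnew;
      for (int j = 0; j < nrc; ++j) vout(rec_i, j) = v[record_comps[j]];
      if (record_currents) {
        const int cp = current_comp;
        const double a = area[cp];
        for (int c = 0; c < nch; ++c) {
          Chan& ch = chans[c];
          double gtot = 0.0;
          const size_t m = ch.comps.size();
          for (size_t i = 0; i < m; ++i) {
            if (ch.comps[i] != cp) continue;
            double gprod = ch.gbar[i];
            for (size_t g = 0; g < ch.gates.size(); ++g) {
              const Gate& gt = ch.gates[g];
              gprod *= std::pow(ch.state[g * m + i], gt.p);
            }
            gtot += gprod;
          }
          // nA -> mA, / cm^2
          iout(rec_i, c) = gtot * (v[cp] + bias_comp[cp] - ch.erev) * 1e-6 / a;
        }
        iout(rec_i, nch) = gl[cp] * (v[cp] + bias_comp[cp] - el[cp]) * 1e-6 / a;
      }
      if (record_pools)
        for (int p = 0; p < npool; ++p) pout(rec_i, p) = ca[p][current_comp];
      ++rec_i;
    }
  }

  NumericVector vfin(n), vdrift(n);
  for (int i = 0; i < n; ++i) {
    vfin[i] = v[i];
    vdrift[i] = (v[i] - vprev[i]) / dt;
  }

  List out = List::create(
    _["time"] = tout,
    _["v"] = vout,
    _["v_final"] = vfin,
    _["v_drift"] = vdrift);
  if (record_currents) out["currents"] = iout;
  if (record_pools) out["pools"] = pout;
  return out;
}
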