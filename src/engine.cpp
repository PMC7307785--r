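// Core fixed-step integrator for the multi-compartment chloride-dynamics model.
//
// The morphology is an unbranched chain of cylindrical compartments ordered
//   distal tip -> distal -> proximal -> soma -> axon -> axon tip,
// so the implicit (backward-Euler) voltage step is a single tridiagonal solve.
// Membrane mechanisms (three-ion leak, axonal HH-style Na/K/M channels, KCC2,
// synapses) are evaluated with conductances frozen at the previous step, which
// keeps the update linear in V^{n+1} (staggered scheme).
//
// Units: mV, ms, mM, nA, uS, nF; densities arrive pre-multiplied by area
// (uS per compartment).  Chloride mass balance: outward Cl- current = anion
// influx; dCl[mM/ms] = I_out[nA] * 1e-9 / (F * vol[L]).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic, platform-independent RNG (splitmix64) for the fluctuating
// conductance streams; R's RNG is never touched by the engine.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) + 5.551115123125783e-17;
  }
  bool has_spare = false;
  double spare = 0.0;
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (1.0 - std::exp(-x / y));
}

struct HHRates {
  double am, bm, ah, bh, an, bn;
};

static inline HHRates hh_rates(double v, double na_shift, double k_shift) {
  HHRates r;
  double vn = v - na_shift;
  r.am = 0.1 * vtrap(vn + 40.0, 10.0);
  r.bm = 4.0 * std::exp(-(vn + 65.0) / 18.0);
  r.ah = 0.07 * std::exp(-(vn + 65.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-(vn + 35.0) / 10.0));
  double vk = v - k_shift;
  r.an = 0.01 * vtrap(vk + 55.0, 10.0);
  r.bn = 0.125 * std::exp(-(vk + 65.0) / 80.0);
  return r;
}

static inline void gate_step(double &x, double a, double b, double dt) {
  double tau = 1.0 / (a + b);
  double xinf = a * tau;
  x = xinf + (x - xinf) * std::exp(-dt / tau);
  if (x < 0.0) x = 0.0;
  if (x > 1.0) x = 1.0;
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List geom, List mech, List syn, List gclamp, List inj,
                List modes, List simctl) {
  // ---- geometry ----
  NumericVector area = geom["area_cm2"];
  NumericVector volL = geom["vol_L"];
  NumericVector cm = geom["cm_nF"];
  NumericVector gax = geom["g_axial_uS"];     // length N-1, interface i|i+1
  NumericVector gdiff = geom["g_diff"];       // amount (mM*um3/ms) per mM, length N-1
  NumericVector vol_um3 = geom["vol_um3"];
  IntegerVector is_axon = geom["is_axon"];
  const int N = area.size();

  // ---- mechanisms (conductances already in uS per compartment) ----
  NumericVector gkl = mech["gk_leak_uS"];
  NumericVector gnal = mech["gna_leak_uS"];
  NumericVector gcll = mech["gcl_leak_uS"];
  NumericVector gna = mech["gna_hh_uS"];
  NumericVector gk = mech["gk_hh_uS"];
  NumericVector gm = mech["gm_uS"];
  NumericVector pk_dcl = mech["kcc2_dcl"];    // mM/ms per mM^2 bracket
  NumericVector pk_ina = mech["kcc2_inA"];    // nA per mM^2 bracket
  const double na_shift = as<double>(mech["na_shift"]);
  const double k_shift = as<double>(mech["k_shift"]);
  const double m_vhalf = as<double>(mech["m_vhalf"]);
  const double m_k = as<double>(mech["m_k"]);
  const double m_tau = as<double>(mech["m_tau"]);
  const int k_exp = as<int>(mech["k_exponent"]);
  const bool kcc2_electro = as<bool>(mech["kcc2_electrogenic"]);

  // ---- ions / constants ----
  const double RTF = as<double>(mech["RTF"]);       // mV
  const double Fconst = as<double>(mech["F"]);
  const double Ko = as<double>(mech["Ko"]);
  const double Clo = as<double>(mech["Clo"]);
  const double ENa = as<double>(mech["ENa"]);
  const double EHCO3 = as<double>(mech["EHCO3"]);
  double EK_fixed = as<double>(mech["EK"]);
  NumericVector ki0 = mech["ki0"];                  // per-comp [K+]i (mM)
  NumericVector cl0 = mech["cl0"];                  // per-comp [Cl-]i (mM)

  // ---- event-driven synapses ----
  IntegerVector e_ev_step = syn["e_ev_step"];  // sorted
  IntegerVector e_ev_comp = syn["e_ev_comp"];
  NumericVector e_ev_wA = syn["e_ev_wA"];      // uS added to AMPA states
  NumericVector e_ev_wN = syn["e_ev_wN"];
  const double trA = as<double>(syn["tau_rise_ampa"]);
  const double tdA = as<double>(syn["tau_decay_ampa"]);
  const double trN = as<double>(syn["tau_rise_nmda"]);
  const double tdN = as<double>(syn["tau_decay_nmda"]);
  const double mg = as<double>(syn["mg_mM"]);
  IntegerVector i_syn_comp = syn["i_syn_comp"];     // per inhibitory synapse
  NumericVector i_syn_g = syn["i_syn_gmax_uS"];
  IntegerVector i_ev_step = syn["i_ev_step"];       // sorted
  IntegerVector i_ev_syn = syn["i_ev_syn"];
  const double alpha = as<double>(syn["alpha"]);    // mM^-1 ms^-1
  const double beta = as<double>(syn["beta"]);      // ms^-1
  const double Tmax = as<double>(syn["t_conc"]);    // mM
  const int pulse_steps = as<int>(syn["pulse_steps"]);
  const int nIsyn = i_syn_comp.size();

  // ---- fluctuating conductances ----
  IntegerVector gc_comp = gclamp["comp"];
  NumericVector gc_me = gclamp["mean_e_uS"];
  NumericVector gc_mi = gclamp["mean_i_uS"];
  NumericVector gc_se = gclamp["sd_e_uS"];
  NumericVector gc_si = gclamp["sd_i_uS"];
  const double gc_tau = as<double>(gclamp["tau_ms"]);
  const double gc_seed = as<double>(gclamp["seed"]);
  const int nGC = gc_comp.size();

  // ---- injected currents ----
  IntegerVector ic_comp = inj["comp"];
  NumericVector ic_amp = inj["amp_nA"];
  NumericVector ic_t0 = inj["t0"];
  NumericVector ic_t1 = inj["t1"];
  const int nInj = ic_comp.size();

  // ---- modes ----
  const bool dyn_cl = as<bool>(modes["dynamic_cl"]);
  const bool dyn_k = as<bool>(modes["dynamic_k"]);
  const double e_inh_fixed = as<double>(modes["e_inh_fixed"]); // NaN => Cl/HCO3 split
  const bool use_fixed_inh = !ISNAN(e_inh_fixed);
  NumericVector gpas = modes["gpas_uS"];        // dynamic-K passive leak
  const double e_pas = as<double>(modes["e_pas"]);

  // ---- sim control ----
  const double dt = as<double>(simctl["dt"]);
  const int nsteps = as<int>(simctl["nsteps"]);
  const int rec_every = as<int>(simctl["rec_every"]);
  IntegerVector rec_comps = simctl["rec_comps"]; // 0-based
  const int spike_comp = as<int>(simctl["spike_comp"]);
  const double thresh = as<double>(simctl["spike_threshold"]);
  const double lockout = as<double>(simctl["spike_lockout"]);
  NumericVector v_init = simctl["v_init"];

  // ---- state ----
  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> Cl(cl0.begin(), cl0.end());
  std::vector<double> Ki(ki0.begin(), ki0.end());
  std::vector<double> ECl(N), EGABA(N), EK(N);
  std::vector<double> m(N, 0), h(N, 0), n(N, 0), mM_(N, 0);
  for (int i = 0; i < N; i++) {
    ECl[i] = RTF * std::log(Cl[i] / Clo);
    EGABA[i] = 0.8 * ECl[i] + 0.2 * EHCO3;
    EK[i] = dyn_k ? RTF * std::log(Ko / Ki[i]) : EK_fixed;
    if (is_axon[i]) {
      HHRates r = hh_rates(V[i], na_shift, k_shift);
      m[i] = r.am / (r.am + r.bm);
      h[i] = r.ah / (r.ah + r.bh);
      n[i] = r.an / (r.an + r.bn);
      mM_[i] = 1.0 / (1.0 + std::exp(-(V[i] - m_vhalf) / m_k));
    }
  }
  // tonic fluxes for the dynamic-K rest fixed point (balance KCC2 at init),
  // and a per-compartment passive reversal absorbing the channel currents
  // at the initial voltage so rest is an exact fixed point by construction
  std::vector<double> tonic_cl(N, 0), tonic_k(N, 0), epas(N, e_pas);
  if (dyn_k) {
    for (int i = 0; i < N; i++) {
      double br0 = Ki[i] * Cl[i] - Ko * Clo;
      tonic_cl[i] = pk_dcl[i] * br0;  // mM/ms influx balancing extrusion
      tonic_k[i] = pk_dcl[i] * br0;
      double ihh = 0.0;
      if (is_axon[i]) {
        double nk = (k_exp == 4) ? n[i] * n[i] * n[i] * n[i] : n[i];
        ihh = gna[i] * m[i] * m[i] * m[i] * h[i] * (V[i] - ENa) +
              (gk[i] * nk + gm[i] * mM_[i]) * (V[i] - EK[i]);
      }
      if (gpas[i] > 0) epas[i] = V[i] + ihh / gpas[i];
    }
  }

  // synapse states, aggregated per compartment (linear superposition)
  std::vector<double> aA(N, 0), bA(N, 0), aN(N, 0), bN(N, 0);
  const double fA_r = std::exp(-dt / trA), fA_d = std::exp(-dt / tdA);
  const double fN_r = std::exp(-dt / trN), fN_d = std::exp(-dt / tdN);
  auto peak_norm = [](double tr, double td) {
    double tp = tr * td / (td - tr) * std::log(td / tr);
    return 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  };
  const double normA = peak_norm(trA, tdA), normN = peak_norm(trN, tdN);

  std::vector<double> s_gaba(nIsyn, 0.0);
  std::vector<int> pulse_left(nIsyn, 0);
  const double rate_on = alpha * Tmax + beta;
  const double s_inf_on = alpha * Tmax / rate_on;
  const double f_on = std::exp(-rate_on * dt);
  const double f_off = std::exp(-beta * dt);

  std::vector<double> gce(nGC), gci(nGC);
  for (int j = 0; j < nGC; j++) { gce[j] = gc_me[j]; gci[j] = gc_mi[j]; }
  const double rho = std::exp(-dt / gc_tau);
  const double rup = std::sqrt(1.0 - rho * rho);
  SplitMix rng((uint64_t)gc_seed);

  // tridiagonal workspace
  std::vector<double> dlo(N), dmid(N), dup(N), rhs(N), cp(N), dp(N);

  // recording
  const int nrec = rec_comps.size();
  const int nsamp = nsteps / rec_every + 1;
  NumericMatrix recV(nsamp, nrec), recCl(nsamp, nrec), recEg(nsamp, nrec);
  NumericVector rect(nsamp);
  std::vector<double> spikes;
  double last_spike = -1e9;
  double v_prev_tip = V[spike_comp];
  int samp = 0;
  for (int k = 0; k < nrec; k++) {
    recV(0, k) = V[rec_comps[k]];
    recCl(0, k) = Cl[rec_comps[k]];
    recEg(0, k) = EGABA[rec_comps[k]];
  }
  rect[0] = 0.0;
  samp = 1;

  int e_ptr = 0, i_ptr = 0;
  const int nEev = e_ev_step.size(), nIev = i_ev_step.size();
  int fail_step = -1, fail_comp = -1;

  std::vector<double> gGABA(N, 0.0); // per-comp summed open GABA conductance

  for (int step = 0; step < nsteps; step++) {
    const double t = step * dt;

    // --- synaptic state updates ---
    for (int i = 0; i < N; i++) { aA[i] *= fA_r; bA[i] *= fA_d; aN[i] *= fN_r; bN[i] *= fN_d; }
    while (e_ptr < nEev && e_ev_step[e_ptr] == step) {
      int c = e_ev_comp[e_ptr];
      aA[c] += e_ev_wA[e_ptr]; bA[c] += e_ev_wA[e_ptr];
      aN[c] += e_ev_wN[e_ptr]; bN[c] += e_ev_wN[e_ptr];
      e_ptr++;
    }
    while (i_ptr < nIev && i_ev_step[i_ptr] == step) {
      pulse_left[i_ev_syn[i_ptr]] = pulse_steps;
      i_ptr++;
    }
    std::fill(gGABA.begin(), gGABA.end(), 0.0);
    for (int j = 0; j < nIsyn; j++) {
      if (pulse_left[j] > 0) {
        s_gaba[j] = s_inf_on + (s_gaba[j] - s_inf_on) * f_on;
        pulse_left[j]--;
      } else {
        s_gaba[j] *= f_off;
      }
      gGABA[i_syn_comp[j]] += i_syn_g[j] * s_gaba[j];
    }
    for (int j = 0; j < nGC; j++) {
      if (gc_me[j] > 0 || gc_se[j] > 0) {
        gce[j] = gc_me[j] + (gce[j] - gc_me[j]) * rho + gc_se[j] * rup * rng.norm();
        if (gce[j] < 0) gce[j] = 0;
      }
      if (gc_mi[j] > 0 || gc_si[j] > 0) {
        gci[j] = gc_mi[j] + (gci[j] - gc_mi[j]) * rho + gc_si[j] * rup * rng.norm();
        if (gci[j] < 0) gci[j] = 0;
      }
    }

    // --- assemble and solve the implicit voltage step ---
    for (int i = 0; i < N; i++) {
      double gsum = 0.0, gE = 0.0, Iconst = 0.0;
      if (dyn_k) {
        gsum += gpas[i]; gE += gpas[i] * epas[i];
      } else {
        gsum += gkl[i] + gnal[i] + gcll[i];
        gE += gkl[i] * EK[i] + gnal[i] * ENa + gcll[i] * ECl[i];
      }
      if (is_axon[i]) {
        double gNa_now = gna[i] * m[i] * m[i] * m[i] * h[i];
        double nk = (k_exp == 4) ? n[i] * n[i] * n[i] * n[i] : n[i];
        double gK_now = gk[i] * nk;
        double gM_now = gm[i] * mM_[i];
        gsum += gNa_now + gK_now + gM_now;
        gE += gNa_now * ENa + (gK_now + gM_now) * EK[i];
      }
      // excitatory synapses (reversal 0 mV): add conductance only
      double gexc = normA * (bA[i] - aA[i]);
      double gn = normN * (bN[i] - aN[i]);
      if (gn > 0) gexc += gn / (1.0 + (mg / 3.57) * std::exp(-0.062 * V[i]));
      gsum += gexc; // gE += gexc * 0
      // inhibitory (kinetic scheme), Cl-/HCO3- split or fixed reversal
      if (gGABA[i] > 0) {
        if (use_fixed_inh) {
          gsum += gGABA[i]; gE += gGABA[i] * e_inh_fixed;
        } else {
          gsum += gGABA[i];
          gE += gGABA[i] * (0.8 * ECl[i] + 0.2 * EHCO3);
        }
      }
      // KCC2 as a Cl--carrying current (inward when extruding)
      if (kcc2_electro && !dyn_k) {
        double br = Ki[i] * Cl[i] - Ko * Clo;
        Iconst += -pk_ina[i] * br; // outward-positive convention
      }
      dmid[i] = cm[i] / dt + gsum;
      rhs[i] = cm[i] / dt * V[i] + gE - Iconst;
      dlo[i] = 0.0; dup[i] = 0.0;
    }
    for (int j = 0; j < nGC; j++) {
      int c = gc_comp[j];
      dmid[c] += gce[j] + gci[j];
      if (use_fixed_inh) rhs[c] += gci[j] * e_inh_fixed;
      else rhs[c] += gci[j] * (0.8 * ECl[c] + 0.2 * EHCO3);
      // excitatory reversal 0 mV: no rhs term
    }
    for (int i = 0; i < nInj; i++) {
      if (t >= ic_t0[i] && t < ic_t1[i]) rhs[ic_comp[i]] += ic_amp[i];
    }
    for (int i = 0; i < N - 1; i++) {
      dmid[i] += gax[i]; dmid[i + 1] += gax[i];
      dup[i] = -gax[i]; dlo[i + 1] = -gax[i];
    }
    // Thomas algorithm
    cp[0] = dup[0] / dmid[0]; dp[0] = rhs[0] / dmid[0];
    for (int i = 1; i < N; i++) {
      double mfac = dmid[i] - dlo[i] * cp[i - 1];
      cp[i] = dup[i] / mfac;
      dp[i] = (rhs[i] - dlo[i] * dp[i - 1]) / mfac;
    }
    V[N - 1] = dp[N - 1];
    for (int i = N - 2; i >= 0; i--) V[i] = dp[i] - cp[i] * V[i + 1];

    // --- gating update at the new voltage ---
    for (int i = 0; i < N; i++) {
      if (!is_axon[i]) continue;
      HHRates r = hh_rates(V[i], na_shift, k_shift);
      gate_step(m[i], r.am, r.bm, dt);
      gate_step(h[i], r.ah, r.bh, dt);
      gate_step(n[i], r.an, r.bn, dt);
      double minf = 1.0 / (1.0 + std::exp(-(V[i] - m_vhalf) / m_k));
      mM_[i] = minf + (mM_[i] - minf) * std::exp(-dt / m_tau);
    }

    // --- chloride (and potassium) mass balance ---
    if (dyn_cl) {
      static std::vector<double> dCl_v, dK_v;
      dCl_v.assign(N, 0.0); dK_v.assign(N, 0.0);
      for (int i = 0; i < N; i++) {
        double Icl_out = 0.0; // nA, outward positive (= Cl- influx)
        if (!dyn_k) Icl_out += gcll[i] * (V[i] - ECl[i]);
        if (gGABA[i] > 0 && !use_fixed_inh)
          Icl_out += 0.8 * gGABA[i] * (V[i] - ECl[i]);
        double flux_fac = 1e-9 / (Fconst * volL[i]); // nA -> mM/ms
        dCl_v[i] += Icl_out * flux_fac;
        double br = Ki[i] * Cl[i] - Ko * Clo;
        dCl_v[i] -= pk_dcl[i] * br;          // extrusion
        if (dyn_k) {
          dCl_v[i] += tonic_cl[i];
          dK_v[i] += -pk_dcl[i] * br + tonic_k[i];
        }
      }
      for (int j = 0; j < nGC; j++) {
        int c = gc_comp[j];
        if (!use_fixed_inh && gci[j] > 0) {
          double Icl_out = 0.8 * gci[j] * (V[c] - ECl[c]);
          dCl_v[c] += Icl_out * 1e-9 / (Fconst * volL[c]);
        }
      }
      // conservative longitudinal diffusion (explicit; flux in mM*um3/ms)
      for (int i = 0; i < N - 1; i++) {
        double q = gdiff[i] * (Cl[i + 1] - Cl[i]);
        dCl_v[i] += q / vol_um3[i];
        dCl_v[i + 1] -= q / vol_um3[i + 1];
      }
      for (int i = 0; i < N; i++) {
        Cl[i] += dt * dCl_v[i];
        if (Cl[i] < 1e-3) { fail_step = step; fail_comp = i; break; }
        ECl[i] = RTF * std::log(Cl[i] / Clo);
        EGABA[i] = 0.8 * ECl[i] + 0.2 * EHCO3;
        if (dyn_k) {
          Ki[i] += dt * dK_v[i];
          if (Ki[i] < 1e-3) { fail_step = step; fail_comp = i; break; }
          EK[i] = RTF * std::log(Ko / Ki[i]);
        }
      }
      if (fail_step >= 0) break;
    }

    // --- spike detection ---
    double vt = V[spike_comp];
    if (v_prev_tip < thresh && vt >= thresh && (t + dt) - last_spike >= lockout) {
      spikes.push_back(t + dt);
      last_spike = t + dt;
    }
    v_prev_tip = vt;

    // --- divergence check & recording ---
    if ((step + 1) % rec_every == 0 && samp < nsamp) {
      for (int k = 0; k < nrec; k++) {
        recV(samp, k) = V[rec_comps[k]];
        recCl(samp, k) = Cl[rec_comps[k]];
        recEg(samp, k) = EGABA[rec_comps[k]];
      }
      rect[samp] = t + dt;
      samp++;
    }
    for (int i = 0; i < N; i++) {
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 200.0) {
        fail_step = step; fail_comp = i; break;
      }
    }
    if (fail_step >= 0) break;
  }

  return List::create(
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["t"] = rect,
    _["vm"] = recV,
    _["cl"] = recCl,
    _["egaba"] = recEg,
    _["v_end"] = NumericVector(V.begin(), V.end()),
    _["cl_end"] = NumericVector(Cl.begin(), Cl.end()),
    _["ki_end"] = NumericVector(Ki.begin(), Ki.end()),
    _["fail_step"] = fail_step,
    _["fail_comp"] = fail_comp);
}
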