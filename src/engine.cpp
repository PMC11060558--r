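// Clock-driven simulation core (1-ms resolution).
//
// The engine advances every integrated (non-relay) E-GLIF neuron on a fixed
// 1-ms grid, using exactly the same update order as the R reference
// implementation in step_neuron(), so R and C++ trajectories are replayable
// against each other. Synapses are alpha-shaped conductances realized as a
// two-state linear filter per (neuron, time-constant, reversal) channel;
// spikes are routed through per-delay ring buffers. Relay units (mossy
// fibres, glomeruli) are pure event routers.
//
// Plasticity is applied online. Each plastic (parallel-fibre) synapse keeps
// a pair of exponential traces (P, Q) from which the alpha-kernel
// convolution sum  sum_k K(t - s_k),  K(t) = (t/tau) e^(1 - t/tau),
// is recovered exactly as (e/tau) * (t*P - Q); this is algebraically
// identical to the brute-force sum over all previous pf spikes, with O(1)
// state per synapse. Climbing-fibre (teaching) spikes trigger the gated
// kernel update; pf spikes without a coincident (same-step) teaching spike
// trigger the fixed-size solo update.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// xorshift64* RNG; fast approximate normal via scaled Irwin-Hall(3).
static inline uint64_t xs_next(uint64_t &s) {
  s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
  return s * 0x2545F4914F6CDD1DULL;
}
static inline double xs_unif(uint64_t &s) {
  return (double)(xs_next(s) >> 11) * (1.0 / 9007199254740992.0);
}
static inline double xs_norm(uint64_t &s) {
  return (xs_unif(s) + xs_unif(s) + xs_unif(s) - 1.5) * 2.0;
}
static inline uint64_t mix_seed(uint64_t a, uint64_t b) {
  uint64_t z = a + 0x9E3779B97F4A7C15ULL * (b + 1);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Tonic spike count of one isolated E-GLIF neuron (no synapses, no noise).
// [[Rcpp::export]]
int egif_tonic_count(double C, double tau_m, double E_L, double V_th,
                     double V_r, double t_ref, double Ie, double k_adap,
                     double k2, double k1, double A1, double A2,
                     int n_steps, double dt) {
  double V = V_th - 1e-3, Iadap = 0.0, Idep = 0.0;
  int refr = 0, count = 0;
  const int ref_steps = (int)std::ceil(t_ref / dt);
  for (int i = 0; i < n_steps; ++i) {
    Idep *= (1.0 - k1 * dt);
    Iadap += dt * (k_adap * (V - E_L) - k2 * Iadap);
    if (refr > 0) {
      V = V_r;
      --refr;
    } else {
      V += dt * (-(V - E_L) / tau_m + (Ie + Idep - Iadap) / C);
      if (V >= V_th) {
        V = V_r; Idep = A1; Iadap += A2; refr = ref_steps;
        ++count;
      }
    }
  }
  return count;
}

struct CondEvent { int ch; double amt; };

// [[Rcpp::export]]
List engine_run(List spec, List state, List stim, int n_trials,
                int trial_len, double seed, int trial_offset,
                bool plastic_on) {
  // --- static network description -------------------------------------
  const int n_neurons = as<int>(spec["n_neurons"]);
  IntegerVector is_relay = spec["is_relay"], record = spec["record"];
  NumericVector p_C = spec["C"], p_taum = spec["tau_m"], p_EL = spec["E_L"],
    p_Vth = spec["V_th"], p_Vr = spec["V_r"], p_Ie = spec["Ie"],
    p_kadap = spec["k_adap"], p_k2 = spec["k2"], p_k1 = spec["k1"],
    p_A1 = spec["A1"], p_A2 = spec["A2"], p_noise = spec["noise_sd"];
  IntegerVector ref_steps = spec["ref_steps"];

  IntegerVector ch_ptr = spec["neuron_ch_ptr"];   // length n_neurons+1
  NumericVector ch_E = spec["ch_E"], ch_decay = spec["ch_decay"];
  const int n_channels = ch_E.size();

  IntegerVector syn_ptr = spec["syn_ptr"];        // CSR by presynaptic id
  IntegerVector syn_post = spec["syn_post"], syn_channel = spec["syn_channel"],
    syn_delay = spec["syn_delay"], syn_site = spec["syn_site"],
    syn_is_cf = spec["syn_is_cf"], syn_post_relay = spec["syn_post_relay"];
  NumericVector syn_coef = spec["syn_coef"];

  IntegerVector pl_ptr = spec["plastic_ptr"];     // CSR by postsynaptic id
  IntegerVector pl_idx = spec["plastic_idx"];
  NumericVector w_max = spec["w_max"];

  const double LTP_PC = as<double>(spec["LTP_PC"]);
  const double LTD_PC = as<double>(spec["LTD_PC"]);
  const double LTP_MLI = as<double>(spec["LTP_MLI"]);
  const double LTD_MLI = as<double>(spec["LTD_MLI"]);
  const double tau_pc = as<double>(spec["tau_pc"]);
  const double tau_mli = as<double>(spec["tau_mli"]);

  IntegerVector goc_ids = spec["goc_ids"];
  const double gap_w = as<double>(spec["gap_w"]);
  IntegerVector stim_ch = spec["stim_ch"];        // -1 when absent
  const double stim_coef = as<double>(spec["stim_coef"]);
  const int D = as<int>(spec["max_delay"]) + 1;

  // --- mutable state (updated in place, owned by the R-side runner) ----
  NumericVector V_ = state["V"], Iadap_ = state["Iadap"],
    Idep_ = state["Idep"], ch_g_ = state["ch_g"], ch_h_ = state["ch_h"],
    syn_w_ = state["syn_w"], trP_ = state["trace_P"], trQ_ = state["trace_Q"];
  IntegerVector refr_ = state["refr"], trT_ = state["trace_t"],
    last_cf_ = state["last_cf"];
  double *V = REAL(V_), *Iadap = REAL(Iadap_), *Idep = REAL(Idep_),
    *ch_g = REAL(ch_g_), *ch_h = REAL(ch_h_), *syn_w = REAL(syn_w_),
    *trP = REAL(trP_), *trQ = REAL(trQ_);
  int *refr = INTEGER(refr_), *trT = INTEGER(trT_),
    *last_cf = INTEGER(last_cf_);

  // --- per-call stimulus ------------------------------------------------
  IntegerVector rs_trial = stim["relay_trial"], rs_neuron = stim["relay_neuron"],
    rs_time = stim["relay_time"];
  IntegerVector cs_trial = stim["cond_trial"], cs_neuron = stim["cond_neuron"],
    cs_time = stim["cond_time"];
  NumericVector cs_amt = stim["cond_amt"];

  for (int i = 0; i < rs_neuron.size(); ++i)
    if (rs_neuron[i] < 0 || rs_neuron[i] >= n_neurons)
      stop("relay stimulus neuron index out of range");
  for (int i = 0; i < cs_neuron.size(); ++i)
    if (cs_neuron[i] < 0 || cs_neuron[i] >= n_neurons)
      stop("conductance stimulus neuron index out of range");

  // kernel decay lookup tables on the 1-ms grid
  const int TABN = 4096;
  std::vector<double> dec_pc(TABN), dec_mli(TABN);
  for (int i = 0; i < TABN; ++i) {
    dec_pc[i] = std::exp(-(double)i / tau_pc);
    dec_mli[i] = std::exp(-(double)i / tau_mli);
  }
  const double E1 = std::exp(1.0);

  std::vector< std::vector<CondEvent> > cond_ring(D);
  std::vector< std::vector<int> > teach_ring(D), relay_ring(D),
    plastic_ring(D);
  std::vector<int> spiking;
  spiking.reserve(1024);
  std::vector<double> noise_cache(n_neurons, 0.0);
  std::vector<double> gap_pend(n_neurons, 0.0);

  std::vector<int> out_trial, out_neuron, out_time;

  int rs_i = 0, cs_i = 0;
  const int n_rs = rs_trial.size(), n_cs = cs_trial.size();

  for (int trial = 0; trial < n_trials; ++trial) {
    // trial boundary: the network state (potentials, adaptation, synaptic
    // conductances, weights) carries over; only the trial-local
    // eligibility traces and teaching bookkeeping restart.
    const int n_syn = syn_w_.size();
    for (int s = 0; s < n_syn; ++s) { trP[s] = 0.0; trQ[s] = 0.0; trT[s] = 0; }
    for (int n = 0; n < n_neurons; ++n) last_cf[n] = -1;
    for (int d = 0; d < D; ++d) {
      cond_ring[d].clear(); teach_ring[d].clear();
      relay_ring[d].clear(); plastic_ring[d].clear();
    }
    uint64_t rng = mix_seed((uint64_t)seed, (uint64_t)(trial_offset + trial));

    for (int t = 0; t < trial_len; ++t) {
      const int slot = t % D;

      // 1. teaching (climbing-fibre) arrivals: gate + kernel update
      for (size_t k = 0; k < teach_ring[slot].size(); ++k) {
        const int post = teach_ring[slot][k];
        last_cf[post] = t;
        if (!plastic_on) continue;
        for (int j = pl_ptr[post]; j < pl_ptr[post + 1]; ++j) {
          const int s = pl_idx[j];
          const int site = syn_site[s];             // 1 = pf-PC, 2 = pf-MLI
          const double tau = (site == 1) ? tau_pc : tau_mli;
          const std::vector<double> &dec = (site == 1) ? dec_pc : dec_mli;
          const int dtl = t - trT[s];
          const double f = (dtl < TABN) ? dec[dtl] : 0.0;
          trP[s] *= f; trQ[s] *= f; trT[s] = t;
          const double S = (E1 / tau) * ((double)t * trP[s] - trQ[s]);
          double w = syn_w[s];
          w += (site == 1) ? (-LTD_PC * S) : (LTP_MLI * S);
          if (w < 0.0) w = 0.0;
          if (w > w_max[s]) w = w_max[s];
          syn_w[s] = w;
        }
      }
      teach_ring[slot].clear();

      // 2. parallel-fibre arrivals at plastic synapses
      for (size_t k = 0; k < plastic_ring[slot].size(); ++k) {
        const int s = plastic_ring[slot][k];
        if (!plastic_on) continue;
        const int post = syn_post[s];
        const int site = syn_site[s];
        const std::vector<double> &dec = (site == 1) ? dec_pc : dec_mli;
        const int dtl = t - trT[s];
        const double f = (dtl < TABN) ? dec[dtl] : 0.0;
        trP[s] *= f; trQ[s] *= f; trT[s] = t;
        if (last_cf[post] != t) {                   // no coincident teaching
          double w = syn_w[s];
          w += (site == 1) ? LTP_PC : (-LTD_MLI);
          if (w < 0.0) w = 0.0;
          if (w > w_max[s]) w = w_max[s];
          syn_w[s] = w;
        }
        trP[s] += 1.0; trQ[s] += (double)t;
      }
      plastic_ring[slot].clear();

      // 3. synaptic conductance arrivals
      for (size_t k = 0; k < cond_ring[slot].size(); ++k)
        ch_h[cond_ring[slot][k].ch] += cond_ring[slot][k].amt;
      cond_ring[slot].clear();

      // 4. stimulus: relay (mossy-fibre) spikes and direct conductance input
      while (rs_i < n_rs && rs_trial[rs_i] == trial && rs_time[rs_i] == t) {
        relay_ring[slot].push_back(rs_neuron[rs_i]);
        ++rs_i;
      }
      while (cs_i < n_cs && cs_trial[cs_i] == trial && cs_time[cs_i] == t) {
        const int ch = stim_ch[cs_neuron[cs_i]];
        if (ch >= 0) ch_h[ch] += cs_amt[cs_i] * stim_coef;
        ++cs_i;
      }

      // 5. relay routing (mf -> glom -> targets), may cascade within a step
      for (size_t k = 0; k < relay_ring[slot].size(); ++k) {
        const int n = relay_ring[slot][k];
        if (record[n]) {
          out_trial.push_back(trial); out_neuron.push_back(n);
          out_time.push_back(t);
        }
        for (int s = syn_ptr[n]; s < syn_ptr[n + 1]; ++s) {
          const int arr = t + syn_delay[s];
          if (arr >= trial_len) continue;
          if (syn_post_relay[s]) {
            relay_ring[arr % D].push_back(syn_post[s]);
          } else {
            CondEvent ev;
            ev.ch = syn_channel[s];
            ev.amt = std::fabs(syn_w[s]) * syn_coef[s];
            cond_ring[arr % D].push_back(ev);
          }
        }
      }
      relay_ring[slot].clear();

      // 6. integrate all non-relay neurons
      spiking.clear();
      const bool refresh_noise = (t % 5 == 0);      // 5-ms correlated noise
      for (int n = 0; n < n_neurons; ++n) {
        if (is_relay[n]) continue;
        double Is = 0.0;
        const double Vn = V[n];
        for (int c = ch_ptr[n]; c < ch_ptr[n + 1]; ++c) {
          Is += ch_g[c] * (ch_E[c] - Vn);
          const double d = ch_decay[c];
          ch_g[c] = d * (ch_g[c] + ch_h[c]);
          ch_h[c] *= d;
        }
        if (p_noise[n] > 0.0 && refresh_noise)
          noise_cache[n] = p_noise[n] * xs_norm(rng);
        Idep[n] *= (1.0 - p_k1[n]);
        Iadap[n] += p_kadap[n] * (Vn - p_EL[n]) - p_k2[n] * Iadap[n];
        double v = Vn + gap_pend[n];
        gap_pend[n] = 0.0;
        if (refr[n] > 0) {
          v = p_Vr[n];
          --refr[n];
        } else {
          v += -(v - p_EL[n]) / p_taum[n] +
            (p_Ie[n] + Idep[n] - Iadap[n] + Is + noise_cache[n]) / p_C[n];
          if (v < -95.0) v = -95.0;   // numerical floor: the explicit 1-ms
                                      // step can overshoot E_inh under
                                      // extreme conductance
          if (v >= p_Vth[n]) {
            v = p_Vr[n]; Idep[n] = p_A1[n]; Iadap[n] += p_A2[n];
            refr[n] = ref_steps[n];
            spiking.push_back(n);
          }
        }
        V[n] = v;
      }

      // 7. spike bookkeeping and propagation
      for (size_t k = 0; k < spiking.size(); ++k) {
        const int n = spiking[k];
        if (record[n]) {
          out_trial.push_back(trial); out_neuron.push_back(n);
          out_time.push_back(t);
        }
        for (int s = syn_ptr[n]; s < syn_ptr[n + 1]; ++s) {
          const int arr = t + syn_delay[s];
          if (arr >= trial_len) continue;
          const int slot2 = arr % D;
          if (syn_is_cf[s]) teach_ring[slot2].push_back(syn_post[s]);
          if (syn_site[s] > 0) plastic_ring[slot2].push_back(s);
          CondEvent ev;
          ev.ch = syn_channel[s];
          ev.amt = std::fabs(syn_w[s]) * syn_coef[s];
          cond_ring[slot2].push_back(ev);
        }
      }
      if (gap_w != 0.0) {
        for (size_t k = 0; k < spiking.size(); ++k) {
          const int n = spiking[k];
          bool is_goc = false;
          for (int g = 0; g < goc_ids.size(); ++g)
            if (goc_ids[g] == n) { is_goc = true; break; }
          if (is_goc)
            for (int g = 0; g < goc_ids.size(); ++g)
              if (goc_ids[g] != n) gap_pend[goc_ids[g]] += gap_w;
        }
      }
    }
  }

  return List::create(
    _["trial"] = wrap(out_trial),
    _["neuron"] = wrap(out_neuron),
    _["time"] = wrap(out_time));
}
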