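// Network integration core: single-compartment Hodgkin-Huxley neurons with
// optional persistent sodium current, event-driven exponential synapses,
// tonic drive conductances, and timed photostimulation (Ar/Ch) epochs.
//
// Units: mV, ms, mS/cm^2, uF/cm^2, uA/cm^2.
//
// Update order per step (fixed for reproducibility):
//   1. decay synaptic conductances,
//   2. deliver spikes detected at the previous step (one-step latency),
//   3. evaluate photostimulation conductances for the current time,
//   4. exponential-Euler membrane update with exact gate relaxation,
//   5. threshold-crossing spike detection.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Exact channel kinetics (voltages in mV, times in ms).
inline double mNa_inf(double v)  { return 1.0 / (1.0 + std::exp(-(v + 34.0) / 7.8)); }
inline double hNa_inf(double v)  { return 1.0 / (1.0 + std::exp((v + 55.0) / 7.0)); }
inline double tau_hNa(double v)  {
  return 20.0 / (std::exp((v + 50.0) / 15.0) + std::exp(-(v + 50.0) / 16.0));
}
inline double mNaP_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 47.1) / 3.1)); }
inline double hNaP_inf(double v) { return 1.0 / (1.0 + std::exp((v + 60.0) / 6.5)); }
inline double tau_hNaP(double v) { return 18000.0 / std::cosh((v + 60.0) / 13.0); }
inline double mK_inf(double v)   { return 1.0 / (1.0 + std::exp(-(v + 28.0) / 4.0)); }
inline double tau_mK(double v)   { return 3.5 / std::cosh((v + 40.0) / 40.0); }

// Voltage-indexed lookup table for gate steady states and per-step
// relaxation factors exp(-dt/tau(V)). Grid is fine enough (0.01 mV, linear
// interpolation) that table error is far below integration error. The 8
// per-voltage values are interleaved so one neuron update touches two
// adjacent cache lines instead of eight arrays.
struct GateTables {
  double vmin, vmax, step, inv_step;
  int n;
  std::vector<double> tab; // n rows x 8: mna, hna, hna_dec, mk, mk_dec, mnap, hnap, hnap_dec

  GateTables(double dt) : vmin(-130.0), vmax(70.0), step(0.01) {
    inv_step = 1.0 / step;
    n = (int)std::floor((vmax - vmin) * inv_step) + 1;
    tab.resize((size_t)n * 8);
    for (int i = 0; i < n; ++i) {
      double v = vmin + i * step;
      double *r = &tab[(size_t)i * 8];
      r[0] = mNa_inf(v);
      r[1] = hNa_inf(v);
      r[2] = std::exp(-dt / tau_hNa(v));
      r[3] = mK_inf(v);
      r[4] = std::exp(-dt / tau_mK(v));
      r[5] = mNaP_inf(v);
      r[6] = hNaP_inf(v);
      r[7] = std::exp(-dt / tau_hNaP(v));
    }
  }

  // row pointers and interpolation fraction for a voltage
  inline void locate(double v, const double *&lo, const double *&hi,
                     double &f) const {
    double x = (v - vmin) * inv_step;
    if (x < 0.0) x = 0.0;
    if (x > n - 1.001) x = n - 1.001;
    int i = (int)x;
    f = x - i;
    lo = &tab[(size_t)i * 8];
    hi = lo + 8;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_run_network(List nrn, List syn,
                     IntegerVector edge_ptr, IntegerVector edge_tgt,
                     NumericVector edge_w, NumericVector g_drive,
                     NumericMatrix epochs, NumericVector v0,
                     double dt, double t_total_ms, double record_from_ms,
                     double spike_thresh,
                     IntegerVector trace_idx, int trace_every) {
  NumericVector C   = nrn["C"],   gNa = nrn["gNa"], gNaP = nrn["gNaP"],
                gK  = nrn["gK"],  gL  = nrn["gL"],  EL   = nrn["EL"];
  IntegerVector has_nap = nrn["has_nap"], photo = nrn["photo"];
  const double ENa = as<double>(nrn["ENa"]), EK  = as<double>(nrn["EK"]),
               EAr = as<double>(nrn["EAr"]), ECh = as<double>(nrn["ECh"]);
  const double gEbar = as<double>(syn["gE"]),   gIbar = as<double>(syn["gI"]),
               EsynE = as<double>(syn["EsynE"]), EsynI = as<double>(syn["EsynI"]),
               tauE  = as<double>(syn["tauE"]),  tauI  = as<double>(syn["tauI"]);

  const int n = v0.size();
  if (C.size() != n || gNa.size() != n || gL.size() != n || EL.size() != n)
    stop("neuron parameter vectors must all have length %d", n);
  if (dt <= 0) stop("dt must be positive");
  const double *pC = C.begin(), *pgNa = gNa.begin(), *pgNaP = gNaP.begin(),
               *pgK = gK.begin(), *pgL = gL.begin(), *pEL = EL.begin(),
               *pdrv = g_drive.begin();
  const int *pnap = has_nap.begin(), *pphoto = photo.begin();
  const int *peptr = edge_ptr.begin(), *petgt = edge_tgt.begin();
  const double *pew = edge_w.begin();

  const int n_steps = (int)std::llround(t_total_ms / dt);
  const double decE = std::exp(-dt / tauE), decI = std::exp(-dt / tauI);
  GateTables tab(dt);

  // State vectors.
  std::vector<double> V(n), hNa(n), hNaP(n), mK(n), gE(n, 0.0), gI(n, 0.0);
  std::vector<char> above(n, 0);
  for (int i = 0; i < n; ++i) {
    V[i] = v0[i];
    hNa[i]  = hNa_inf(V[i]);
    hNaP[i] = hNaP_inf(V[i]);
    mK[i]   = mK_inf(V[i]);
    above[i] = V[i] >= spike_thresh;
  }

  std::vector<int> spiked_prev, spiked_now;
  spiked_prev.reserve(256); spiked_now.reserve(256);
  std::vector<double> spike_t; std::vector<int> spike_id;

  const int n_ep = epochs.nrow();
  const int n_tr = trace_idx.size();
  int n_trace_rows = 0;
  if (n_tr > 0 && trace_every > 0) n_trace_rows = n_steps / trace_every + 1;
  NumericMatrix traces(n_trace_rows, n_tr);
  NumericVector trace_time(n_trace_rows);
  int trace_row = 0;
  if (n_trace_rows > 0) {
    for (int k = 0; k < n_tr; ++k) traces(0, k) = V[trace_idx[k] - 1];
    trace_time[0] = 0.0;
    trace_row = 1;
  }

  double vlo = R_PosInf, vhi = R_NegInf;

  for (int step = 0; step < n_steps; ++step) {
    const double t_now = step * dt;        // state time before update
    const double t_next = (step + 1) * dt; // spike timestamp after update

    // 1. synaptic decay
    for (int i = 0; i < n; ++i) { gE[i] *= decE; gI[i] *= decI; }

    // 2. deliver previous-step spikes
    for (size_t s = 0; s < spiked_prev.size(); ++s) {
      const int j = spiked_prev[s];
      for (int e = peptr[j]; e < peptr[j + 1]; ++e) {
        const double w = pew[e];
        if (w > 0)      gE[petgt[e]] += gEbar * w;
        else if (w < 0) gI[petgt[e]] += gIbar * (-w);
      }
    }

    // 3. photostimulation conductances per photo group (1 = V1, 2 = V1-1)
    double gAr_grp[3] = {0.0, 0.0, 0.0}, gCh_grp[3] = {0.0, 0.0, 0.0};
    for (int e = 0; e < n_ep; ++e) {
      if (t_now >= epochs(e, 0) && t_now < epochs(e, 1)) {
        const int target = (int)epochs(e, 4);
        for (int g = 1; g <= 2; ++g) {
          if (target == g || target == 3) {
            gAr_grp[g] = epochs(e, 2);
            gCh_grp[g] = epochs(e, 3);
          }
        }
      }
    }

    // 4. membrane + gate update
    spiked_now.clear();
    for (int i = 0; i < n; ++i) {
      const double v = V[i];
      const double *lo, *hi; double tf;
      tab.locate(v, lo, hi, tf);
      #define TAB(k) (lo[k] + tf * (hi[k] - lo[k]))

      // exact exponential relaxation of dynamic gates toward steady state
      const double hna_i = TAB(1);
      hNa[i] = hna_i + (hNa[i] - hna_i) * TAB(2);
      const double mk_i = TAB(3);
      mK[i] = mk_i + (mK[i] - mk_i) * TAB(4);

      const double mna = TAB(0); // instantaneous
      double g_nap = 0.0;
      if (pnap[i]) {
        const double hnap_i = TAB(6);
        hNaP[i] = hnap_i + (hNaP[i] - hnap_i) * TAB(7);
        g_nap = pgNaP[i] * TAB(5) * hNaP[i];
      }
      #undef TAB

      const double g_na = pgNa[i] * mna * mna * mna * hNa[i];
      const double mk2 = mK[i] * mK[i];
      const double g_k = pgK[i] * mk2 * mk2;
      double g_ar = 0.0, g_ch = 0.0;
      if (pphoto[i] > 0) { g_ar = gAr_grp[pphoto[i]]; g_ch = gCh_grp[pphoto[i]]; }
      const double g_e = gE[i] + pdrv[i];
      const double g_i = gI[i];

      const double G = g_na + g_nap + g_k + pgL[i] + g_ar + g_ch + g_e + g_i;
      const double Esum = (g_na + g_nap) * ENa + g_k * EK + pgL[i] * pEL[i] +
                          g_ar * EAr + g_ch * ECh + g_e * EsynE + g_i * EsynI;
      const double veq = Esum / G;
      const double vnew = veq + (v - veq) * std::exp(-G * dt / pC[i]);
      if (!std::isfinite(vnew))
        stop("numerical instability: non-finite V in neuron %d at t = %.1f ms",
             i + 1, t_next);
      V[i] = vnew;
      if (vnew < vlo) vlo = vnew;
      if (vnew > vhi) vhi = vnew;

      // 5. spike detection (upward crossing, edge-triggered)
      if (vnew >= spike_thresh) {
        if (!above[i]) {
          above[i] = 1;
          spiked_now.push_back(i);
          if (t_next >= record_from_ms) {
            spike_t.push_back(t_next);
            spike_id.push_back(i + 1);
          }
        }
      } else {
        above[i] = 0;
      }
    }
    spiked_prev.swap(spiked_now);

    if (n_trace_rows > 0 && (step + 1) % trace_every == 0 && trace_row < n_trace_rows) {
      for (int k = 0; k < n_tr; ++k) traces(trace_row, k) = V[trace_idx[k] - 1];
      trace_time[trace_row] = t_next;
      ++trace_row;
    }
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector vfin(n), hna_fin(n), hnap_fin(n), mk_fin(n), ge_fin(n), gi_fin(n);
  for (int i = 0; i < n; ++i) {
    vfin[i] = V[i]; hna_fin[i] = hNa[i]; hnap_fin[i] = hNaP[i];
    mk_fin[i] = mK[i]; ge_fin[i] = gE[i]; gi_fin[i] = gI[i];
  }

  return List::create(
    _["spike_time"] = wrap(spike_t),
    _["spike_neuron"] = wrap(spike_id),
    _["traces"] = traces,
    _["trace_time"] = trace_time,
    _["v_range"] = NumericVector::create(vlo, vhi),
    _["final"] = List::create(_["V"] = vfin, _["hNa"] = hna_fin,
                              _["hNaP"] = hnap_fin, _["mK"] = mk_fin,
                              _["gSynE"] = ge_fin, _["gSynI"] = gi_fin),
    _["n_steps"] = n_steps);
}
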