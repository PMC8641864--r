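// Leaky integrate-and-fire ring network with optional short-term synaptic
// plasticity (facilitation u, depression x) on excitatory synapses.
//
// Populations: n_exc excitatory neurons on a ring (preferred angles evenly
// spaced on [0, 2*pi)) and n_inh inhibitory neurons. E->E connections are
// all-to-all and spatially tuned (Gaussian kernel over angular distance,
// normalized to mean 1 so the total recurrent strength g_ee is kernel-width
// independent); E->I, I->E and I->I are all-to-all and untuned, which lets
// them be carried by scalar synaptic traces. Exponential current synapses,
// Euler integration, per-neuron white-noise current.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double ang_dist(double a, double b) {
  double d = std::fabs(a - b);
  return d > M_PI ? 2.0 * M_PI - d : d;
}

// [[Rcpp::export(name = ".lif_ring_cpp")]]
List lif_ring_cpp(List spec, List proto, int seed) {
  const int nE = as<int>(spec["n_exc"]);
  const int nI = as<int>(spec["n_inh"]);
  const double dt = as<double>(spec["dt"]);
  const double tau_e = as<double>(spec["tau_m_e"]);
  const double tau_i = as<double>(spec["tau_m_i"]);
  const double v_th = as<double>(spec["v_th"]);
  const double v_reset = as<double>(spec["v_reset"]);
  const double t_ref = as<double>(spec["t_ref"]);
  const double tau_se = as<double>(spec["tau_se"]);
  const double tau_si = as<double>(spec["tau_si"]);
  const double g_ee = as<double>(spec["g_ee"]);
  const double g_ie = as<double>(spec["g_ie"]);
  const double g_ei = as<double>(spec["g_ei"]);
  const double g_ii = as<double>(spec["g_ii"]);
  const double ee_sigma = as<double>(spec["ee_sigma"]);
  const bool stp = as<bool>(spec["stp_enabled"]);
  const double U = as<double>(spec["stp_U"]);
  const double tau_f = as<double>(spec["stp_tau_f"]);
  const double tau_d = as<double>(spec["stp_tau_d"]);
  const double mu_e = as<double>(spec["mu_bg_e"]);
  const double mu_i = as<double>(spec["mu_bg_i"]);
  const double noise_sd = as<double>(spec["noise_sd"]);
  const double max_rate = as<double>(spec["max_rate"]);

  const double duration = as<double>(proto["duration"]);
  const double cue_angle = as<double>(proto["cue_angle"]) * M_PI / 180.0;
  const double cue_strength = as<double>(proto["cue_strength"]);
  const NumericVector cue_win = proto["cue_window"];
  const double cue_width = as<double>(proto["cue_width"]) * M_PI / 180.0;
  const double drive_strength = as<double>(proto["drive_strength"]);
  const NumericVector drive_win = proto["drive_window"];

  const int n_steps = (int)std::llround(duration / dt);
  const int ref_steps = (int)std::llround(t_ref / dt);
  const double dec_e = std::exp(-dt / tau_se);
  const double dec_i = std::exp(-dt / tau_si);
  const double sq_dt = std::sqrt(dt);

  std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 1442695040888963407ULL);
  std::normal_distribution<double> nd(0.0, 1.0);

  // tuned E->E kernel, normalized so its ring mean is 1
  std::vector<double> kernel(nE);
  double ksum = 0.0;
  for (int d = 0; d < nE; ++d) {
    double th = 2.0 * M_PI * d / nE;
    double ad = ang_dist(th, 0.0);
    kernel[d] = std::exp(-0.5 * ad * ad / (ee_sigma * ee_sigma));
    ksum += kernel[d];
  }
  for (int d = 0; d < nE; ++d) kernel[d] *= (double)nE / ksum;

  // per-neuron cue current profile
  std::vector<double> theta(nE), cue_prof(nE);
  for (int i = 0; i < nE; ++i) {
    theta[i] = 2.0 * M_PI * i / nE;
    double ad = ang_dist(theta[i], cue_angle);
    cue_prof[i] = std::exp(-0.5 * ad * ad / (cue_width * cue_width));
  }

  std::vector<double> vE(nE, 0.0), vI(nI, 0.0);
  std::vector<int> refE(nE, 0), refI(nI, 0);
  std::vector<double> sEE(nE, 0.0);      // tuned recurrent input to each E
  double sEI = 0.0, sIE = 0.0, sII = 0.0; // untuned scalar traces
  std::vector<double> u(nE, U), x(nE, 1.0);

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  spk_id.reserve(1 << 16);
  spk_t.reserve(1 << 16);
  std::vector<int> spk_id_i;
  std::vector<double> spk_t_i;

  // synaptic-state recorder: mean u*x (and u, x) over cue-adjacent E neurons
  // (within 30 deg) and over the whole ring, sampled every 10 ms
  const int rec_every = std::max(1, (int)std::llround(0.01 / dt));
  std::vector<double> rec_t, rec_ux_cue, rec_ux_all, rec_u_cue, rec_x_cue;
  std::vector<int> cue_idx;
  for (int i = 0; i < nE; ++i)
    if (ang_dist(theta[i], cue_angle) < 30.0 * M_PI / 180.0)
      cue_idx.push_back(i);

  const double max_spikes =
      max_rate * (double)(nE + nI) * duration; // divergence guard

  const double wee = g_ee / nE;   // per-connection peak-free scale
  const double wie = g_ie / nE;   // E -> I per connection
  const double wei = g_ei / nI;   // I -> E per connection
  const double wii = g_ii / nI;

  const double u_rec = dt / tau_f;
  const double x_rec = dt / tau_d;

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const bool in_cue = (t >= cue_win[0] && t < cue_win[1]);
    const bool in_drive = (t >= drive_win[0] && t < drive_win[1]);

    // synaptic decay
    for (int i = 0; i < nE; ++i) sEE[i] *= dec_e;
    sEI *= dec_e;
    sIE *= dec_i;
    sII *= dec_i;

    // STP recovery
    if (stp) {
      for (int i = 0; i < nE; ++i) {
        u[i] += (U - u[i]) * u_rec;
        x[i] += (1.0 - x[i]) * x_rec;
      }
    }

    // excitatory membrane update
    for (int i = 0; i < nE; ++i) {
      if (refE[i] > 0) { --refE[i]; continue; }
      double I = mu_e + sEE[i] - sIE;
      if (in_cue) I += cue_strength * cue_prof[i];
      if (in_drive) I += drive_strength;
      vE[i] += dt / tau_e * (-vE[i] + I) + noise_sd * sq_dt * nd(rng);
    }
    // inhibitory membrane update
    for (int j = 0; j < nI; ++j) {
      if (refI[j] > 0) { --refI[j]; continue; }
      double I = mu_i + sEI - sII;
      vI[j] += dt / tau_i * (-vI[j] + I) + noise_sd * sq_dt * nd(rng);
    }

    // threshold crossings
    for (int i = 0; i < nE; ++i) {
      if (refE[i] > 0 || vE[i] < v_th) continue;
      vE[i] = v_reset;
      refE[i] = ref_steps;
      spk_id.push_back(i + 1);
      spk_t.push_back(t);
      double eff = 1.0;
      if (stp) {
        u[i] += U * (1.0 - u[i]);
        eff = u[i] * x[i];
        x[i] -= eff;
      }
      const double we = wee * eff;
      for (int k = 0; k < nE; ++k) {
        int d = k - i; if (d < 0) d += nE;
        sEE[k] += we * kernel[d];
      }
      sEI += wie * eff;
    }
    for (int j = 0; j < nI; ++j) {
      if (refI[j] > 0 || vI[j] < v_th) continue;
      vI[j] = v_reset;
      refI[j] = ref_steps;
      spk_id_i.push_back(j + 1);
      spk_t_i.push_back(t);
      sIE += wei;
      sII += wii;
    }

    if ((double)(spk_id.size() + spk_id_i.size()) > max_spikes) {
      double mean_rate = (double)spk_id.size() / ((t + dt) * nE);
      stop("network rate diverged (mean excitatory rate %.1f Hz by t = %.3f s);"
           " reduce recurrent strength or drive", mean_rate, t);
    }

    if (s % rec_every == 0) {
      double sc = 0, sa = 0, su = 0, sx = 0;
      for (int idx : cue_idx) { sc += u[idx] * x[idx]; su += u[idx]; sx += x[idx]; }
      for (int i = 0; i < nE; ++i) sa += u[i] * x[i];
      rec_t.push_back(t);
      rec_ux_cue.push_back(sc / cue_idx.size());
      rec_ux_all.push_back(sa / nE);
      rec_u_cue.push_back(su / cue_idx.size());
      rec_x_cue.push_back(sx / cue_idx.size());
    }
  }

  return List::create(
      _["neuron"] = wrap(spk_id), _["time"] = wrap(spk_t),
      _["neuron_inh"] = wrap(spk_id_i), _["time_inh"] = wrap(spk_t_i),
      _["stp_time"] = wrap(rec_t), _["stp_ux_cue"] = wrap(rec_ux_cue),
      _["stp_ux_all"] = wrap(rec_ux_all), _["stp_u_cue"] = wrap(rec_u_cue),
      _["stp_x_cue"] = wrap(rec_x_cue));
}
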