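// Event-resolved integrator for coordinated spike-coding networks.
//
// The membrane dynamics V' = -lambda V + F(lambda x + x') - F D s + sigma eta
// are integrated with an exponentially consistent scheme: both V and the
// filtered spike trains r decay by exp(-lambda dt) per step, and the
// feedforward drive enters as the increment F (x_{n+1} - exp(-lambda dt) x_n),
// so that in the noiseless, undelayed case the identity V = F (x - D r) is
// preserved to machine precision (it agrees with forward Euler-Maruyama to
// O(dt^2) per step). Threshold crossings within a step are resolved one at a
// time in order of decreasing violation ("slowed-down time"); delayed
// recurrent spikes are delivered at the end of the step of their target grid
// point, while self-resets remain instantaneous.

#include <RcppArmadillo.h>
#include <deque>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(const arma::mat& Fdrive,      // N x nsteps drive increments F * B
              const arma::mat& Omega,       // N x N fast recurrent weights
              const arma::mat& Omega2,      // alternate weights (0x0 if unused)
              int om2_start, int om2_end,   // alt-weight step window [start, end)
              const arma::mat& Wslow,       // N x N slow weights (0x0 if none)
              const arma::vec& Tbase,       // length-N thresholds
              const arma::mat& Tshift,      // N x (nsteps+1) threshold shifts
              const arma::mat& Pcur,        // N x nsteps currents, V/s
              const arma::vec& sigma_t,     // length-nsteps noise sd per step
              double lambda, double dt, double tau_ref,
              int delay_steps, int max_substeps, double max_total_spikes,
              const arma::vec& V0, const arma::vec& r0,
              bool record_V) {
  const int N = Omega.n_rows;
  const int nsteps = Fdrive.n_cols;
  const double decay = std::exp(-lambda * dt);
  const double sqdt = std::sqrt(dt);
  const bool has_alt = Omega2.n_elem > 0;
  const bool has_slow = Wslow.n_elem > 0;
  const bool has_tshift = Tshift.n_elem > 0;
  const bool has_cur = Pcur.n_elem > 0;

  arma::vec V = V0;
  arma::vec r = r0;
  arma::vec refrac_until(N);
  refrac_until.fill(-1e300);

  arma::mat Vrec, rrec;
  rrec.zeros(N, nsteps + 1);
  rrec.col(0) = r;
  if (record_V) {
    Vrec.zeros(N, nsteps + 1);
    Vrec.col(0) = V;
  }
  int completed = 0;

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  IntegerVector spikes_per_step(nsteps);
  // pending[k] holds neurons whose recurrent effect is delivered at the end of
  // the step that lands on grid point (current step index + 1 + k).
  std::deque<std::vector<int>> pending;
  for (int k = 0; k <= delay_steps; ++k) pending.push_back(std::vector<int>());

  bool overflow = false, truncated = false, diverged = false;
  int diverged_step = -1;
  long total_spikes = 0;

  for (int n = 0; n < nsteps && !truncated; ++n) {
    const arma::mat& Om = (has_alt && n >= om2_start && n < om2_end) ? Omega2
                                                                     : Omega;
    // decay + drive
    V *= decay;
    r *= decay;
    V += Fdrive.col(n);
    if (has_slow) V += dt * (Wslow * r);
    if (has_cur) V += dt * Pcur.col(n);
    double sig = sigma_t[n];
    if (sig > 0.0) {
      for (int i = 0; i < N; ++i) V[i] += sig * sqdt * ::norm_rand();
    }

    const double tnow = (n + 1) * dt;  // spikes of this step carry this time
    // thresholds in effect at this grid point
    arma::vec Teff = Tbase;
    if (has_tshift) Teff += Tshift.col(n + 1);

    // resolve crossings one at a time, largest violation first
    int sub = 0;
    for (;;) {
      int best = -1;
      double best_v = 0.0;
      for (int i = 0; i < N; ++i) {
        if (tnow < refrac_until[i] - 1e-12) continue;  // refractory: omit spike
        double viol = V[i] - Teff[i];
        if (viol >= 0.0 && (best < 0 || viol > best_v)) {
          best = i;
          best_v = viol;
        }
      }
      if (best < 0) break;
      if (++sub > max_substeps) {
        overflow = true;
        break;
      }
      spike_t.push_back(tnow);
      spike_id.push_back(best + 1);
      ++total_spikes;
      refrac_until[best] = tnow + tau_ref;
      if (delay_steps == 0) {
        V += Om.col(best);  // full column: self-reset plus lateral recurrence
        r[best] += 1.0;
      } else {
        V[best] += Om(best, best);  // self-reset is never delayed
        pending[delay_steps - 1].push_back(best);
      }
      if (static_cast<double>(total_spikes) >= max_total_spikes) {
        truncated = true;
        break;
      }
    }
    spikes_per_step[n] = sub;

    // delayed lateral recurrence arrives only at the end of the step
    if (delay_steps > 0) {
      std::vector<int> due = pending.front();
      pending.pop_front();
      pending.push_back(std::vector<int>());
      for (size_t q = 0; q < due.size(); ++q) {
        int j = due[q];
        V += Om.col(j);
        V[j] -= Om(j, j);  // self part was applied at spike time
        r[j] += 1.0;       // delayed readout (Eq. for r(t - theta))
      }
    }

    if (!V.is_finite()) {
      diverged = true;
      diverged_step = n + 1;
      break;
    }
    rrec.col(n + 1) = r;
    if (record_V) Vrec.col(n + 1) = V;
    completed = n + 1;
  }

  return List::create(
      _["spike_times"] = wrap(spike_t), _["spike_ids"] = wrap(spike_id),
      _["V"] = record_V ? wrap(Vrec) : R_NilValue, _["r"] = wrap(rrec),
      _["substep_overflow"] = overflow, _["truncated"] = truncated,
      _["diverged"] = diverged, _["diverged_step"] = diverged_step,
      _["spikes_per_step"] = spikes_per_step,
      _["completed_steps"] = completed,
      _["total_spikes"] = static_cast<double>(total_spikes));
}
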