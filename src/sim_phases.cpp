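#include <Rcpp.h>
using namespace Rcpp;

// Evolve one frequency band of a two-brain dyad as coupled phase
// oscillators.
//
// Uncoupled channels perform constant-frequency phase random walks pulled
// (rate k_intra * pull_rate) towards their own brain's rhythm xi_b.
// Channels of the inter-coupling set instead lock with unit strength onto
// the weighted circular mean of xi_b and that brain's *received copy* of a
// dyad-level rhythm psi; the mixing weight (mix_w) is fixed whenever any
// inter-brain coupling is scheduled, and the coupling strength kappa
// controls the fidelity of the received copy: each brain's copy carries an
// Ornstein-Uhlenbeck phase error with stationary SD eta0 * (1 - kappa).
// Because that error is common to all channels of a brain, within-brain
// phase relations are invariant in kappa; only the between-brain alignment
// improves as kappa grows. Brain 2 (the follower) receives the dyad rhythm
// delayed by delay_samp samples when directed coupling is scheduled, giving
// the leader a consistent temporal precedence. Per-channel phase offsets
// are applied after mixing, so two same-brain coupled channels differ by a
// constant angle whatever the weights — non-zero lags that lag-sensitive
// synchronization measures require.
//
// Uses R's RNG so results are reproducible under set.seed().
//
// Returns a (2*n_ch) x n matrix of phases; rows 1..n_ch are brain 1.
// [[Rcpp::export]]
NumericMatrix sim_band_phases_cpp(int n, double fs, NumericVector freq,
                                  double phase_noise, double pull_rate,
                                  NumericVector k_intra, NumericVector k_inter,
                                  NumericVector k_dir, LogicalVector coupled,
                                  int delay_samp, double mix_w, double eta0,
                                  double eta_rate, NumericMatrix off_intra,
                                  NumericMatrix off_inter,
                                  NumericVector theta0, double psi0,
                                  double xi10, double xi20) {
  const int n_ch = off_intra.nrow();
  const int n_tot = 2 * n_ch;
  const double dt = 1.0 / fs;
  const double sdt = std::sqrt(dt);
  const double two_pi = 2.0 * M_PI;

  NumericMatrix theta(n_tot, n);
  std::vector<double> psi(n);     // dyad rhythm history (for the delay)
  double xi1 = xi10, xi2 = xi20;  // per-brain rhythms
  double eta1 = 0.0, eta2 = 0.0;  // per-brain rhythm-copy phase errors

  // rhythms advance at the mean channel frequency
  double f0 = 0.0;
  for (int c = 0; c < n_tot; ++c) f0 += freq[c];
  f0 /= n_tot;

  psi[0] = psi0;
  for (int c = 0; c < n_tot; ++c) theta(c, 0) = theta0[c];

  for (int t = 0; t < n - 1; ++t) {
    psi[t + 1] = psi[t] + two_pi * f0 * dt + phase_noise * sdt * R::norm_rand();
    xi1 += two_pi * f0 * dt + phase_noise * sdt * R::norm_rand();
    xi2 += two_pi * f0 * dt + phase_noise * sdt * R::norm_rand();

    double ki = k_intra[t], ke = k_inter[t], kd = k_dir[t];
    double k_eff = std::min(1.0, ke + kd);
    // OU phase error of each brain's rhythm copy; stationary SD shrinks
    // to zero as the coupling strength approaches 1
    double sd_eta = eta0 * (1.0 - k_eff);
    double s_eta = sd_eta * std::sqrt(2.0 * eta_rate);
    eta1 += -eta_rate * eta1 * dt + s_eta * sdt * R::norm_rand();
    eta2 += -eta_rate * eta2 * dt + s_eta * sdt * R::norm_rand();

    int td = t - delay_samp;
    double psi_del = (td >= 0) ? psi[td] : psi[0];
    double w_ext = (ke + kd > 0) ? mix_w : 0.0;

    for (int b = 0; b < 2; ++b) {
      double xib = (b == 0) ? xi1 : xi2;
      double etab = (b == 0) ? eta1 : eta2;
      // the follower's copy is delayed only under directed coupling
      double psib = (b == 1 && kd > 0) ? psi_del : psi[t];
      for (int c = 0; c < n_ch; ++c) {
        int row = b * n_ch + c;
        double th = theta(row, t);
        double pull = 0.0;
        if (coupled[c] && w_ext > 0) {
          double off = off_inter(c, b);
          double a_int = xib + off;
          double a_ext = psib + etab + off;
          double vx = (1.0 - w_ext) * std::cos(a_int) +
                      w_ext * std::cos(a_ext);
          double vy = (1.0 - w_ext) * std::sin(a_int) +
                      w_ext * std::sin(a_ext);
          if (vx != 0.0 || vy != 0.0)
            pull = std::sin(std::atan2(vy, vx) - th);
        } else if (coupled[c]) {
          pull = std::sin(xib + off_inter(c, b) - th);
        } else if (ki > 0) {
          pull = ki * std::sin(xib + off_intra(c, b) - th);
        }
        theta(row, t + 1) = th + two_pi * freq[row] * dt +
                            pull_rate * pull * dt +
                            phase_noise * sdt * R::norm_rand();
      }
    }
  }
  return theta;
}
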