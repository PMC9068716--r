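# Shared fixtures: small, fast simulation configurations and hand-built
# analytic-epoch objects.

fast_config <- function(..., n_trials = 14L, fs = 160, seed = 1L) {
  sim_config(n_trials = n_trials, fs = fs, seed = seed, ...)
}

gamma_only_coupling <- function(kappa = 0.8) {
  list(eye_contact = c(gamma = kappa), control = numeric(0))
}

no_coupling <- list(eye_contact = numeric(0), control = numeric(0))

# build an "analytic_epochs" object directly from per-channel phase arrays
# (trial x channel x time), bypassing the preprocessing chain
epochs_from_phases <- function(ph1, ph2, fs = 250, band = c(30, 45),
                               mask = NULL, labels = NULL) {
  nt <- dim(ph1)[1]
  len <- dim(ph1)[3]
  if (is.null(mask)) mask <- matrix(FALSE, nt, len)
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(ph1)[2]))
  structure(list(p1 = exp(1i * ph1), p2 = exp(1i * ph2), mask = mask,
                 condition = "eye_contact", n_valid = nt, band = band,
                 window = c(0.5, 2), fs = fs, channel_labels = labels),
            class = "analytic_epochs")
}

# Ornstein-Uhlenbeck-style phase random walk (independent channels)
random_phases <- function(nt, nch, len, drift = 0.5, sd_step = 0.15) {
  arr <- array(0, c(nt, nch, len))
  for (t in seq_len(nt))
    for (c in seq_len(nch))
      arr[t, c, ] <- cumsum(drift + rnorm(len, 0, sd_step)) +
        runif(1, 0, 2 * pi)
  arr
}

# inter-brain edge cells among a coupled channel subset
coupled_inter_cells <- function(config) {
  coupled <- eeg_montage()[seq_len(config$n_channels)] %in%
    config$coupled_channels
  inter_mask(config$n_channels) &
    outer(rep(coupled, 2), rep(coupled, 2))
}
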