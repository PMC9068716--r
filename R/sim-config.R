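#' Simulation configuration for synthetic dyads
#'
#' Parameterizes the coupled-oscillator dyad generator. Each EEG channel is a
#' sum of band-limited oscillations (one phase process per frequency band)
#' plus a zero-lag shared source, white sensor noise and blink pulses. Phase
#' processes are constant-frequency random walks with Kuramoto-style pull
#' terms. Within-brain coupling attracts every channel towards its brain's
#' rhythm. Inter-brain coupling acts on the channels listed in
#' `coupled_channels`: they lock onto a fixed-weight mixture of their
#' brain's rhythm and that brain's received copy of a dyad-level rhythm,
#' and the coupling strength sets the fidelity of the copy (a slow
#' common-mode phase error shrinking to zero at coupling 1). The error is
#' common to all channels of a brain, so within-brain synchrony is
#' invariant in the coupling strength; only between-brain alignment
#' changes. Directed coupling delivers the follower's copy delayed by
#' `directed_delay_s`, so the leader's phases consistently precede the
#' follower's. Fixed per-channel phase offsets (applied after mixing) give
#' locked pairs non-zero phase lags.
#'
#' @param n_channels Channels per brain; labels follow [eeg_montage()].
#' @param fs Sampling rate in Hz; must exceed twice the highest band edge.
#' @param bands Named list of frequency bands (see [frequency_bands()]).
#' @param band_amplitudes Named numeric, oscillation amplitude per band (uV).
#' @param inter_coupling,directed_coupling,intra_coupling Coupling strengths
#'   in `[0, 1]`: a list with elements `eye_contact` and `control`, each a
#'   named numeric vector keyed by band name (absent bands couple at 0).
#'   `inter_coupling` is the undirected (zero-lag rhythm) inter-brain pull,
#'   `directed_coupling` the time-delayed leader-to-follower pull, and
#'   `intra_coupling` the within-brain pull.
#' @param coupled_channels Channels participating in inter-brain coupling.
#' @param directed_delay_s Leader-to-follower coupling lag in seconds.
#' @param shared_source_gain Mixing gain in `[0, 1]` of a zero-lag source
#'   added identically to every channel of both brains (volume-conduction
#'   surrogate).
#' @param noise_sd White sensor-noise SD (uV).
#' @param blink_rate_hz Poisson rate of +100 uV, 60 ms raised-cosine blink
#'   pulses injected on Fp1/Fp2.
#' @param n_trials Trials per condition (eye-contact and control tasks).
#' @param iti_s Inter-trial gap in seconds.
#' @param leadership_bias Probability in `[0.5, 1]` that the leader (P1)
#'   breaks eye contact first on an eye-contact trial.
#' @param repro_cv SD of the log reproduction-duration noise.
#' @param pair_correlation Correlation of the partners' log reproduction
#'   noise (behavioral coupling).
#' @param friend_effect Additive increment to inter-brain coupling for
#'   "friends" dyads (applied by [generate_cohort()]).
#' @param phase_noise Phase-diffusion intensity (rad per sqrt-second).
#' @param pull_rate Locking pull rate (1/s).
#' @param mix_weight Fixed mixing weight of the dyad rhythm in the coupled
#'   channels' locking target whenever inter-brain coupling is scheduled.
#' @param fidelity_sd Stationary SD (rad) of the per-brain rhythm-copy
#'   phase error at coupling 0; the error SD is
#'   `fidelity_sd * (1 - coupling)`.
#' @param fidelity_rate Mean-reversion rate (1/s) of the rhythm-copy error.
#' @param freq_jitter_sd SD (Hz) of per-channel center-frequency jitter.
#' @param include_reference Append two earlobe-like reference channels
#'   ("A1", "A2") carrying low-amplitude noise.
#' @param seed Integer RNG seed; identical seed and config give
#'   bit-identical output.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_channels = 18L,
                       fs = 500,
                       bands = frequency_bands(),
                       band_amplitudes = c(theta = 8, alpha = 10,
                                           lower_beta = 6, upper_beta = 5,
                                           gamma = 4),
                       inter_coupling = list(
                         eye_contact = c(gamma = 0.6),
                         control = numeric(0)),
                       directed_coupling = list(
                         eye_contact = numeric(0),
                         control = numeric(0)),
                       intra_coupling = list(
                         eye_contact = c(theta = 0.45, alpha = 0.45,
                                         lower_beta = 0.45, upper_beta = 0.45,
                                         gamma = 0.45),
                         control = c(theta = 0.45, alpha = 0.45,
                                     lower_beta = 0.45, upper_beta = 0.45,
                                     gamma = 0.45)),
                       coupled_channels = c("P8", "F8", "F4", "C4", "T8",
                                            "P4", "Fp2", "Fz", "Cz", "Pz"),
                       directed_delay_s = 0.02,
                       shared_source_gain = 0.3,
                       noise_sd = 2,
                       blink_rate_hz = 0.1,
                       n_trials = 40L,
                       iti_s = 0.5,
                       leadership_bias = 0.75,
                       repro_cv = 0.15,
                       pair_correlation = 0.4,
                       friend_effect = 0.2,
                       phase_noise = 3,
                       pull_rate = 40,
                       mix_weight = 0.75,
                       fidelity_sd = 1.8,
                       fidelity_rate = 2,
                       freq_jitter_sd = 0.2,
                       include_reference = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_channels = as.integer(n_channels), fs = fs, bands = bands,
    band_amplitudes = band_amplitudes, inter_coupling = inter_coupling,
    directed_coupling = directed_coupling, intra_coupling = intra_coupling,
    coupled_channels = coupled_channels,
    directed_delay_s = directed_delay_s,
    shared_source_gain = shared_source_gain, noise_sd = noise_sd,
    blink_rate_hz = blink_rate_hz, n_trials = as.integer(n_trials),
    iti_s = iti_s, leadership_bias = leadership_bias, repro_cv = repro_cv,
    pair_correlation = pair_correlation, friend_effect = friend_effect,
    phase_noise = phase_noise, pull_rate = pull_rate,
    mix_weight = mix_weight, fidelity_sd = fidelity_sd,
    fidelity_rate = fidelity_rate,
    freq_jitter_sd = freq_jitter_sd,
    include_reference = isTRUE(include_reference), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!length(cfg$bands)) stop("band set must not be empty")
  f_hi_max <- max(vapply(cfg$bands, `[`, numeric(1), 2))
  if (cfg$fs <= 2 * f_hi_max)
    stop("fs must exceed twice the highest band edge (", 2 * f_hi_max,
         " Hz); got ", cfg$fs)
  for (nm in c("inter_coupling", "directed_coupling", "intra_coupling")) {
    for (cond in c("eye_contact", "control")) {
      k <- cfg[[nm]][[cond]]
      if (length(k)) {
        stopifnot_scalar01(k, nm)
        bad <- setdiff(names(k), names(cfg$bands))
        if (length(bad))
          stop(nm, " names unknown band(s): ", paste(bad, collapse = ", "))
      }
    }
  }
  stopifnot_scalar01(cfg$shared_source_gain, "shared_source_gain")
  if (cfg$leadership_bias < 0.5 || cfg$leadership_bias > 1)
    stop("leadership_bias must lie in [0.5, 1]")
  if (cfg$n_trials < 1L) stop("n_trials must be >= 1")
  miss <- setdiff(names(cfg$bands), names(cfg$band_amplitudes))
  if (length(miss))
    stop("band_amplitudes missing band(s): ", paste(miss, collapse = ", "))
  if (!all(cfg$coupled_channels %in% eeg_montage()[seq_len(cfg$n_channels)]))
    stop("coupled_channels must be montage channels")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_channels, "ch/brain,", x$fs, "Hz,",
      length(x$bands), "bands,", x$n_trials, "trials/condition, seed",
      x$seed, "\n")
  invisible(x)
}

# coupling strength lookup with 0 default
coupling_value <- function(map, condition, band) {
  k <- map[[condition]]
  if (is.null(k) || !band %in% names(k)) return(0)
  unname(k[[band]])
}
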