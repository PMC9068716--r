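#' Generate the behavioral trial table of one dyad
#'
#' Draws tone durations (1.5 s or 2.5 s per participant, all four
#' combinations equally likely), reproduced durations (tone duration times a
#' log-normal noise term whose log is correlated between partners by
#' `pair_correlation`), and — for eye-contact trials — which participant
#' broke eye contact first (Bernoulli with `leadership_bias`; P1 is the
#' nominal leader).
#'
#' @param config A [sim_config()].
#' @param dyad_id Dyad identifier.
#' @param n_trials Trials per task; defaults to `config$n_trials`.
#' @param tasks Tasks to generate.
#' @return Data frame with one row per trial: `dyad_id`, `task`, `trial`,
#'   `tone_p1`, `tone_p2`, `repro_p1`, `repro_p2`, `first_breaker`.
#' @export
generate_behavior <- function(config, dyad_id = "dyad01",
                              n_trials = config$n_trials,
                              tasks = c("eye_contact", "control")) {
  stopifnot(inherits(config, "sim_config"))
  if (n_trials < 1L) stop("n_trials must be >= 1")
  set.seed(config$seed)
  behavior_trials(config, dyad_id, n_trials, tasks)
}

# trial-table generation on the current RNG stream
behavior_trials <- function(config, dyad_id, n_trials, tasks) {
  tones <- c(1.5, 2.5)
  rho <- config$pair_correlation
  out <- lapply(tasks, function(task) {
    combo <- sample.int(4L, n_trials, replace = TRUE)
    tone_p1 <- tones[c(1, 2, 1, 2)][combo]
    tone_p2 <- tones[c(1, 2, 2, 1)][combo]
    # correlated log-normal reproduction noise
    z1 <- rnorm(n_trials)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_trials)
    repro_p1 <- tone_p1 * exp(config$repro_cv * z1)
    repro_p2 <- tone_p2 * exp(config$repro_cv * z2)
    first <- if (task == "eye_contact") {
      ifelse(rbinom(n_trials, 1L, config$leadership_bias) == 1L, "P1", "P2")
    } else NA_character_
    data.frame(dyad_id = dyad_id, task = task, trial = seq_len(n_trials),
               tone_p1 = tone_p1, tone_p2 = tone_p2,
               repro_p1 = repro_p1, repro_p2 = repro_p2,
               first_breaker = first, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate one synthetic dyad recording
#'
#' Simulates a two-brain multichannel EEG recording with the coupling
#' structure described in [sim_config()]: condition-dependent inter-brain
#' phase coupling on the configured channel set, optional time-delayed
#' leader-to-follower coupling, a zero-lag shared source mixed into both
#' brains, white noise and blink artifacts. Trial events (the common
#' tone-reproduction windows) are embedded in the recording; coupling is
#' active only inside trial windows, with strengths chosen by the trial's
#' condition.
#'
#' @param config A [sim_config()].
#' @param dyad_id Dyad identifier.
#' @param group `"friends"` or `"strangers"` (label only; coupling increments
#'   for friends are applied by [generate_cohort()]).
#' @return An object of class `"dyad_recording"`: channel-by-time signal
#'   matrices `signals_p1`/`signals_p2` (uV), `fs`, `channel_labels`, an
#'   `events` table (onset/offset samples, condition, tone and reproduction
#'   durations, gaze-break order), `dyad_id`, `group`, `seed`.
#' @export
generate_dyad <- function(config, dyad_id = "dyad01", group = "strangers") {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n_ch <- config$n_channels
  fs <- config$fs
  labels <- eeg_montage()[seq_len(n_ch)]

  trials <- behavior_trials(config, dyad_id, config$n_trials,
                            c("eye_contact", "control"))
  # schedule: sequential trials; the epoch is the common reproduction window
  cursor <- config$iti_s
  onset <- offset <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    onset[i] <- cursor
    common <- min(trials$repro_p1[i], trials$repro_p2[i])
    offset[i] <- cursor + common
    cursor <- cursor + max(trials$repro_p1[i], trials$repro_p2[i]) +
      config$iti_s
  }
  n <- ceiling((cursor + config$iti_s) * fs)
  events <- cbind(trials,
                  onset = as.integer(round(onset * fs)) + 1L,
                  offset = as.integer(round(offset * fs)) + 1L,
                  condition = trials$task)

  x <- matrix(0, 2L * n_ch, n)
  shared <- numeric(n)
  coupled <- labels %in% config$coupled_channels
  delay_samp <- as.integer(round(config$directed_delay_s * fs))

  for (band in names(config$bands)) {
    f0 <- mean(config$bands[[band]])
    amp <- config$band_amplitudes[[band]]
    # per-sample coupling schedule from the trial windows
    k_intra <- k_inter <- k_dir <- numeric(n)
    for (i in seq_len(nrow(events))) {
      idx <- events$onset[i]:min(events$offset[i], n)
      cond <- events$condition[i]
      k_intra[idx] <- coupling_value(config$intra_coupling, cond, band)
      k_inter[idx] <- coupling_value(config$inter_coupling, cond, band)
      k_dir[idx]   <- coupling_value(config$directed_coupling, cond, band)
    }
    freq <- f0 + rnorm(2L * n_ch, 0, config$freq_jitter_sd)
    off_intra <- matrix(runif(2L * n_ch, 0, 2 * pi), n_ch, 2L)
    off_inter <- matrix(runif(2L * n_ch, 0, 2 * pi), n_ch, 2L)
    theta0 <- runif(2L * n_ch, 0, 2 * pi)
    theta <- sim_band_phases_cpp(n, fs, freq, config$phase_noise,
                                 config$pull_rate, k_intra, k_inter, k_dir,
                                 coupled, delay_samp, config$mix_weight,
                                 config$fidelity_sd, config$fidelity_rate,
                                 off_intra, off_inter,
                                 theta0, runif(1, 0, 2 * pi),
                                 runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
    x <- x + amp * cos(theta)

    # zero-lag source shared by both brains, same band structure
    if (config$shared_source_gain > 0) {
      dphi <- 2 * pi * f0 / fs +
        config$phase_noise * sqrt(1 / fs) * rnorm(n)
      shared <- shared + amp * cos(cumsum(dphi))
    }
  }

  # convex mixing: gain g replaces a fraction g of every channel's
  # oscillatory content by the common zero-lag source
  g <- config$shared_source_gain
  if (g > 0) x <- (1 - g) * x + g * rep(shared, each = 2L * n_ch)

  x <- x + matrix(rnorm(length(x), 0, config$noise_sd), nrow(x))

  p1 <- x[seq_len(n_ch), , drop = FALSE]
  p2 <- x[n_ch + seq_len(n_ch), , drop = FALSE]
  rownames(p1) <- rownames(p2) <- labels

  p1 <- add_blinks(p1, fs, config$blink_rate_hz)
  p2 <- add_blinks(p2, fs, config$blink_rate_hz)

  if (config$include_reference) {
    ref1 <- matrix(rnorm(2L * n, 0, config$noise_sd / 2), 2L, n,
                   dimnames = list(c("A1", "A2"), NULL))
    ref2 <- matrix(rnorm(2L * n, 0, config$noise_sd / 2), 2L, n,
                   dimnames = list(c("A1", "A2"), NULL))
    p1 <- rbind(p1, ref1)
    p2 <- rbind(p2, ref2)
    labels <- c(labels, "A1", "A2")
  }

  structure(list(signals_p1 = p1, signals_p2 = p2, fs = fs,
                 channel_labels = labels, events = events,
                 dyad_id = dyad_id, group = group, seed = config$seed,
                 config = config),
            class = "dyad_recording")
}

# +100 uV raised-cosine blink pulses (60 ms) on Fp1/Fp2 at a Poisson rate
add_blinks <- function(sig, fs, rate_hz) {
  rows <- intersect(c("Fp1", "Fp2"), rownames(sig))
  if (!length(rows) || rate_hz <= 0) return(sig)
  n <- ncol(sig)
  dur_s <- n / fs
  n_blinks <- rpois(1, rate_hz * dur_s)
  if (n_blinks == 0) return(sig)
  len <- round(0.06 * fs)
  pulse <- 100 * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
  starts <- sample.int(n - len, n_blinks, replace = TRUE)
  for (s in starts) {
    idx <- s:(s + len - 1L)
    sig[rows, idx] <- sig[rows, idx] +
      matrix(pulse, length(rows), len, byrow = TRUE)
  }
  sig
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat("<dyad_recording>", x$dyad_id, "(", x$group, "):",
      nrow(x$signals_p1), "ch x", ncol(x$signals_p1), "samples @", x$fs,
      "Hz;", nrow(x$events), "trials\n")
  invisible(x)
}

#' Generate a cohort of synthetic dyads
#'
#' Friend dyads receive `config$friend_effect` added to every configured
#' inter-brain coupling strength (capped at 1). Per-dyad seeds are derived
#' reproducibly from `config$seed`.
#'
#' @param n_dyads Number of dyads (>= 2).
#' @param friends_fraction Fraction of dyads labeled friends, in `[0, 1]`.
#' @param config A [sim_config()]; `config$seed` acts as the master seed.
#' @param leadership_bias Optional per-dyad vector overriding
#'   `config$leadership_bias` (recycled), e.g. to mix strong- and
#'   weak-leadership dyads.
#' @return List with elements `recordings` (list of [generate_dyad()]
#'   outputs) and `behavior` (row-bound trial tables).
#' @export
generate_cohort <- function(n_dyads, friends_fraction = 0.5, config,
                            leadership_bias = NULL) {
  if (n_dyads < 2) stop("n_dyads must be >= 2")
  stopifnot_scalar01(friends_fraction, "friends_fraction")
  stopifnot(inherits(config, "sim_config"))
  n_friends <- round(n_dyads * friends_fraction)
  groups <- rep(c("friends", "strangers"),
                c(n_friends, n_dyads - n_friends))
  seeds <- derive_seeds(config$seed, n_dyads)
  bias <- if (is.null(leadership_bias)) rep(config$leadership_bias, n_dyads)
          else rep_len(leadership_bias, n_dyads)
  recs <- vector("list", n_dyads)
  for (d in seq_len(n_dyads)) {
    cfg_d <- config
    cfg_d$seed <- seeds[d]
    cfg_d$leadership_bias <- bias[d]
    if (groups[d] == "friends") {
      for (cond in names(cfg_d$inter_coupling)) {
        k <- cfg_d$inter_coupling[[cond]]
        if (length(k))
          cfg_d$inter_coupling[[cond]] <- pmin(k + config$friend_effect, 1)
      }
    }
    recs[[d]] <- generate_dyad(cfg_d, sprintf("dyad%02d", d), groups[d])
  }
  behavior <- do.call(rbind, lapply(recs, function(r) r$events))
  list(recordings = recs, behavior = behavior)
}
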