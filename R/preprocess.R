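#' Re-reference a dyad recording to the earlobe average
#'
#' Subtracts the algebraic mean of the two reference channels from every
#' channel of each participant and drops the references from the montage.
#'
#' @param recording A `dyad_recording`.
#' @param reference_channels Labels of the two reference channels.
#' @param allow_missing If `TRUE` and the references are absent the
#'   recording is returned unchanged; otherwise their absence is an error.
#' @return The re-referenced `dyad_recording`.
#' @export
rereference <- function(recording, reference_channels = c("A1", "A2"),
                        allow_missing = FALSE) {
  labs <- recording$channel_labels
  present <- reference_channels %in% labs
  if (!all(present)) {
    if (allow_missing) return(recording)
    stop("reference channel(s) missing: ",
         paste(reference_channels[!present], collapse = ", "))
  }
  keep <- setdiff(labs, reference_channels)
  for (p in c("signals_p1", "signals_p2")) {
    sig <- recording[[p]]
    ref <- colMeans(sig[reference_channels, , drop = FALSE])
    sig <- sweep(sig[keep, , drop = FALSE], 2L, ref, "-")
    recording[[p]] <- sig
  }
  recording$channel_labels <- keep
  recording
}

# squared magnitude response of a digital Butterworth band-pass at the FFT
# bin frequencies of an n-sample record: the transfer function realized by
# forward-backward (zero-phase) filtering
butter_h2 <- function(n, fs, f_lo, f_hi, order = 4) {
  if (f_hi >= fs / 2) stop("band edge ", f_hi, " Hz at or above Nyquist")
  if (f_lo <= 0) stop("f_lo must be positive")
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1L) / n
  E <- exp(-1i * outer(w, seq(0, length(bf$b) - 1L)))
  H <- as.vector(E %*% bf$b) / as.vector(E %*% bf$a)
  Mod(H)^2
}

# zero-phase 4th-order Butterworth band-pass of a channel-by-time matrix,
# applied in the frequency domain (identical response to forward-backward
# time-domain filtering, with circular rather than reflected boundaries);
# records are zero-padded to a 2-3-5-smooth length for the FFT
filter_matrix <- function(x, fs, f_lo, f_hi, order = 4) {
  n <- ncol(x)
  np <- stats::nextn(n, c(2, 3, 5))
  xp <- cbind(x, matrix(0, nrow(x), np - n))
  h2 <- butter_h2(np, fs, f_lo, f_hi, order)
  out <- t(apply(xp, 1L,
                 function(ch) Re(fft(fft(ch) * h2, inverse = TRUE) / np)))
  out[, seq_len(n), drop = FALSE]
}

# band-passed Hilbert analytic signal in one pass: the band response and
# the one-sided spectrum doubling share a single inverse FFT per channel
analytic_band_matrix <- function(x, fs, f_lo, f_hi, order = 4) {
  analytic_bands_cached(x, fs, list(c(f_lo, f_hi)), order)[[1]]
}

# analytic signals for several bands with the forward FFT computed once
# per channel; returns a list of complex channel-by-time matrices
analytic_bands_cached <- function(x, fs, bands, order = 4) {
  n <- ncol(x)
  np <- stats::nextn(n, c(2, 3, 5))
  xp <- cbind(x, matrix(0, nrow(x), np - n))
  fx <- t(apply(xp, 1L, fft))
  hm <- hilbert_mask(np)
  lapply(bands, function(b) {
    h2 <- butter_h2(np, fs, b[1], b[2], order) * hm
    out <- t(apply(fx, 1L, function(ch) fft(ch * h2, inverse = TRUE) / np))
    out[, seq_len(n), drop = FALSE]
  })
}

hilbert_mask <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase, no group delay) to every channel of both participants.
#'
#' @param recording A `dyad_recording`.
#' @param f_lo,f_hi Band edges in Hz; `f_hi` must be below Nyquist.
#' @return The filtered `dyad_recording`.
#' @export
filter_band <- function(recording, f_lo, f_hi) {
  for (p in c("signals_p1", "signals_p2")) {
    lab <- rownames(recording[[p]])
    recording[[p]] <- filter_matrix(recording[[p]], recording$fs, f_lo, f_hi)
    rownames(recording[[p]]) <- lab
  }
  recording
}

#' Detect blink artifacts from the frontal channels
#'
#' Samples where `|Fp1|` or `|Fp2|` of either participant exceeds the
#' amplitude threshold are marked, the mark is dilated by `pad_s` on both
#' sides, and the resulting mask applies to every channel of both
#' participants.
#'
#' @param recording A `dyad_recording`.
#' @param amp_threshold_uV Absolute amplitude threshold (uV).
#' @param pad_s Dilation in seconds on each side of a suprathreshold sample.
#' @return Logical vector (length = samples); `TRUE` marks excluded samples.
#' @export
detect_blinks <- function(recording, amp_threshold_uV = 70, pad_s = 0.040) {
  fs <- recording$fs
  n <- ncol(recording$signals_p1)
  mask <- rep(FALSE, n)
  for (p in c("signals_p1", "signals_p2")) {
    sig <- recording[[p]]
    front <- intersect(c("Fp1", "Fp2"), rownames(sig))
    if (length(front) < 2L)
      stop("frontal channel(s) missing: ",
           paste(setdiff(c("Fp1", "Fp2"), front), collapse = ", "))
    hit <- apply(abs(sig[front, , drop = FALSE]) > amp_threshold_uV, 2L, any)
    mask <- mask | hit
  }
  pad <- as.integer(round(pad_s * fs))
  if (pad > 0 && any(mask)) {
    idx <- which(mask)
    lo <- pmax(1L, idx - pad)
    hi <- pmin(n, idx + pad)
    out <- rep(FALSE, n)
    for (k in seq_along(idx)) out[lo[k]:hi[k]] <- TRUE
    mask <- out
  }
  mask
}

# FFT analytic signal (one-sided spectrum doubling) per row
analytic_signal <- function(x) {
  one <- is.null(dim(x))
  if (one) x <- matrix(x, 1L)
  n <- ncol(x)
  np <- stats::nextn(n, c(2, 3, 5))
  xp <- cbind(x, matrix(0, nrow(x), np - n))
  h <- hilbert_mask(np)
  z <- t(apply(xp, 1L, function(ch) fft(fft(ch) * h, inverse = TRUE) / np))
  z <- z[, seq_len(n), drop = FALSE]
  if (one) z[1L, ] else z
}

#' Band-limited analytic-signal epochs
#'
#' Band-pass filters the recording, takes the Hilbert analytic signal, and
#' slices the analysis window (`window[1]` to `window[2]` seconds after
#' epoch onset) out of each trial. The epoch onset is the start of the
#' common tone-reproduction period; trials whose common period is shorter
#' than `window[2]` are excluded. Conditions retaining fewer than
#' `min_trials` valid trials flag the dyad invalid.
#'
#' @param recording A `dyad_recording` (re-referenced).
#' @param band Numeric `c(f_lo, f_hi)` in Hz or a band name.
#' @param window Analysis window in seconds relative to epoch onset.
#' @param mask Optional recording-level logical artifact mask (from
#'   [detect_blinks()]); sliced per trial and carried with the epochs.
#' @param min_trials Minimum valid trials per condition.
#' @param conditions Condition labels to epoch.
#' @return Object of class `"analytic_epochs_set"`: per condition an
#'   `"analytic_epochs"` list with complex arrays `p1`, `p2`
#'   (trial x channel x time), logical `mask` (trial x time), `n_valid`,
#'   plus `valid_dyad`, `band`, `window`, `fs`, `channel_labels`.
#' @export
epoch_analytic <- function(recording, band, window = c(0.5, 2.0),
                           mask = NULL, min_trials = 5L,
                           conditions = c("eye_contact", "control")) {
  if (is.character(band)) band <- frequency_bands(band)[[1]]
  fs <- recording$fs
  z1 <- analytic_band_matrix(recording$signals_p1, fs, band[1], band[2])
  z2 <- analytic_band_matrix(recording$signals_p2, fs, band[1], band[2])
  epoch_from_analytic(recording, z1, z2, window, mask, min_trials,
                      conditions, band)
}

# shared epoch slicing for analytic (complex) or raw (real) signals
epoch_from_analytic <- function(recording, z1, z2, window, mask, min_trials,
                                conditions, band) {
  fs <- recording$fs
  n <- ncol(z1)
  if (is.null(mask)) mask <- rep(FALSE, n)
  ev <- recording$events
  w0 <- as.integer(round(window[1] * fs))
  w1 <- as.integer(round(window[2] * fs))
  len <- w1 - w0
  out <- list()
  for (cond in conditions) {
    rows <- ev[ev$condition == cond, , drop = FALSE]
    keep <- (rows$offset - rows$onset) / fs >= window[2] &
      (rows$onset + w1 - 1L) <= n
    rows <- rows[keep, , drop = FALSE]
    nt <- nrow(rows)
    nch <- nrow(z1)
    fill <- if (is.complex(z1)) complex(real = 0) else 0
    a1 <- array(fill, c(nt, nch, len))
    a2 <- array(fill, c(nt, nch, len))
    m <- matrix(FALSE, nt, len)
    for (t in seq_len(nt)) {
      idx <- (rows$onset[t] + w0):(rows$onset[t] + w1 - 1L)
      a1[t, , ] <- z1[, idx]
      a2[t, , ] <- z2[, idx]
      m[t, ] <- mask[idx]
    }
    out[[cond]] <- structure(
      list(p1 = a1, p2 = a2, mask = m, condition = cond, n_valid = nt,
           band = band, window = window, fs = fs,
           channel_labels = recording$channel_labels),
      class = "analytic_epochs")
  }
  n_valid <- vapply(out, function(e) e$n_valid, integer(1))
  structure(list(epochs = out, valid_dyad = all(n_valid >= min_trials),
                 n_valid = n_valid, band = band, window = window, fs = fs,
                 channel_labels = recording$channel_labels,
                 dyad_id = recording$dyad_id, group = recording$group),
            class = "analytic_epochs_set")
}

# analytic epochs for several bands, sharing the forward FFT per channel
epoch_analytic_bands <- function(recording, bands, window = c(0.5, 2.0),
                                 mask = NULL, min_trials = 5L,
                                 conditions = c("eye_contact", "control")) {
  bl <- frequency_bands(bands)
  z1s <- analytic_bands_cached(recording$signals_p1, recording$fs, bl)
  z2s <- analytic_bands_cached(recording$signals_p2, recording$fs, bl)
  out <- lapply(seq_along(bl), function(i)
    epoch_from_analytic(recording, z1s[[i]], z2s[[i]], window, mask,
                        min_trials, conditions, bl[[i]]))
  names(out) <- bands
  out
}

#' Broadband time-domain epochs
#'
#' Like [epoch_analytic()] but returns real-valued broadband-filtered
#' epochs, as needed for cross-spectral (phase slope index) estimation.
#'
#' @inheritParams epoch_analytic
#' @param broadband Broadband filter edges in Hz.
#' @return As [epoch_analytic()], with real arrays.
#' @export
epoch_raw <- function(recording, broadband = c(0.5, 45),
                      window = c(0.5, 2.0), mask = NULL, min_trials = 5L,
                      conditions = c("eye_contact", "control")) {
  filt <- filter_band(recording, broadband[1], broadband[2])
  epoch_from_analytic(recording, filt$signals_p1, filt$signals_p2, window,
                      mask, min_trials, conditions, broadband)
}
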