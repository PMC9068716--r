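#' @name connectivity
#' @title Phase-synchronization estimators
#' @description
#' [ciplv_matrix()] computes the corrected imaginary phase-locking value for
#' every channel pair of the hyperbrain (both participants stacked): with
#' `z = mean(exp(1i * (phi_i - phi_j)))` pooled over unmasked samples of all
#' trials, `ciPLV = |Im(z)| / sqrt(1 - Re(z)^2)`, clipped to `[0, 1]`. Being
#' based on the imaginary part only, it discards zero-lag (volume-conducted)
#' synchronization. [plv_matrix()] returns the uncorrected `|z|`, exposed for
#' volume-conduction diagnostics. [psi_matrix()] computes the phase slope
#' index: segment-averaged Hanning-windowed cross-spectra give the complex
#' coherency `C_ij(f)`, the raw slope is
#' `Im(sum_f C*_ij(f) C_ij(f + df))` over the band's discrete frequencies,
#' and the result is normalized by its leave-one-segment-out jackknife
#' standard deviation. Positive `PSI[i, j]` means channel `i` temporally
#' precedes (drives) channel `j`; the matrix is antisymmetric by
#' construction.
NULL

# stack both participants' epochs into a (2N x samples) phase-carrier
# matrix, dropping masked samples; optionally pairs p1 of `e` with p2 of
# `e2` (mismatched-partner control), trimming to the common trial count
stack_epochs <- function(e, e2 = NULL) {
  p1 <- e$p1
  p2 <- (e2 %||% e)$p2
  m1 <- e$mask
  m2 <- (e2 %||% e)$mask
  nt <- min(dim(p1)[1], dim(p2)[1])
  len <- min(dim(p1)[3], dim(p2)[3])
  p1 <- p1[seq_len(nt), , seq_len(len), drop = FALSE]
  p2 <- p2[seq_len(nt), , seq_len(len), drop = FALSE]
  mask <- m1[seq_len(nt), seq_len(len), drop = FALSE] |
    m2[seq_len(nt), seq_len(len), drop = FALSE]
  # (ch x time x trial) -> ch x (time * trial)
  flat <- function(p) {
    p <- aperm(p, c(2, 3, 1))
    dim(p) <- c(dim(p)[1], dim(p)[2] * dim(p)[3])
    p
  }
  keep <- !as.vector(t(mask))
  x <- rbind(flat(p1), flat(p2))[, keep, drop = FALSE]
  labs <- e$channel_labels
  rownames(x) <- c(paste0("P1_", labs), paste0("P2_", labs))
  x
}

#' Corrected imaginary phase-locking value matrix
#'
#' @param epochs An `"analytic_epochs"` object (one condition) from
#'   [epoch_analytic()].
#' @param epochs2 Optional second `"analytic_epochs"`; if given, participant
#'   1 of `epochs` is paired with participant 2 of `epochs2` (used by the
#'   shuffled-pairs control).
#' @param min_samples Minimum unmasked pooled samples; below it all edges
#'   are returned missing (`NA`).
#' @return 2N x 2N symmetric matrix in `[0, 1]`, zero diagonal, dimnames
#'   `P1_<ch>` / `P2_<ch>`.
#' @rdname connectivity
#' @export
ciplv_matrix <- function(epochs, epochs2 = NULL, min_samples = 100L) {
  z <- mean_phasor(epochs, epochs2, min_samples)
  if (is.null(z$ok)) return(z$mat)
  re2 <- Re(z$mat)^2
  out <- abs(Im(z$mat)) / sqrt(pmax(1 - re2, 0))
  out[1 - re2 < 1e-12] <- 0  # constant zero-lag: no imaginary component
  out <- clip01(out)
  diag(out) <- 0
  dimnames(out) <- dimnames(z$mat)
  out
}

#' Uncorrected phase-locking value matrix
#'
#' @rdname connectivity
#' @export
plv_matrix <- function(epochs, epochs2 = NULL, min_samples = 100L) {
  z <- mean_phasor(epochs, epochs2, min_samples)
  if (is.null(z$ok)) return(z$mat)
  out <- Mod(z$mat)
  diag(out) <- 0
  dimnames(out) <- dimnames(z$mat)
  clip01(out)
}

# mean phase-difference phasor over pooled unmasked samples
mean_phasor <- function(epochs, epochs2, min_samples) {
  x <- stack_epochs(epochs, epochs2)
  s <- ncol(x)
  nch <- nrow(x)
  if (s < min_samples) {
    mat <- matrix(NA_real_, nch, nch,
                  dimnames = list(rownames(x), rownames(x)))
    return(list(mat = mat, ok = NULL))
  }
  ph <- x / Mod(x)
  ph[Mod(x) == 0] <- 0
  z <- ph %*% Conj(t(ph)) / s
  list(mat = z, ok = TRUE)
}

#' Phase slope index matrix
#'
#' @param epochs For `psi_matrix()`, an `"analytic_epochs"` object holding
#'   broadband time-domain epochs from [epoch_raw()].
#' @param band Numeric `c(f_lo, f_hi)` in Hz or a band name.
#' @param seg_len_s Spectral segment length in seconds (frequency
#'   resolution is `1/seg_len_s`).
#' @param overlap Fractional segment overlap within a trial window.
#' @param min_segments Minimum artifact-free segments (jackknife stability).
#' @rdname connectivity
#' @export
psi_matrix <- function(epochs, band, seg_len_s = 1, overlap = 0.5,
                       min_segments = 8L) {
  if (is.character(band)) band <- frequency_bands(band)[[1]]
  fs <- epochs$fs
  seg_len <- as.integer(round(seg_len_s * fs))
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  nt <- dim(epochs$p1)[1]
  len <- dim(epochs$p1)[3]
  if (seg_len > len)
    stop("segment length exceeds the analysis window")
  starts <- seq(1L, len - seg_len + 1L, by = step)
  labs <- epochs$channel_labels
  nch <- length(labs)
  segs <- list()
  for (t in seq_len(nt)) {
    for (s0 in starts) {
      idx <- s0:(s0 + seg_len - 1L)
      if (any(epochs$mask[t, idx])) next  # artifact-contaminated segment
      segs[[length(segs) + 1L]] <-
        rbind(Re(epochs$p1[t, , idx]), Re(epochs$p2[t, , idx]))
    }
  }
  if (length(segs) < min_segments)
    stop("fewer than ", min_segments, " clean segments (",
         length(segs), "); jackknife unstable")
  x <- array(unlist(segs), c(2L * nch, seg_len, length(segs)))
  out <- psi_core(x, fs, band)
  dimnames(out) <- list(c(paste0("P1_", labs), paste0("P2_", labs)),
                        c(paste0("P1_", labs), paste0("P2_", labs)))
  out
}

#' Phase slope index of a continuous multichannel signal
#'
#' Splits a channel-by-time matrix into overlapping segments and estimates
#' the jackknife-normalized phase slope index for every channel pair.
#'
#' @param x Channel-by-time numeric matrix.
#' @param fs Sampling rate in Hz.
#' @inheritParams psi_matrix
#' @return Antisymmetric channel-by-channel matrix.
#' @export
psi <- function(x, fs, band, seg_len_s = 1, overlap = 0.5,
                min_segments = 8L) {
  if (is.character(band)) band <- frequency_bands(band)[[1]]
  seg_len <- as.integer(round(seg_len_s * fs))
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, ncol(x) - seg_len + 1L, by = step)
  if (length(starts) < min_segments)
    stop("fewer than ", min_segments, " segments; jackknife unstable")
  xs <- array(0, c(nrow(x), seg_len, length(starts)))
  for (k in seq_along(starts))
    xs[, , k] <- x[, starts[k]:(starts[k] + seg_len - 1L)]
  out <- psi_core(xs, fs, band)
  dimnames(out) <- list(rownames(x), rownames(x))
  out
}

# core PSI estimator on a (ch x seg_len x n_seg) segment array
psi_core <- function(xs, fs, band) {
  nch <- dim(xs)[1]
  seg_len <- dim(xs)[2]
  ns <- dim(xs)[3]
  df <- fs / seg_len
  fall <- (seq_len(seg_len) - 1L) * df
  fbase <- which(fall >= band[1] & (fall + df) <= band[2])
  if (length(fbase) < 3L)
    stop("band holds fewer than 3 discrete frequencies at resolution ",
         df, " Hz")
  fneed <- sort(unique(c(fbase, fbase + 1L)))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(seg_len) - 1L) / (seg_len - 1L)))

  # windowed segment spectra at the needed frequencies: ch x freq x seg
  spec <- array(complex(real = 0), c(nch, length(fneed), ns))
  for (s in seq_len(ns)) {
    xw <- xs[, , s] * rep(w, each = nch)
    ft <- t(apply(xw, 1L, fft))
    spec[, , s] <- ft[, fneed, drop = FALSE]
  }

  cross_sum <- vector("list", length(fneed))   # sum over segments of X X^H
  outer_seg <- vector("list", length(fneed))   # per-segment outer products
  for (fi in seq_along(fneed)) {
    M <- spec[, fi, , drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, nch, ns)
    cross_sum[[fi]] <- M %*% Conj(t(M))
    outer_seg[[fi]] <- M
  }
  pos <- match(fbase, fneed)
  pos_next <- match(fbase + 1L, fneed)

  slope_from <- function(Slist) {
    acc <- matrix(complex(real = 0), nch, nch)
    for (k in seq_along(pos)) {
      C1 <- coherency(Slist[[pos[k]]])
      C2 <- coherency(Slist[[pos_next[k]]])
      acc <- acc + Conj(C1) * C2
    }
    Im(acc)
  }

  psi_raw <- slope_from(cross_sum)
  # leave-one-segment-out jackknife
  jk <- array(0, c(nch, nch, ns))
  for (s in seq_len(ns)) {
    Sm <- lapply(seq_along(fneed), function(fi) {
      m <- outer_seg[[fi]][, s]
      cross_sum[[fi]] - m %*% Conj(t(m))
    })
    jk[, , s] <- slope_from(Sm)
  }
  jm <- apply(jk, c(1, 2), mean)
  jvar <- apply(jk, c(1, 2), function(v) sum((v - mean(v))^2))
  jsd <- sqrt((ns - 1) / ns * jvar)
  out <- psi_raw / jsd
  out[jsd == 0] <- 0
  out <- (out - t(out)) / 2  # enforce exact antisymmetry against
                             # summation-order rounding in the BLAS
  zero_power <- apply(xs, 1L, function(ch) all(ch == 0))
  out[zero_power, ] <- NA_real_
  out[, zero_power] <- NA_real_
  diag(out) <- 0
  out
}

coherency <- function(S) {
  d <- Re(diag(S))
  den <- sqrt(pmax(d, 0) %o% pmax(d, 0))
  C <- S / den
  C[den == 0] <- 0
  C
}

#' Absolute and relative band power
#'
#' Mean squared analytic amplitude per channel in a band, and its fraction
#' of the broadband (0.5-45 Hz) power.
#'
#' @param x Channel-by-time matrix or a `dyad_recording`.
#' @param fs Sampling rate (ignored for recordings).
#' @param band Numeric `c(f_lo, f_hi)` in Hz or a band name.
#' @param total_band Broadband reference for relative power.
#' @return Data frame with `channel`, `absolute`, `relative` (and
#'   `participant` for recordings). Channels with zero total power get
#'   `NA` relative power.
#' @export
band_power <- function(x, fs = NULL, band = "gamma",
                       total_band = c(0.5, 45)) {
  if (is.character(band)) band <- frequency_bands(band)[[1]]
  if (inherits(x, "dyad_recording")) {
    res <- lapply(c(p1 = "signals_p1", p2 = "signals_p2"), function(p) {
      band_power(x[[p]], x$fs, band, total_band)
    })
    res$p1$participant <- "P1"
    res$p2$participant <- "P2"
    return(rbind(res$p1, res$p2))
  }
  stopifnot(!is.null(fs))
  absolute <-
    rowMeans(Mod(analytic_signal(filter_matrix(x, fs, band[1], band[2])))^2)
  # total power by Parseval over the broadband bins (one-sided, doubled to
  # match the squared-analytic-amplitude convention of `absolute`)
  n <- ncol(x)
  freqs <- (seq_len(n) - 1L) * fs / n
  keep <- freqs >= total_band[1] & freqs <= total_band[2]
  total <- apply(x, 1L, function(ch) {
    px <- Mod(fft(ch))^2 / n^2
    # x2 folds the one-sided spectrum, x2 matches the analytic convention
    4 * sum(px[keep])
  })
  relative <- ifelse(total > 0, absolute / total, NA_real_)
  data.frame(channel = rownames(x) %||% as.character(seq_len(nrow(x))),
             absolute = absolute, relative = relative,
             row.names = NULL, stringsAsFactors = FALSE)
}
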