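#' Standard 18-channel montage
#'
#' Channel labels of the extended 10-20 montage used throughout the package,
#' in their canonical order. Two earlobe reference channels ("A1", "A2") may
#' additionally be present in raw recordings and are removed by
#' [rereference()].
#'
#' @return Character vector of 18 channel labels.
#' @export
eeg_montage <- function() {
  c("P8", "F8", "F4", "C4", "T8", "P4", "Fp2", "Fp1", "Fz",
    "Cz", "Pz", "Oz", "P3", "F3", "F7", "C3", "T7", "P7")
}

#' Canonical frequency bands
#'
#' The five analysis bands: theta (4-8 Hz), alpha (8-12 Hz), lower beta
#' (13-20 Hz), upper beta (21-30 Hz) and gamma (30-45 Hz).
#'
#' @param names Optional subset of band names to return.
#' @return Named list; each element is `c(f_lo, f_hi)` in Hz.
#' @export
frequency_bands <- function(names = NULL) {
  bands <- list(
    theta      = c(4, 8),
    alpha      = c(8, 12),
    lower_beta = c(13, 20),
    upper_beta = c(21, 30),
    gamma      = c(30, 45)
  )
  if (is.null(names)) return(bands)
  missing <- setdiff(names, names(bands))
  if (length(missing))
    stop("unknown frequency band(s): ", paste(missing, collapse = ", "))
  bands[names]
}

#' Region-of-interest map
#'
#' Fixed grouping of the montage into 8 scalp regions: right/left frontal,
#' right/left parietal, right/left centro-temporal, midfrontal and
#' midposterior.
#'
#' @return Named character vector mapping channel label -> ROI code.
#' @export
roi_map <- function() {
  rois <- list(
    RF  = c("F4", "F8", "Fp2"),
    RP  = c("P8", "P4"),
    LF  = c("Fp1", "F7", "F3"),
    LP  = c("P3", "P7"),
    RCT = c("C4", "T8"),
    LCT = c("C3", "T7"),
    MF  = c("Fz", "Cz"),
    MP  = c("Pz", "Oz")
  )
  out <- rep(names(rois), lengths(rois))
  names(out) <- unlist(rois, use.names = FALSE)
  out[eeg_montage()]
}

#' Edge block labels of a hyperbrain matrix
#'
#' For a 2N x 2N matrix whose first N rows/columns are participant 1, label
#' every cell as `"intra1"`, `"intra2"` or `"inter"`.
#'
#' @param n_ch Channels per brain (N).
#' @return 2N x 2N character matrix.
#' @export
edge_blocks <- function(n_ch) {
  brain <- rep(c(1L, 2L), each = n_ch)
  out <- outer(brain, brain, function(a, b) {
    ifelse(a != b, "inter", ifelse(a == 1L, "intra1", "intra2"))
  })
  out
}
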