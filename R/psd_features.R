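# Band-power feature extraction: sliding-window Welch PSD sampled onto the
# 8-30 Hz / 2 Hz grid over the 8 centro-parietal channels -> 96-dim rows.

#' Conventional EEG frequency bands
#'
#' Metadata constants: delta (< 4 Hz), theta (4-8), alpha (8-14),
#' beta (14-40), gamma (> 40 Hz).
#'
#' @return Named list of `c(low, high)` pairs in Hz (gamma's high is `Inf`).
#' @export
band_definitions <- function() {
  list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 14),
       beta = c(14, 40), gamma = c(40, Inf))
}

#' Look up a conventional band's frequency range
#'
#' @param name Band name (`delta`, `theta`, `alpha`, `beta`, `gamma`).
#' @return `c(low, high)` in Hz.
#' @export
band_range <- function(name) {
  bands <- band_definitions()
  if (!name %in% names(bands)) {
    stop("unknown frequency band '", name, "'; known: ",
         paste(names(bands), collapse = ", "))
  }
  bands[[name]]
}

#' PSD feature-extraction configuration
#'
#' Defaults reproduce the competition feature layout: band power in 8-30 Hz at
#' 2 Hz resolution (12 bins at 8, 10, ..., 30 Hz) on the 8 centro-parietal
#' channels, computed 16 times per second (step 0.0625 s) over a 1 s sliding
#' window — 12 x 8 = 96 features per row. The spectral estimator is Welch's
#' segment-averaged periodogram with 0.5 s segments at 50% overlap (segment
#' length 1/resolution, so periodogram bins fall exactly on the 2 Hz grid),
#' per-segment mean removal, and a rectangular taper by default so a tone on
#' the bin grid concentrates its power in a single bin.
#'
#' @param band_low_hz,band_high_hz,resolution_hz Band edges and bin spacing.
#' @param window_s Sliding analysis window length (s); must be at least
#'   `1/resolution_hz`.
#' @param step_s Window step (s); default 0.0625 (16 windows per second).
#' @param channels Channels used, in feature order.
#' @param welch_segment_s Welch segment length (s); default `1/resolution_hz`.
#' @param welch_overlap_fraction Fractional overlap of successive segments.
#' @param taper `"rect"` (default) or `"hann"`.
#' @param detrend `"mean"` (subtract per-segment mean, default) or `"none"`.
#' @return A `psd_config` list.
#' @export
psd_config <- function(band_low_hz = 8, band_high_hz = 30, resolution_hz = 2,
                       window_s = 1.0, step_s = 0.0625,
                       channels = analysis_channels(),
                       welch_segment_s = 1 / resolution_hz,
                       welch_overlap_fraction = 0.5,
                       taper = c("rect", "hann"),
                       detrend = c("mean", "none")) {
  taper <- match.arg(taper)
  detrend <- match.arg(detrend)
  if (step_s <= 0) stop("step_s must be positive")
  if (window_s < 1 / resolution_hz) {
    stop("window_s must be at least 1/resolution_hz = ", 1 / resolution_hz, " s")
  }
  n_bins <- (band_high_hz - band_low_hz) / resolution_hz + 1
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("(band_high_hz - band_low_hz) must be a multiple of resolution_hz")
  }
  cfg <- list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
              resolution_hz = resolution_hz, window_s = window_s,
              step_s = step_s, channels = channels,
              welch_segment_s = welch_segment_s,
              welch_overlap_fraction = welch_overlap_fraction,
              taper = taper, detrend = detrend,
              bin_freqs = seq(band_low_hz, band_high_hz, by = resolution_hz))
  cfg$n_features <- length(cfg$bin_freqs) * length(channels)
  class(cfg) <- "psd_config"
  cfg
}

# Welch PSD of a single-channel segment matrix.  x: numeric vector; returns
# the one-sided density (unit^2/Hz) at frequencies k*fs/nseg, averaged over
# overlapping segments.
#' @keywords internal
#' @noRd
welch_psd <- function(x, fs, segment_s, overlap, taper = "rect", detrend = "mean") {
  n <- length(x)
  nseg <- round(segment_s * fs)
  if (nseg > n) nseg <- n
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  w <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / nseg)  # periodic Hann
  } else {
    rep(1, nseg)
  }
  segs <- vapply(starts, function(s) x[s:(s + nseg - 1L)], numeric(nseg))
  segs <- matrix(segs, nrow = nseg)
  if (detrend == "mean") segs <- sweep(segs, 2L, colMeans(segs))
  segs <- segs * w
  ft <- stats::mvfft(segs)
  scale <- 1 / (fs * sum(w^2))
  p <- rowMeans(Mod(ft)^2) * scale
  half <- floor(nseg / 2)
  freqs <- (0:half) * fs / nseg
  p <- p[1:(half + 1)]
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  dbl <- rep(2, half + 1)
  dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[half + 1] <- 1
  list(freq = freqs, psd = p * dbl)
}

#' Extract 96-dimensional PSD feature rows from a recording
#'
#' Slides a `window_s`-second window in steps of `step_s` over the recording;
#' for each window and configured channel, estimates the power spectral
#' density by Welch's method and samples/aggregates it onto the configured
#' frequency bins (periodogram values whose frequency falls within half a
#' resolution step of each bin center are averaged). Rows are ordered by
#' window start time, channel-major within a row (all bins of channel 1, then
#' channel 2, ...).
#'
#' Each row is labelled with the task annotation at the window's final
#' sample; windows spanning a task boundary are dropped.
#'
#' @param rec An [eeg_recording()] (typically the output of
#'   [surface_laplacian()]).
#' @param cfg A [psd_config()].
#' @return A [psd_feature_matrix()] (unlabelled when the recording carries no
#'   annotations).
#' @export
extract_psd <- function(rec, cfg = psd_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "psd_config"))
  absent <- setdiff(cfg$channels, rownames(rec$data))
  if (length(absent) > 0) {
    stop("configuration error: channel(s) absent from recording: ",
         paste(absent, collapse = ", "))
  }
  fs <- rec$rate_hz
  n <- ncol(rec$data)
  n_win <- round(cfg$window_s * fs)
  step <- max(1L, round(cfg$step_s * fs))
  if (n < n_win) {
    warning("recording shorter than one analysis window; empty feature matrix")
    return(psd_feature_matrix(matrix(numeric(0), 0, cfg$n_features),
                              labels = if (!is.null(rec$annotations)) character(0)))
  }
  starts <- seq(1L, n - n_win + 1L, by = step)
  nb <- length(cfg$bin_freqs)
  res2 <- cfg$resolution_hz / 2

  rows <- vector("list", length(starts))
  labs <- character(length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    s0 <- starts[i]; s1 <- s0 + n_win - 1L
    if (!is.null(rec$annotations)) {
      ann <- rec$annotations[s0:s1]
      if (length(unique(ann)) > 1) next  # spans a task boundary: drop
      labs[i] <- ann[n_win]
    }
    feat <- numeric(cfg$n_features)
    for (k in seq_along(cfg$channels)) {
      wp <- welch_psd(rec$data[cfg$channels[k], s0:s1], fs,
                      cfg$welch_segment_s, cfg$welch_overlap_fraction,
                      cfg$taper, cfg$detrend)
      for (j in seq_len(nb)) {
        f0 <- cfg$bin_freqs[j]
        sel <- wp$freq > f0 - res2 & wp$freq <= f0 + res2
        feat[(k - 1) * nb + j] <- if (any(sel)) mean(wp$psd[sel]) else 0
      }
    }
    rows[[i]] <- feat
    keep[i] <- TRUE
  }
  values <- do.call(rbind, rows[keep])
  if (is.null(values)) values <- matrix(numeric(0), 0, cfg$n_features)
  psd_feature_matrix(values,
                     labels = if (!is.null(rec$annotations)) labs[keep])
}
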