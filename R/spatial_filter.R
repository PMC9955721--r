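# Surface (small) Laplacian spatial filter.

#' Apply the surface Laplacian spatial filter
#'
#' For each requested channel, subtracts the unweighted mean of its montage
#' neighbors at every sample (the "small Laplacian"): a spatial high-pass
#' that sharpens local activity and rejects signal components common to a
#' neighborhood (reference drift, broad artifacts). Channels not requested
#' are dropped from the output; per-sample annotations are preserved.
#'
#' The filter is linear and maps any spatially uniform signal to zero.
#' Channels with fewer than two available neighbors are rejected rather than
#' zero-padded, so boundary effects never leak silently into band powers.
#'
#' @param rec An [eeg_recording()].
#' @param channels Channels to filter and keep (default: the 8 centro-parietal
#'   [analysis_channels()]).
#' @return An [eeg_recording()] restricted to `channels`, on a reduced montage
#'   retaining their positions (the neighbor relation of the output montage is
#'   recomputed among the kept channels and is not used further).
#' @export
surface_laplacian <- function(rec, channels = analysis_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  mont <- rec$montage
  missing_ch <- setdiff(channels, mont$labels)
  if (length(missing_ch) > 0) {
    stop("montage error: channel(s) not in montage: ",
         paste(missing_ch, collapse = ", "))
  }
  out <- matrix(0, length(channels), ncol(rec$data),
                dimnames = list(channels, NULL))
  for (ch in channels) {
    nb <- mont$neighbors[[ch]]
    if (length(nb) < 2) {
      stop("configuration error: channel ", ch, " has ", length(nb),
           " neighbor(s); >= 2 required for the surface Laplacian")
    }
    absent <- setdiff(nb, rownames(rec$data))
    if (length(absent) > 0) {
      stop("montage error: neighbor(s) of ", ch, " missing from recording: ",
           paste(absent, collapse = ", "))
    }
    out[ch, ] <- rec$data[ch, ] - colMeans(rec$data[nb, , drop = FALSE])
  }
  keep <- match(channels, mont$labels)
  sub_mont <- montage(channels, mont$positions[keep, , drop = FALSE],
                      neighbors = stats::setNames(
                        rep(list(character(0)), length(channels)), channels))
  eeg_recording(out, rec$rate_hz, sub_mont, rec$annotations)
}
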