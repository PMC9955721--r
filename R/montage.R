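# Electrode montages: 10-20 labels, schematic 2D scalp positions, and the
# neighbor tables consumed by the surface Laplacian.

#' Construct an electrode montage
#'
#' A montage is a set of named 10-20 electrode positions on a schematic 2D
#' scalp grid plus a symmetric neighbor relation. When `neighbors` is not
#' supplied it is derived from the positions: two electrodes are neighbors
#' when their distance is at most `radius_factor` times the minimum
#' inter-electrode spacing, which on the default unit grid yields the
#' 4-neighborhood (anterior/posterior/left/right nearest electrodes). The
#' derived table is stored explicitly so it can be inspected or edited.
#'
#' @param labels Character vector of unique electrode names.
#' @param positions Numeric matrix, one row per electrode, columns x
#'   (left-negative/right-positive) and y (posterior-negative/anterior-positive),
#'   unitless scheme.
#' @param neighbors Optional named list mapping each label to a character
#'   vector of neighbor labels; must be symmetric.
#' @param radius_factor Neighbor cutoff as a multiple of the minimum spacing.
#' @return An object of class `eeg_montage`.
#' @export
montage <- function(labels, positions, neighbors = NULL, radius_factor = 1.3) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("montage labels must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(labels) || ncol(positions) != 2) {
    stop("positions must be a ", length(labels), " x 2 matrix")
  }
  rownames(positions) <- labels
  if (is.null(neighbors)) {
    d <- as.matrix(stats::dist(positions))
    cutoff <- radius_factor * min(d[d > 0])
    neighbors <- lapply(labels, function(l) {
      nb <- labels[d[l, ] > 0 & d[l, ] <= cutoff]
      nb[order(d[l, nb])]
    })
    names(neighbors) <- labels
  } else {
    if (!setequal(names(neighbors), labels)) stop("neighbors must name every label")
    for (l in labels) {
      for (nb in neighbors[[l]]) {
        if (!nb %in% labels) stop("neighbor '", nb, "' of '", l, "' not in montage")
        if (!l %in% neighbors[[nb]]) {
          stop("neighbor relation not symmetric: ", l, " -> ", nb)
        }
      }
    }
  }
  structure(list(labels = labels, positions = positions, neighbors = neighbors),
            class = "eeg_montage")
}

#' The 8 centro-parietal analysis channels
#'
#' The channel set whose band powers form the 96-dimensional feature rows.
#' @export
analysis_channels <- function() c("C3", "Cz", "C4", "CP1", "CP2", "P3", "Pz", "P4")

#' Default 32-channel 10-20 montage
#'
#' A 32-electrode superset of the 8 centro-parietal analysis channels laid out
#' on a schematic unit grid, chosen so that every analysis channel has its
#' full 4-neighborhood available for the surface Laplacian (e.g. C3's
#' neighbors are FC1, Cz, CP1 and T7).
#'
#' @return An `eeg_montage`.
#' @export
default_montage <- function() {
  rows <- list(
    c("Fp1", -1, 3), c("Fp2", 1, 3),
    c("F7", -2, 2), c("F3", -1, 2), c("Fz", 0, 2), c("F4", 1, 2), c("F8", 2, 2),
    c("FC5", -2, 1), c("FC1", -1, 1), c("FCz", 0, 1), c("FC2", 1, 1), c("FC6", 2, 1),
    c("T7", -2, 0), c("C3", -1, 0), c("Cz", 0, 0), c("C4", 1, 0), c("T8", 2, 0),
    c("CP5", -2, -1), c("CP1", -1, -1), c("CPz", 0, -1), c("CP2", 1, -1), c("CP6", 2, -1),
    c("P7", -2, -2), c("P3", -1, -2), c("Pz", 0, -2), c("P4", 1, -2), c("P8", 2, -2),
    c("PO7", -2, -3), c("PO3", -1, -3), c("POz", 0, -3), c("PO4", 1, -3), c("PO8", 2, -3)
  )
  labels <- vapply(rows, `[[`, "", 1)
  pos <- cbind(as.numeric(vapply(rows, `[[`, "", 2)),
               as.numeric(vapply(rows, `[[`, "", 3)))
  montage(labels, pos)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$labels), " electrodes: ",
      paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Construct a raw EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts; row count
#'   must equal the montage's electrode count (rows follow montage order).
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param montage An `eeg_montage`.
#' @param annotations Optional per-sample task code (character, canonical
#'   class names) or `NULL` when unlabelled.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate_hz, montage, annotations = NULL) {
  data <- as.matrix(data)
  if (!inherits(montage, "eeg_montage")) stop("montage must be an eeg_montage")
  if (nrow(data) != length(montage$labels)) {
    stop("data has ", nrow(data), " rows but montage has ",
         length(montage$labels), " electrodes")
  }
  if (rate_hz <= 0) stop("rate_hz must be positive")
  rownames(data) <- montage$labels
  if (!is.null(annotations)) {
    annotations <- as.character(annotations)
    if (length(annotations) != ncol(data)) {
      stop("annotations must have one entry per sample")
    }
  }
  structure(list(data = data, rate_hz = rate_hz, montage = montage,
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$rate_hz, " Hz (",
      round(ncol(x$data) / x$rate_hz, 2), " s)\n", sep = "")
  invisible(x)
}
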