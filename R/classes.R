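# Core containers: PSD feature matrices and per-subject session bundles.

#' Canonical task classes
#'
#' The three imagined mental tasks, in the canonical order used throughout the
#' package: left-hand movement imagery, right-hand movement imagery, word
#' generation. All sorting, averaging, confusion matrices and classifier
#' outputs use this order.
#'
#' @export
task_classes <- function() c("left", "right", "word")

#' Default task-label code map
#'
#' Ordered mapping from canonical class names to the integer codes used in the
#' competition-style ASCII feature files. Files may use any 3-symbol integer
#' alphabet; pass a different named vector to [read_psd_ascii()] /
#' [write_psd_ascii()] to override.
#'
#' @return Named integer vector (names `left`, `right`, `word`).
#' @export
default_label_map <- function() c(left = 2L, right = 3L, word = 7L)

#' Construct a PSD feature matrix
#'
#' The unit of analysis: one row per PSD sample. For the default pipeline
#' configuration each row has 96 columns, ordered channel-major — for each of
#' the 8 centro-parietal channels (C3, Cz, C4, CP1, CP2, P3, Pz, P4) the 12
#' band-power values at 8, 10, ..., 30 Hz.
#'
#' @param values Numeric matrix, rows = PSD samples. All entries must be
#'   finite; negative entries trigger a validation warning but are retained
#'   (data are never silently altered).
#' @param labels Optional character vector of canonical class names (see
#'   [task_classes()]), one per row. `NULL` for unlabelled data.
#' @param subject_id,session_id Opaque identifiers.
#' @return An object of class `psd_feature_matrix`.
#' @export
psd_feature_matrix <- function(values, labels = NULL, subject_id = NA_character_,
                               session_id = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) > 0 && any(!is.finite(values))) {
    stop("PSD feature values must all be finite")
  }
  if (nrow(values) > 0 && any(values < 0)) {
    warning("negative PSD values present; retained unmodified")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values)) {
      stop("labels length (", length(labels), ") != number of rows (", nrow(values), ")")
    }
    bad <- setdiff(unique(labels), task_classes())
    if (length(bad) > 0) {
      stop("unknown task labels: ", paste(bad, collapse = ", "))
    }
  }
  structure(
    list(values = values, labels = labels,
         subject_id = subject_id, session_id = session_id),
    class = "psd_feature_matrix"
  )
}

#' @export
print.psd_feature_matrix <- function(x, ...) {
  cat("<psd_feature_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " features", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = task_classes()))
    cat("  [", paste(names(tab), tab, sep = ":", collapse = " "), "]", sep = "")
  }
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id)
  cat("\n")
  invisible(x)
}

#' @export
dim.psd_feature_matrix <- function(x) dim(x$values)

#' Bundle the training sessions of one subject
#'
#' @param subject_id Identifier shared by all sessions.
#' @param sessions Ordered list of [psd_feature_matrix()] objects (at least one).
#' @return An object of class `subject_sessions`.
#' @export
subject_sessions <- function(subject_id, sessions) {
  if (length(sessions) < 1) stop("at least one session required")
  for (s in sessions) {
    if (!inherits(s, "psd_feature_matrix")) stop("sessions must be psd_feature_matrix objects")
    if (!is.na(s$subject_id) && s$subject_id != subject_id) {
      stop("session subject_id '", s$subject_id, "' differs from '", subject_id, "'")
    }
  }
  structure(list(subject_id = subject_id, sessions = sessions),
            class = "subject_sessions")
}

#' @export
print.subject_sessions <- function(x, ...) {
  cat("<subject_sessions> subject ", x$subject_id, ": ",
      length(x$sessions), " session(s), ",
      paste(vapply(x$sessions, function(s) nrow(s$values), 1L), collapse = "/"),
      " rows\n", sep = "")
  invisible(x)
}

# Concatenate the rows of several psd_feature_matrix objects.
#' @keywords internal
#' @noRd
rbind_psd <- function(mats, subject_id = NA_character_) {
  values <- do.call(rbind, lapply(mats, function(m) m$values))
  labels <- if (all(vapply(mats, function(m) !is.null(m$labels), TRUE))) {
    unlist(lapply(mats, function(m) m$labels), use.names = FALSE)
  }
  psd_feature_matrix(values, labels, subject_id = subject_id)
}
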