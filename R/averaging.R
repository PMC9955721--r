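# Task-sorting, within-subject session averaging, cross-subject averaging,
# LOSO fold construction, and (optional, leakage-flagged) test-time averaging.

#' Stable task-sort of a PSD feature matrix
#'
#' Re-arranges rows by task class in the canonical (left, right, word) order,
#' preserving the original order within each class. The original row indices
#' are attached as the `provenance` attribute.
#'
#' @param m A labelled [psd_feature_matrix()].
#' @return The sorted [psd_feature_matrix()].
#' @export
sort_by_task <- function(m) {
  stopifnot(inherits(m, "psd_feature_matrix"))
  if (is.null(m$labels)) stop("sort_by_task requires labels")
  cls <- match(m$labels, task_classes())
  if (anyNA(cls)) {
    stop("unmapped label value(s): ",
         paste(unique(m$labels[is.na(cls)]), collapse = ", "))
  }
  ord <- order(cls)  # radix sort: stable
  out <- psd_feature_matrix(m$values[ord, , drop = FALSE], m$labels[ord],
                            subject_id = m$subject_id, session_id = m$session_id)
  attr(out, "provenance") <- ord
  out
}

# Split a task-sorted (or any labelled) matrix into per-class blocks.
#' @keywords internal
#' @noRd
class_blocks <- function(m) {
  lapply(stats::setNames(task_classes(), task_classes()), function(cl) {
    idx <- which(m$labels == cl)
    list(values = m$values[idx, , drop = FALSE], rows = idx)
  })
}

# Task-wise aligned mean of several labelled matrices: per class, truncate to
# the minimum per-class row count, then element-wise mean of aligned rows.
# Provenance: for each output row, the contributing (source, original row).
#' @keywords internal
#' @noRd
average_labelled_matrices <- function(mats, source_ids, require_all_classes = TRUE) {
  stopifnot(length(mats) >= 1, length(mats) == length(source_ids))
  blocks <- lapply(mats, class_blocks)
  out_vals <- list(); out_labs <- character(0); prov <- list()
  for (cl in task_classes()) {
    counts <- vapply(blocks, function(b) nrow(b[[cl]]$values), 1L)
    if (any(counts == 0)) {
      if (require_all_classes) {
        miss <- source_ids[counts == 0]
        stop("class '", cl, "' absent from: ", paste(miss, collapse = ", "))
      }
      next
    }
    n <- min(counts)
    acc <- matrix(0, n, ncol(mats[[1]]$values))
    for (b in blocks) acc <- acc + b[[cl]]$values[seq_len(n), , drop = FALSE]
    acc <- acc / length(blocks)
    out_vals[[cl]] <- acc
    out_labs <- c(out_labs, rep(cl, n))
    for (i in seq_len(n)) {
      prov[[length(prov) + 1L]] <- data.frame(
        source = source_ids,
        class = cl,
        original_row = vapply(blocks, function(b) b[[cl]]$rows[i], 1L)
      )
    }
  }
  feat <- psd_feature_matrix(do.call(rbind, out_vals), out_labs)
  list(features = feat, provenance = prov)
}

#' Within-subject session averaging
#'
#' For each task class, truncates every session's class block to the minimum
#' per-class row count across the subject's sessions, then takes the
#' element-wise mean of aligned rows (row i of a class averaged across
#' sessions). The alternative reading — concatenating the sessions instead of
#' averaging them — is available via `mode = "concat"`.
#'
#' @param s A [subject_sessions()] whose sessions are labelled.
#' @param mode `"average"` (default) or `"concat"`.
#' @return A labelled [psd_feature_matrix()] for the subject, with a
#'   `provenance` attribute (list of per-row contribution data frames for
#'   `"average"`).
#' @export
within_subject_average <- function(s, mode = c("average", "concat")) {
  stopifnot(inherits(s, "subject_sessions"))
  mode <- match.arg(mode)
  sorted <- lapply(s$sessions, sort_by_task)
  if (mode == "concat") {
    out <- sort_by_task(rbind_psd(sorted, subject_id = s$subject_id))
    return(out)
  }
  res <- tryCatch(
    average_labelled_matrices(sorted, paste0(s$subject_id, "/session",
                                             seq_along(sorted))),
    error = function(e) stop("subject ", s$subject_id, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  out <- res$features
  out$subject_id <- s$subject_id
  attr(out, "provenance") <- res$provenance
  out
}

#' Pairwise cross-subject averaging
#'
#' Task-wise mean of two subjects' (task-sorted, labelled) feature matrices:
#' left rows are averaged with left rows, right with right, word with word,
#' pairing by within-class row index and truncating to the shorter class
#' block. This builds the training files of the subject-independent scheme.
#'
#' @param a,b Labelled [psd_feature_matrix()] objects (typically the outputs
#'   of [within_subject_average()]).
#' @return An `averaged_training_set`: list with `features` (labelled
#'   [psd_feature_matrix()]) and `provenance` (per-row contribution data
#'   frames, each class-pure).
#' @export
pairwise_subject_average <- function(a, b) {
  average_subjects(list(a, b))
}

#' Task-wise average across k subjects
#'
#' Generalization of [pairwise_subject_average()] to any number of training
#' subjects: element-wise mean across all k aligned class blocks.
#'
#' @param mats List of labelled [psd_feature_matrix()] objects.
#' @return An `averaged_training_set` (see [pairwise_subject_average()]).
#' @export
average_subjects <- function(mats) {
  stopifnot(length(mats) >= 1)
  sorted <- lapply(mats, sort_by_task)
  ids <- vapply(seq_along(mats), function(i) {
    id <- mats[[i]]$subject_id
    if (is.na(id)) paste0("input", i) else id
  }, "")
  res <- average_labelled_matrices(sorted, ids)
  # invariant: every provenance set is class-pure
  stopifnot(all(vapply(res$provenance,
                       function(p) length(unique(p$class)) == 1, TRUE)))
  structure(list(features = res$features, provenance = res$provenance),
            class = "averaged_training_set")
}

#' LOSO fold specification
#'
#' @param fold_id Integer fold index.
#' @param train_subjects Character vector of training subject ids.
#' @param test_subject Held-out subject id (never in `train_subjects`).
#' @param averaging_mode `"train_averaged"` or `"none"`.
#' @param test_averaging `"off"` or `"label_matched"` (the latter uses true
#'   test labels and is always flagged as leakage in reports).
#' @return A `fold_spec`.
#' @export
fold_spec <- function(fold_id, train_subjects, test_subject,
                      averaging_mode = c("train_averaged", "none"),
                      test_averaging = c("off", "label_matched")) {
  averaging_mode <- match.arg(averaging_mode)
  test_averaging <- match.arg(test_averaging)
  if (test_subject %in% train_subjects) {
    stop("test subject must not appear among training subjects")
  }
  structure(list(fold_id = fold_id, train_subjects = train_subjects,
                 test_subject = test_subject, averaging_mode = averaging_mode,
                 test_averaging = test_averaging),
            class = "fold_spec")
}

#' Build leave-one-subject-out folds
#'
#' One fold per subject as the held-out test set; all remaining subjects form
#' the training set (task-wise averaged across the k training subjects when
#' `averaging_mode = "train_averaged"`; for 3 subjects this is the pairwise
#' average).
#'
#' @param cohort List of [subject_sessions()] (>= 3 subjects), or a character
#'   vector of subject ids.
#' @param averaging_mode,test_averaging See [fold_spec()].
#' @return List of [fold_spec()] objects.
#' @export
build_loso_folds <- function(cohort, averaging_mode = "train_averaged",
                             test_averaging = "off") {
  ids <- if (is.character(cohort)) cohort else {
    vapply(cohort, function(s) s$subject_id, "")
  }
  if (length(ids) < 3) stop("LOSO requires at least 3 subjects")
  lapply(seq_along(ids), function(i) {
    fold_spec(i, ids[-i], ids[i], averaging_mode, test_averaging)
  })
}

#' Test-time averaging (optional, leakage-flagged)
#'
#' Reproduces the configuration in which the test subject's PSD rows are
#' averaged with the training data before classification: in
#' `"label_matched"` mode each test row is replaced by the mean of itself and
#' the training per-class mean vector of its TRUE class. Because this uses
#' true test labels, the output carries `uses_test_labels = TRUE` and every
#' downstream report is flagged as leaking label information. `"off"` is the
#' identity.
#'
#' @param test A labelled [psd_feature_matrix()].
#' @param train_class_means Named list (per class) of mean feature vectors
#'   from the training set.
#' @param mode `"off"` or `"label_matched"`.
#' @return A [psd_feature_matrix()]; in `label_matched` mode with attribute
#'   `uses_test_labels = TRUE`.
#' @export
test_time_average <- function(test, train_class_means,
                              mode = c("off", "label_matched")) {
  mode <- match.arg(mode)
  if (mode == "off") return(test)
  if (is.null(test$labels)) stop("label_matched averaging requires test labels")
  miss <- setdiff(unique(test$labels), names(train_class_means))
  if (length(miss) > 0) {
    stop("training class mean missing for: ", paste(miss, collapse = ", "))
  }
  vals <- test$values
  for (i in seq_len(nrow(vals))) {
    vals[i, ] <- (vals[i, ] + train_class_means[[test$labels[i]]]) / 2
  }
  out <- psd_feature_matrix(vals, test$labels, subject_id = test$subject_id,
                            session_id = test$session_id)
  attr(out, "uses_test_labels") <- TRUE
  out
}

# Per-class mean feature vectors of a labelled matrix.
#' @keywords internal
#' @noRd
class_means <- function(m) {
  lapply(stats::setNames(task_classes(), task_classes()), function(cl) {
    idx <- which(m$labels == cl)
    if (length(idx) == 0) return(NULL)
    colMeans(m$values[idx, , drop = FALSE])
  })
}
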