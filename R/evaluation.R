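# Confusion matrices, the precision/recall/F1/accuracy metric suite with
# micro/macro/weighted aggregation, LOSO experiment orchestration, and the
# input-criteria comparison table.

#' Build a 3x3 confusion matrix
#'
#' Rows are actual classes, columns predicted classes, both in canonical
#' (left, right, word) order.
#'
#' @param y_true,y_pred Equal-length vectors of canonical class names.
#' @param classes Class alphabet (default [task_classes()]).
#' @return A `confusion_matrix` (integer matrix with dimnames).
#' @export
confusion <- function(y_true, y_pred, classes = task_classes()) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tt <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  cm <- matrix(as.integer(tt), length(classes), length(classes),
               dimnames = list(actual = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Wrap a printed/counted matrix as a confusion matrix
#'
#' @param counts Square matrix of non-negative counts, rows = actual,
#'   columns = predicted, in canonical class order.
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  cls <- task_classes()[seq_len(nrow(counts))]
  dimnames(counts) <- list(actual = cls, predicted = cls)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Metric suite from a confusion matrix
#'
#' One-vs-rest Tp/Fp/Fn/Tn per class, per-class precision, recall and F1,
#' and three aggregations: micro (pool the one-vs-rest counts), macro
#' (unweighted mean of per-class values) and weighted (support-weighted
#' mean). Accuracy is the diagonal fraction. For single-label multiclass
#' data the pooled (micro) true-positive rate is identical to accuracy, and
#' for C classes the pooled true-negative rate is
#' `((C-2)*N + sum(diag)) / ((C-1)*N)` — for 3 classes, `(1 + accuracy)/2`;
#' both identities are asserted on every report. Metrics with a zero
#' denominator are defined as 0 and flagged.
#'
#' @param cm A `confusion_matrix` (or plain square count matrix).
#' @param aggregation Which aggregation to label as the report's headline:
#'   `"micro"` (default), `"macro"` or `"weighted"`; all three are computed.
#' @param leakage_flag Propagated marker that test-label information entered
#'   the pipeline (see [test_time_average()]).
#' @param fold_id Optional fold identifier.
#' @return A `metrics_report`: `per_class` data frame, `micro`/`macro`/
#'   `weighted` precision-recall-F1 lists, `accuracy`, `micro_tpr`,
#'   `micro_tnr`, `zero_division` flag, `leakage_flag`, `fold_id`.
#' @export
metrics_from_confusion <- function(cm, aggregation = c("micro", "macro", "weighted"),
                                   leakage_flag = FALSE, fold_id = NA_integer_) {
  aggregation <- match.arg(aggregation)
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  C <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp

  zero_div <- FALSE
  safe_div <- function(num, den) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0)) zero_div <<- TRUE
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  support <- rowSums(cm)
  per_class <- data.frame(class = rownames(cm), tp = tp, fp = fp, fn = fn,
                          tn = tn, precision = precision, recall = recall,
                          f1 = f1, support = support, row.names = NULL)

  micro_p <- safe_div(sum(tp), sum(tp + fp))
  micro_r <- safe_div(sum(tp), sum(tp + fn))
  micro <- list(precision = micro_p, recall = micro_r,
                f1 = safe_div(2 * micro_p * micro_r, micro_p + micro_r))
  macro <- list(precision = mean(precision), recall = mean(recall),
                f1 = mean(f1))
  wts <- support / total
  weighted <- list(precision = sum(wts * precision), recall = sum(wts * recall),
                   f1 = sum(wts * f1))

  accuracy <- sum(tp) / total
  micro_tpr <- safe_div(sum(tp), sum(tp + fn))
  micro_tnr <- safe_div(sum(tn), sum(tn + fp))
  # identities for single-label multiclass data
  stopifnot(abs(micro_tpr - accuracy) < 1e-12)
  stopifnot(abs(micro_tnr - ((C - 2) * total + sum(tp)) / ((C - 1) * total)) < 1e-12)

  structure(list(per_class = per_class, micro = micro, macro = macro,
                 weighted = weighted, accuracy = accuracy,
                 micro_tpr = micro_tpr, micro_tnr = micro_tnr,
                 aggregation = aggregation, zero_division = zero_div,
                 leakage_flag = leakage_flag, fold_id = fold_id),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  agg <- x[[x$aggregation]]
  cat("<metrics_report> accuracy ", sprintf("%.4f", x$accuracy),
      " | ", x$aggregation, " P/R/F1 ",
      sprintf("%.4f/%.4f/%.4f", agg$precision, agg$recall, agg$f1), sep = "")
  if (isTRUE(x$leakage_flag)) cat("  [LEAKAGE: uses test labels]")
  cat("\n")
  invisible(x)
}

#' LOSO pipeline configuration
#'
#' @param averaging_mode `"train_averaged"` (task-wise average the training
#'   subjects, the subject-independent scheme) or `"none"` (plain
#'   concatenation of training subjects' rows).
#' @param test_averaging `"off"` (default) or `"label_matched"`; the latter
#'   averages each test row with the training mean of its true class and is
#'   always flagged as label leakage in reports.
#' @param within_subject `"average"` or `"concat"`: how each subject's
#'   sessions are combined before cross-subject averaging.
#' @param pca_retain,pca_k Explained-variance fraction (default 0.95) or
#'   exact component count for the per-fold PCA.
#' @param mlp An [mlp_config()].
#' @param seed Master seed; per-fold classifier seeds are split from it.
#' @return A `loso_config`.
#' @export
loso_config <- function(averaging_mode = c("train_averaged", "none"),
                        test_averaging = c("off", "label_matched"),
                        within_subject = c("average", "concat"),
                        pca_retain = 0.95, pca_k = NULL,
                        mlp = mlp_config(), seed = 1) {
  structure(list(averaging_mode = match.arg(averaging_mode),
                 test_averaging = match.arg(test_averaging),
                 within_subject = match.arg(within_subject),
                 pca_retain = pca_retain, pca_k = pca_k,
                 mlp = mlp, seed = as.integer(seed)),
            class = "loso_config")
}

#' Run the full leave-one-subject-out experiment
#'
#' For every fold (each subject held out once): combine and optionally
#' task-wise average the training subjects' features, fit PCA on the training
#' rows only, project train and test, train the MLP, predict the held-out
#' subject, and report a confusion matrix plus metric suite. A provenance
#' audit asserts that the held-out subject contributed to no training-stage
#' artifact; a fold whose pipeline fails is marked failed with its diagnostic
#' and the run continues.
#'
#' @param cohort List of [subject_sessions()] with labelled feature matrices
#'   (e.g. from [cohort_features()]); >= 3 subjects.
#' @param config A [loso_config()].
#' @return A `loso_result`: `folds` (per fold: `fold`, `confusion`,
#'   `metrics`, sizes, `pca_k`, `audit_pass`, or `error`), `mean_accuracy`
#'   (unweighted mean over successful folds), `config`, `leakage_flag`.
#' @export
run_loso <- function(cohort, config = loso_config()) {
  stopifnot(inherits(config, "loso_config"))
  folds <- build_loso_folds(cohort, config$averaging_mode, config$test_averaging)
  ids <- vapply(cohort, function(s) s$subject_id, "")
  fold_seeds <- split_seed(config$seed, length(folds))
  leak <- config$test_averaging == "label_matched"

  results <- lapply(seq_along(folds), function(i) {
    fs <- folds[[i]]
    tryCatch({
      train_ss <- cohort[match(fs$train_subjects, ids)]
      test_ss <- cohort[[match(fs$test_subject, ids)]]

      if (config$averaging_mode == "train_averaged") {
        per_subj <- lapply(train_ss, within_subject_average,
                           mode = config$within_subject)
        avg <- average_subjects(per_subj)
        train <- avg$features
        prov_sources <- unique(unlist(lapply(avg$provenance, function(p) p$source)))
      } else {
        train <- sort_by_task(rbind_psd(
          lapply(train_ss, function(s) rbind_psd(s$sessions, s$subject_id))))
        prov_sources <- fs$train_subjects
      }

      test <- rbind_psd(test_ss$sessions, test_ss$subject_id)
      test <- test_time_average(test, class_means(train), fs$test_averaging)

      # provenance audit: held-out subject absent from all training sources
      audit_pass <- !any(grepl(fs$test_subject, prov_sources, fixed = TRUE))
      if (!audit_pass) stop("provenance audit failed: test subject ",
                            fs$test_subject, " present in training artifacts")

      pca <- fit_pca(train, retain = config$pca_retain, k = config$pca_k)
      tr_scores <- predict(pca, train)
      te_scores <- predict(pca, test)

      cfg <- config$mlp
      cfg$seed <- fold_seeds[i]
      model <- init_mlp(ncol(tr_scores), cfg)
      model <- train_mlp(model, tr_scores, train$labels, cfg)
      pred <- predict(model, te_scores)

      cm <- confusion(test$labels, pred)
      rep <- metrics_from_confusion(cm, leakage_flag = leak, fold_id = fs$fold_id)
      list(fold = fs, confusion = cm, metrics = rep,
           n_train = nrow(train$values), n_test = nrow(test$values),
           pca_k = pca$n_components_retained, audit_pass = audit_pass,
           history = model$history, error = NULL)
    }, error = function(e) {
      list(fold = fs, confusion = NULL, metrics = NULL, n_train = NA,
           n_test = NA, pca_k = NA, audit_pass = NA, history = NULL,
           error = conditionMessage(e))
    })
  })
  ok <- !vapply(results, function(r) is.null(r$metrics), TRUE)
  mean_acc <- if (any(ok)) {
    mean(vapply(results[ok], function(r) r$metrics$accuracy, 1))
  } else NA_real_
  structure(list(folds = results, mean_accuracy = mean_acc,
                 config = config, leakage_flag = leak),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("<loso_result> ", length(x$folds), " folds, mean accuracy ",
      sprintf("%.4f", x$mean_accuracy),
      " (", x$config$averaging_mode, ")", sep = "")
  if (isTRUE(x$leakage_flag)) cat("  [LEAKAGE: uses test labels]")
  cat("\n")
  for (r in x$folds) {
    if (is.null(r$error)) {
      cat("  test ", r$fold$test_subject, ": accuracy ",
          sprintf("%.4f", r$metrics$accuracy), "\n", sep = "")
    } else {
      cat("  test ", r$fold$test_subject, ": FAILED (", r$error, ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Input-criteria comparison table
#'
#' Runs [run_loso()] under each supplied configuration and tabulates, per
#' test subject and configuration, the accuracy and macro precision, recall
#' and F1, with the leakage flag per row — the layout of the averaging
#' ablation study. Full per-fold results are attached as the `results`
#' attribute; the tabulated metrics are recomputed from the stored confusion
#' matrices.
#'
#' @param cohort As in [run_loso()].
#' @param configs Named list of >= 2 [loso_config()] objects.
#' @return A data frame (configs x subjects rows).
#' @export
compare_input_criteria <- function(cohort, configs) {
  if (length(configs) < 2) stop("at least 2 configurations required")
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    stop("configs must be a named list")
  }
  runs <- lapply(configs, function(cf) run_loso(cohort, cf))
  rows <- list()
  for (nm in names(runs)) {
    for (r in runs[[nm]]$folds) {
      if (is.null(r$metrics)) next
      m <- metrics_from_confusion(r$confusion, aggregation = "macro",
                                  leakage_flag = r$metrics$leakage_flag,
                                  fold_id = r$fold$fold_id)
      rows[[length(rows) + 1L]] <- data.frame(
        config = nm, test_subject = r$fold$test_subject,
        accuracy = m$accuracy, precision = m$macro$precision,
        recall = m$macro$recall, f1 = m$macro$f1,
        leakage = m$leakage_flag)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- runs
  out
}
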