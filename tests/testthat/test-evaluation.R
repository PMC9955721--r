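test_that("confusion matrices count actual x predicted pairs in canonical order", {
  perfect <- confusion(rep(task_classes(), each = 3), rep(task_classes(), each = 3))
  expect_equal(unname(diag(perfect)), c(3L, 3L, 3L))
  expect_equal(sum(perfect), 9L)

  cm <- confusion(c("left", "right", "word"), c("right", "right", "word"))
  expect_equal(cm["left", "right"], 1L)
  expect_equal(cm["right", "right"], 1L)
  expect_equal(cm["word", "word"], 1L)
  expect_equal(sum(cm), 3L)

  # row sums equal per-class true counts
  set.seed(1)
  yt <- sample(task_classes(), 60, replace = TRUE)
  yp <- sample(task_classes(), 60, replace = TRUE)
  cm2 <- confusion(yt, yp)
  expect_equal(unname(rowSums(cm2)), unname(as.vector(table(factor(yt, task_classes())))))

  expect_error(confusion("left", c("left", "word")), "lengths differ")
  expect_error(confusion("up", "left"), "unknown label")
})

test_that("the printed subject confusion matrices reproduce the published pooled rates", {
  t4 <- as_confusion(matrix(c(757, 71, 57, 112, 1000, 184, 10, 49, 1183),
                            3, byrow = TRUE))
  m <- metrics_from_confusion(t4)
  expect_equal(m$micro_tpr, 0.858895706, tolerance = 1e-9)
  expect_equal(m$accuracy, m$micro_tpr)
})

test_that("metrics match a hand-computed binary oracle when one class is empty", {
  cm <- as_confusion(matrix(c(8, 2, 0,
                              3, 7, 0,
                              0, 0, 0), 3, byrow = TRUE))
  m <- metrics_from_confusion(cm)
  # binary one-vs-rest for class 'left': tp=8, fp=3, fn=2
  expect_equal(m$per_class$precision[1], 8 / 11)
  expect_equal(m$per_class$recall[1], 8 / 10)
  expect_equal(m$per_class$f1[1], 2 * (8 / 11) * (8 / 10) / (8 / 11 + 8 / 10))
  # empty class: zero-division policy gives 0 with a flag
  expect_equal(m$per_class$recall[3], 0)
  expect_true(m$zero_division)
  expect_equal(m$accuracy, 15 / 20)

  perfect <- metrics_from_confusion(diag(c(5, 5, 5)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro$f1, 1)
  expect_equal(perfect$micro_tnr, 1)

  expect_error(metrics_from_confusion(matrix(0, 3, 3)), "empty")
})

test_that("micro TPR/TNR identities hold on random confusion matrices", {
  set.seed(2)
  for (i in 1:50) {
    cm <- as_confusion(matrix(rpois(9, 5), 3))
    if (sum(cm) == 0) next
    m <- metrics_from_confusion(cm)
    expect_equal(m$micro_tpr, m$accuracy)
    expect_equal(m$micro_tnr, (1 + m$accuracy) / 2)
    expect_true(all(unlist(m[c("accuracy", "micro_tpr", "micro_tnr")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "micro_tpr", "micro_tnr")]) <= 1))
  }
})

# small, fast cohort for pipeline-structure tests
tiny_feature_cohort <- function(seed = 31, gain_sd = 0.3) {
  spec <- cohort_spec(trials_per_task_per_session = 2, trial_duration_s = 1.5,
                      seed = seed)
  profs <- sample_subject_profiles(spec, gain_log_sd = gain_sd,
                                   baseline_offset_sd = 0.3)
  cohort_features(generate_cohort(spec, profiles = profs))
}

tiny_loso_config <- function(...) {
  loso_config(..., mlp = mlp_config(hidden_layers = c(8, 8), epochs = 8,
                                    seed = 1), seed = 7)
}

test_that("run_loso produces three audited fold reports and a mean accuracy", {
  feats <- tiny_feature_cohort()
  res <- run_loso(feats, tiny_loso_config())
  expect_length(res$folds, 3)
  test_subjects <- vapply(res$folds, function(r) r$fold$test_subject, "")
  expect_setequal(test_subjects, c("S1", "S2", "S3"))
  accs <- vapply(res$folds, function(r) r$metrics$accuracy, 1)
  expect_equal(res$mean_accuracy, mean(accs))
  expect_true(all(vapply(res$folds, function(r) isTRUE(r$audit_pass), TRUE)))
  expect_false(res$leakage_flag)
  # training artifacts never mention the fold's held-out subject
  for (r in res$folds) {
    expect_false(r$fold$test_subject %in% r$fold$train_subjects)
  }
})

test_that("label-matched test averaging carries the leakage flag into every report", {
  feats <- tiny_feature_cohort()
  res <- run_loso(feats, tiny_loso_config(test_averaging = "label_matched"))
  expect_true(res$leakage_flag)
  for (r in res$folds) expect_true(r$metrics$leakage_flag)
})

test_that("compare_input_criteria tabulates configs x subjects consistently with stored matrices", {
  feats <- tiny_feature_cohort()
  tab <- compare_input_criteria(feats, list(
    averaged = tiny_loso_config("train_averaged"),
    raw = tiny_loso_config("none")
  ))
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$config), c("averaged", "raw"))
  expect_true(all(!tab$leakage))
  runs <- attr(tab, "results")
  for (nm in names(runs)) {
    for (r in runs[[nm]]$folds) {
      m <- metrics_from_confusion(r$confusion)
      row <- tab[tab$config == nm & tab$test_subject == r$fold$test_subject, ]
      expect_equal(row$accuracy, m$accuracy)
    }
  }
  expect_error(compare_input_criteria(feats, list(a = tiny_loso_config())),
               "at least 2")
})

test_that("a failing fold is reported as failed while the run continues", {
  feats <- tiny_feature_cohort()
  # remove one class from subject 1's sessions: averaging must fail that uses S1
  for (i in seq_along(feats[[1]]$sessions)) {
    keep <- feats[[1]]$sessions[[i]]$labels != "word"
    feats[[1]]$sessions[[i]] <- psd_feature_matrix(
      feats[[1]]$sessions[[i]]$values[keep, ], feats[[1]]$sessions[[i]]$labels[keep],
      subject_id = "S1")
  }
  res <- run_loso(feats, tiny_loso_config())
  failed <- vapply(res$folds, function(r) !is.null(r$error), TRUE)
  expect_true(any(failed))
  expect_true(any(!failed))
  expect_false(is.na(res$mean_accuracy))
})
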