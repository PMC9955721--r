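test_that("task sort is stable, idempotent, and matches an oracle sort", {
  m <- psd_feature_matrix(matrix(1:16, 4, 4), c("word", "left", "right", "left"))
  s <- sort_by_task(m)
  expect_equal(s$labels, c("left", "left", "right", "word"))
  # stability: the two left rows keep their original relative order
  expect_equal(attr(s, "provenance"), c(2L, 4L, 3L, 1L))
  expect_equal(s$values, m$values[c(2, 4, 3, 1), ])
  # idempotence
  s2 <- sort_by_task(s)
  expect_equal(s2$values, s$values)

  # random 50-row fixture vs independent comparison sort
  r <- random_psd_matrix(c(20, 15, 15), n_features = 5, seed = 99)
  sorted <- sort_by_task(r)
  oracle <- order(match(r$labels, task_classes()))  # order() is a stable sort
  expect_equal(sorted$values, r$values[oracle, ])

  bad <- psd_feature_matrix(matrix(0, 1, 3))
  expect_error(sort_by_task(bad), "labels")
})

test_that("within-subject averaging is the aligned element-wise mean with min truncation", {
  one_session <- function(vals, labels, id = "S1") {
    psd_feature_matrix(vals, labels, subject_id = id)
  }
  # two sessions, one class: rows (2,2,..) and (4,4,..) -> (3,3,..)
  a <- one_session(matrix(2, 1, 4), "left")
  b <- one_session(matrix(4, 1, 4), "left")
  # need all classes present: add right/word rows
  a$values <- rbind(a$values, matrix(1, 2, 4)); a$labels <- c("left", "right", "word")
  b$values <- rbind(b$values, matrix(5, 2, 4)); b$labels <- c("left", "right", "word")
  ss <- subject_sessions("S1", list(a, b))
  avg <- within_subject_average(ss)
  expect_equal(avg$values[avg$labels == "left", ], rep(3, 4))

  # three identical sessions -> any one session back (after sorting)
  r <- random_psd_matrix(c(4, 3, 2), n_features = 6, seed = 1, subject_id = "S2")
  ss3 <- subject_sessions("S2", list(r, r, r))
  avg3 <- within_subject_average(ss3)
  expect_equal(avg3$values, sort_by_task(r)$values)

  # per-class counts 10/12/11 across sessions -> 10 output rows for that class
  s1 <- random_psd_matrix(c(10, 3, 3), n_features = 4, seed = 2, subject_id = "S3")
  s2 <- random_psd_matrix(c(12, 3, 3), n_features = 4, seed = 3, subject_id = "S3")
  s3 <- random_psd_matrix(c(11, 3, 3), n_features = 4, seed = 4, subject_id = "S3")
  avg_min <- within_subject_average(subject_sessions("S3", list(s1, s2, s3)))
  expect_equal(sum(avg_min$labels == "left"), 10L)

  # a class absent from one session is an error naming the subject
  missing <- random_psd_matrix(c(3, 3), n_features = 4, seed = 5, subject_id = "S4")
  expect_error(
    within_subject_average(subject_sessions("S4", list(missing, missing))),
    "S4.*word"
  )
})

test_that("pairwise cross-subject averaging matches the brute-force mean oracle", {
  a <- random_psd_matrix(c(5, 4, 3), n_features = 8, seed = 11, subject_id = "A")
  b <- random_psd_matrix(c(4, 6, 3), n_features = 8, seed = 12, subject_id = "B")
  avg <- pairwise_subject_average(a, b)

  # independent recomputation: per class, truncate and mean
  sa <- sort_by_task(a); sb <- sort_by_task(b)
  for (cl in task_classes()) {
    ia <- which(sa$labels == cl); ib <- which(sb$labels == cl)
    n <- min(length(ia), length(ib))
    oracle <- (sa$values[ia[1:n], , drop = FALSE] +
               sb$values[ib[1:n], , drop = FALSE]) / 2
    got <- avg$features$values[avg$features$labels == cl, , drop = FALSE]
    expect_equal(got, oracle)
  }

  # identity and midpoint cases
  same <- pairwise_subject_average(a, a)
  expect_equal(same$features$values, sort_by_task(a)$values)
  x1 <- random_psd_matrix(c(2, 2, 2), n_features = 3, seed = 13)
  x3 <- x1; x3$values <- x1$values + 2
  mid <- pairwise_subject_average(x1, x3)
  expect_equal(mid$features$values, sort_by_task(x1)$values + 1)

  # provenance is class-pure and non-empty
  expect_true(all(lengths(avg$provenance) > 0))
  expect_true(all(vapply(avg$provenance,
                         function(p) length(unique(p$class)) == 1, TRUE)))
})

test_that("grand mean per class is preserved under equal-count pairwise averaging", {
  a <- random_psd_matrix(c(5, 5, 5), n_features = 4, seed = 21, subject_id = "A")
  b <- random_psd_matrix(c(5, 5, 5), n_features = 4, seed = 22, subject_id = "B")
  avg <- pairwise_subject_average(a, b)
  for (cl in task_classes()) {
    ma <- colMeans(a$values[a$labels == cl, , drop = FALSE])
    mb <- colMeans(b$values[b$labels == cl, , drop = FALSE])
    mo <- colMeans(avg$features$values[avg$features$labels == cl, , drop = FALSE])
    expect_equal(mo, (ma + mb) / 2)
  }
})

test_that("LOSO folds partition subjects with disjoint train/test", {
  folds <- build_loso_folds(c("S1", "S2", "S3"))
  expect_length(folds, 3)
  test_subjects <- vapply(folds, function(f) f$test_subject, "")
  expect_setequal(test_subjects, c("S1", "S2", "S3"))
  for (f in folds) {
    expect_false(f$test_subject %in% f$train_subjects)
    expect_setequal(c(f$train_subjects, f$test_subject), c("S1", "S2", "S3"))
  }
  # fold testing S3 trains on S1 and S2
  f3 <- folds[[which(test_subjects == "S3")]]
  expect_setequal(f3$train_subjects, c("S1", "S2"))
  expect_error(build_loso_folds(c("S1", "S2")), "at least 3")
  expect_error(fold_spec(1, c("S1", "S2"), "S1"), "must not appear")
})

test_that("test-time averaging is identity when off and flagged label-matched midpoint otherwise", {
  m <- random_psd_matrix(c(3, 3, 3), n_features = 4, seed = 31)
  expect_identical(test_time_average(m, list(), "off"), m)

  means <- list(left = rep(0, 4), right = rep(10, 4), word = rep(20, 4))
  out <- test_time_average(m, means, "label_matched")
  expect_true(isTRUE(attr(out, "uses_test_labels")))
  i <- which(m$labels == "right")[1]
  expect_equal(out$values[i, ], (m$values[i, ] + means$right) / 2)

  expect_error(test_time_average(m, means["left"], "label_matched"), "missing")
})
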