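# Seeded study-condition experiments: the averaging-contrast study that
# probes whether task-wise cross-subject averaging of the training data
# improves subject-independent (LOSO) accuracy under injected subject shift.

#' Averaging-contrast study on synthetic cohorts
#'
#' For each of `n_replicates` derived seeds, generates a 3-subject x
#' 3-session cohort with the stated subject and session shift, runs the LOSO
#' experiment with task-wise train averaging and without it (plain
#' concatenation of the training subjects' rows), and records both mean
#' accuracies. Both arms see the same cohort, folds and classifier seeds, so
#' each replicate is a paired comparison; per arm, the accuracy is the mean
#' over `n_model_seeds` independent classifier initializations, the standard
#' variance-reduction for stochastically trained networks (dropout and
#' minibatch order make single runs noisy by several accuracy points).
#'
#' Study conditions (fixture parameters, not estimates of real data): 8
#' trials per task per session, 2 s trials at 512 Hz, log-normal per-channel
#' subject gains (`gain_log_sd`), additive baseline band-power offsets
#' (`baseline_offset_sd`), log-normal per-channel session gains
#' (`session_gain_log_sd`), and the default task signatures. Two further
#' choices keep the comparison clean at this scaled-down problem size.
#' First, within each subject the sessions are concatenated (rather than
#' averaged) before cross-subject averaging, which keeps the averaged
#' training set at half of the unaveraged one instead of one sixth — the
#' feed-forward classifier needs that row count for stable fits, while the
#' cross-subject averaging step under study is unaffected. Second, PCA
#' retains a fixed `pca_k = 8` components in both arms, so both classifiers
#' share an identical input dimensionality and architecture; with a
#' variance-fraction rule the two arms would train networks of different
#' input width, confounding the comparison.
#'
#' @param seed Master seed; replicate and classifier seeds are split from it.
#' @param n_replicates Number of seeded cohort replicates (default 5).
#' @param gain_log_sd,baseline_offset_sd,session_gain_log_sd Shift magnitudes
#'   (defaults: the strong-shift study condition; set all 0 for the no-shift
#'   control).
#' @param trials_per_task Trials of each class per session (default 8).
#' @param n_model_seeds Classifier initializations averaged per arm (default 2).
#' @param pca_k Retained principal components in both arms (default 8).
#' @return A data frame with one row per replicate: `seed`,
#'   `acc_train_averaged`, `acc_no_averaging`, `averaging_wins`.
#' @export
averaging_contrast_experiment <- function(seed = 1, n_replicates = 5,
                                          gain_log_sd = 0.5,
                                          baseline_offset_sd = 0.5,
                                          session_gain_log_sd = 0.5,
                                          trials_per_task = 8,
                                          n_model_seeds = 2,
                                          pca_k = 8) {
  rep_seeds <- split_seed(seed, n_replicates)
  rows <- lapply(seq_len(n_replicates), function(i) {
    spec <- cohort_spec(trials_per_task_per_session = trials_per_task,
                        session_gain_log_sd = session_gain_log_sd,
                        seed = rep_seeds[i])
    profs <- sample_subject_profiles(spec, gain_log_sd = gain_log_sd,
                                     baseline_offset_sd = baseline_offset_sd)
    feats <- cohort_features(generate_cohort(spec, profiles = profs))
    clf_seeds <- split_seed(rep_seeds[i] + 1L, n_model_seeds)
    arm <- function(mode) {
      mean(vapply(clf_seeds, function(cs) {
        run_loso(feats, loso_config(mode, within_subject = "concat",
                                    pca_k = pca_k, seed = cs))$mean_accuracy
      }, 1))
    }
    a <- arm("train_averaged")
    b <- arm("none")
    data.frame(seed = rep_seeds[i], acc_train_averaged = a,
               acc_no_averaging = b, averaging_wins = a > b)
  })
  do.call(rbind, rows)
}
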