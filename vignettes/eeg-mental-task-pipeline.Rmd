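---
title: "Subject-independent mental-task classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-independent mental-task classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmtc)
```

## The problem

A brain–computer interface that must be re-calibrated for every new user is
of limited practical use. The pipeline in this package targets the
*subject-independent* setting: classify three imagined mental tasks —
left-hand movement imagery, right-hand movement imagery, and word
generation — from EEG band-power features of a person whose data were never
seen during training. The obstacle is inter-subject variability: absolute
EEG band power differs across people by large factors (electrode impedance,
skull anatomy, idiosyncratic rhythm amplitudes), so a classifier trained on
raw feature rows of some subjects transfers poorly to another.

The method studied here counters that variability by *task-wise averaging*:
feature rows of the training subjects that belong to the same mental task
are averaged element-wise before the classifier sees them, pulling the
training distribution toward a population template and cancelling
uncorrelated per-subject noise.

## Pipeline

1. **Surface Laplacian** (`surface_laplacian()`): each analysis channel
   minus the unweighted mean of its montage neighbors (the "small
   Laplacian"). The filter is linear, maps any spatially uniform signal to
   zero, and is applied to raw recordings only — precomputed feature files
   are assumed to carry whatever spatial filtering their producer applied.
2. **PSD features** (`extract_psd()`): a 1 s window sliding in 62.5 ms
   steps (16 rows per second of signal); per window and channel, Welch's
   segment-averaged periodogram sampled onto 12 bins at 8, 10, ..., 30 Hz.
   With the 8 centro-parietal channels C3, Cz, C4, CP1, CP2, P3, Pz, P4
   this gives 96 features per row, the analysis unit everywhere downstream.
3. **Task-wise averaging** (`within_subject_average()`,
   `pairwise_subject_average()`, `average_subjects()`): rows are stably
   sorted by task, aligned by within-class index, truncated to the shortest
   class block, and averaged element-wise — first across a subject's
   sessions, then across training subjects. Averaging never mixes classes;
   every output row keeps a provenance record of its contributing rows.
4. **PCA** (`fit_pca()`): fit on training rows only, per fold; retains the
   smallest leading set of components reaching 95% explained variance.
5. **Classifier** (`init_mlp()`, `train_mlp()`): a feed-forward network
   (default 12–24–12–24–12 hidden ReLU units, softmax output) trained for
   64 epochs with minibatches of 10 under dropout 0.5, minimizing
   cross-entropy with optional L1/L2 weight penalties.
6. **Evaluation** (`run_loso()`, `metrics_from_confusion()`):
   leave-one-subject-out folds; per fold a confusion matrix and the
   precision/recall/F1/accuracy suite under micro, macro and weighted
   aggregation, plus pooled TPR/TNR.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| band, resolution | 8–30 Hz, 2 Hz | mu and beta rhythms; 12 bins/channel |
| window, step | 1 s, 0.0625 s | 16 feature rows per second of signal |
| Welch segments | 0.5 s, 50% overlap | periodogram bins fall exactly on the 2 Hz grid |
| taper | rectangular, mean-detrended | see "Numerical choices" |
| PCA retention | 0.95 | standard practice; logged per fold |
| hidden layers | 12, 24, 12, 24, 12 | the best of the studied topologies |
| dropout | 0.5 | strong regularization against subject overfit |
| epochs, batch | 64, 10 | study conditions |
| optimizer | Adam, lr 3e-3 | see "Numerical choices" |

## The synthetic-data generator

Because the original recordings cannot be shipped, every stage is exercised
on synthetic cohorts (`generate_cohort()`). Per channel, a trial is a sum
of band-limited sinusoids (mu at 10 Hz, beta at 22 Hz) with random phases,
a 1/f background, and white noise; the sinusoid amplitude is set so its
band power equals *baseline x task modulation x channel gain*, and these
analytic targets are recorded per trial. Task signatures encode stylized
motor-imagery physiology: contralateral mu/beta suppression for hand
imagery, parietal modulation for word generation (ratios 0.25–0.75
suppression, 1.6 enhancement). Inter-subject variability is injected as
per-channel log-normal gains and additive baseline offsets drawn once per
subject; setting both SDs to zero gives identical subjects, the control
condition.

What the generator does *not* emulate: volume-conducted correlated
artifacts (EOG/EMG), non-stationarity within a session, session-to-session
electrode displacement, and realistic spatial covariance from cortical
sources. Passing tests therefore show the pipeline's *mechanics* are
correct and that averaging confers its benefit under controlled subject
shift — they do not certify accuracy levels on real EEG.

Recordings of the same person also drift between sessions (electrode
re-application, impedance changes); the generator models this as an extra
per-channel log-normal gain drawn once per (subject, session)
(`session_gain_log_sd` in `cohort_spec()`). Session disturbances are
precisely what task-wise averaging cancels and concatenation preserves, so
they are part of the strong-shift study condition.

The averaging-contrast study (`averaging_contrast_experiment()`) uses 3
subjects x 3 sessions x 8 trials per task of 2 s each, subject gain shift
`gain_log_sd = 0.5`, baseline offsets `0.5`, and session gain shift `0.5`
as the strong-shift condition. Two design choices keep the paired
comparison clean. Because dropout and minibatch order make a single
training run noisy by several accuracy points, each arm's accuracy in a
replicate is the mean over 2 classifier initializations — standard
reporting practice that sharpens the comparison without changing what is
measured. And both arms retain a fixed 8 principal components, so the two
classifiers share an identical input dimensionality (a variance-fraction
rule would give the arms networks of different width); this fixed budget
is also where the averaging benefit mechanically lives: on unaveraged
concatenated training data the leading components are spent on
subject- and session-variance directions, crowding class-discriminant
structure out of a small component budget, whereas averaging suppresses
that variance before PCA sees it. These sizes keep a full 5-replicate
paired study within minutes on one CPU with ~600 test rows per fold.

## Numerical choices

- **Rectangular Welch taper.** At 2 Hz bin spacing a Hann taper spreads
  even an exactly bin-centered tone over three bins (only ~2/3 of its power
  lands in its own bin). Since the band grid here *is* the analysis object,
  the default taper is rectangular with per-segment mean removal, which
  concentrates on-grid rhythms in single bins; a Hann taper remains
  available in `psd_config()` for off-grid content.
- **Adam at lr 3e-3.** With a few hundred averaged training rows and 64
  epochs, lr 1e-3 cannot reach the training-loss plateau (the network stays
  at chance on its own training data); 3e-3 converges reliably across the
  study conditions while remaining stable. The learning rate is plain
  config.
- **Within-subject session combination.** Whether a subject's three
  sessions should be averaged or concatenated before cross-subject
  averaging is genuinely ambiguous; both are implemented
  (`within_subject = "average"` / `"concat"`, default `"average"`). The
  contrast study uses `"concat"`: at desk scale the averaged arm would
  otherwise train on ~200 rows — far below what the classifier needs for
  stable decision boundaries — and the comparison would measure training-set
  size, not the cross-subject averaging step under study.
- **Row alignment.** Averaging pairs rows by within-class index after a
  stable task sort and truncates to the shortest block: the only
  order-preserving, data-independent rule; truncation losses are visible in
  the provenance records.
- **Sign-canonical PCA.** Each component's largest-magnitude coordinate is
  made positive, so fits are bit-reproducible across platforms.
- **Zero-division metrics.** Any metric with a zero denominator is defined
  as 0 and flagged (`zero_division`), never NaN.
- **Degenerate inputs.** Recordings shorter than one window yield an empty
  feature matrix with a warning; boundary electrodes with fewer than two
  neighbors are rejected by the Laplacian rather than zero-padded; windows
  spanning a task boundary are dropped rather than majority-labelled.

## Leakage policy

Two leakage hazards are handled explicitly:

- PCA and the classifier are fit per fold on training rows only; a test in
  the suite verifies that refitting with test rows present changes the
  model (so the per-fold fingerprint proves test data were absent).
- The test-time averaging mode that reproduces the "averaged testing data"
  configuration (`test_averaging = "label_matched"`) replaces each test row
  by the mean of itself and the training mean of its *true* class. This
  uses test labels and is therefore information leakage; it is off by
  default, and every object it touches carries `uses_test_labels = TRUE`,
  which propagates to a `leakage_flag` on every downstream report.

## Known limitations

- The MLP is a pure-R reference implementation: exact and convenient to
  verify (its gradients are checked against finite differences) but not
  fast; problem sizes beyond a few thousand rows per fold will be slow.
- The spherical-spline Laplacian and current-source-density variants are
  out of scope; the neighbor-mean small Laplacian is the only spatial
  filter.
- Parametric (Burg/Yule–Walker) and subspace PSD estimators are not
  implemented; Welch is the single estimator, configurable in segment
  length, overlap, taper and detrending.
- Accuracies on synthetic cohorts are properties of the fixture parameters
  and must not be read as estimates of performance on real recordings.

## A worked run

```{r, eval = FALSE}
spec <- cohort_spec(trials_per_task_per_session = 6,
                    session_gain_log_sd = 0.4, seed = 1)
profiles <- sample_subject_profiles(spec, gain_log_sd = 0.5,
                                    baseline_offset_sd = 0.5)
features <- cohort_features(generate_cohort(spec, profiles = profiles))
averaged <- run_loso(features, loso_config("train_averaged",
                                           within_subject = "concat", seed = 1))
plain <- run_loso(features, loso_config("none", seed = 1))
c(averaged = averaged$mean_accuracy, plain = plain$mean_accuracy)
```
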