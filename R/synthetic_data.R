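# Seeded multi-subject synthetic EEG with task-dependent band-power
# signatures and controllable inter-subject variability.  The generator is
# first-class, tested code: it defines the study conditions under which the
# averaging pipeline is exercised.

#' Synthesis bands
#'
#' The narrow-band rhythms the generator places energy in: mu (10 Hz) and a
#' beta rhythm (22 Hz), both on the 2 Hz analysis grid.
#' @export
synthesis_bands <- function() c(mu = 10, beta = 22)

#' Subject profile: stable per-subject signal characteristics
#'
#' Houses the inter-subject variability the averaging method targets:
#' per-channel multiplicative gains (electrode impedance / skull geometry),
#' per-channel per-band baseline rhythm power, broadband noise level, and the
#' spectral slope of the 1/f background.
#'
#' @param subject_id Identifier.
#' @param channel_gain Named positive numeric vector, one entry per montage
#'   electrode (unitless).
#' @param baseline_band_power Channels x bands matrix of resting band power
#'   (µV²), rows named by electrode, columns by [synthesis_bands()] names.
#' @param noise_scale Standard deviation of additive white noise (µV), >= 0.
#' @param background_scale Standard deviation of the 1/f background (µV).
#' @param one_over_f_exponent Spectral slope of the background (power ~
#'   f^-exponent).
#' @return A `subject_profile`.
#' @export
subject_profile <- function(subject_id, channel_gain, baseline_band_power,
                            noise_scale = 1, background_scale = 0.5,
                            one_over_f_exponent = 1) {
  if (any(channel_gain <= 0)) stop("channel gains must be positive")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  stopifnot(is.matrix(baseline_band_power),
            !is.null(rownames(baseline_band_power)),
            !is.null(colnames(baseline_band_power)))
  if (any(baseline_band_power < 0)) stop("baseline band powers must be >= 0")
  structure(list(subject_id = subject_id, channel_gain = channel_gain,
                 baseline_band_power = baseline_band_power,
                 noise_scale = noise_scale, background_scale = background_scale,
                 one_over_f_exponent = one_over_f_exponent),
            class = "subject_profile")
}

#' Task signature: band-power modulation of one mental task
#'
#' @param task_class One of [task_classes()].
#' @param band_modulation Channels x bands matrix of positive multiplicative
#'   modulations of baseline band power during the task (values < 1 encode
#'   event-related desynchronization, > 1 synchronization).
#' @return A `task_signature`.
#' @export
task_signature <- function(task_class, band_modulation) {
  task_class <- match.arg(task_class, task_classes())
  stopifnot(is.matrix(band_modulation))
  if (any(band_modulation <= 0)) stop("band modulations must be positive")
  structure(list(task_class = task_class, band_modulation = band_modulation),
            class = "task_signature")
}

#' Default task signatures
#'
#' Motor-imagery physiology in stylized form: left-hand imagery suppresses mu
#' (and, more weakly, beta) over the contralateral right sensorimotor cortex
#' (C4/CP2); right-hand imagery mirrors this over C3/CP1; word generation
#' suppresses parietal mu and enhances left-parietal beta. Modulation ratios
#' (0.25-0.75 suppression, 1.6 enhancement) are fixture parameters chosen to
#' make the classes separable at short trial lengths; they are not estimates
#' of real effect sizes.
#'
#' @param montage An `eeg_montage` supplying the channel set.
#' @return Named list of three [task_signature()] objects (left, right, word).
#' @export
default_task_signatures <- function(montage = default_montage()) {
  bands <- names(synthesis_bands())
  base <- matrix(1, length(montage$labels), length(bands),
                 dimnames = list(montage$labels, bands))
  sig <- function(class, mods) {
    m <- base
    for (md in mods) m[md[[1]], md[[2]]] <- md[[3]]
    task_signature(class, m)
  }
  list(
    left = sig("left", list(list("C4", "mu", 0.25), list("CP2", "mu", 0.4),
                            list("C4", "beta", 0.5), list("P4", "mu", 0.7))),
    right = sig("right", list(list("C3", "mu", 0.25), list("CP1", "mu", 0.4),
                              list("C3", "beta", 0.5), list("P3", "mu", 0.7))),
    word = sig("word", list(list("P3", "mu", 0.5), list("Pz", "mu", 0.5),
                            list("P3", "beta", 1.6), list("Cz", "mu", 0.75)))
  )
}

#' Cohort specification
#'
#' @param n_subjects Number of subjects (default 3).
#' @param n_sessions_per_subject Labelled sessions per subject (default 3).
#' @param trials_per_task_per_session Trials of each task per session.
#' @param trial_duration_s Trial length in seconds.
#' @param sampling_rate_hz Sampling rate (default 512); must satisfy Nyquist
#'   for the highest synthesis band.
#' @param montage An `eeg_montage`.
#' @param session_gain_log_sd SD of the log of per-channel multiplicative
#'   gains drawn once per (subject, session): session-to-session variability
#'   (electrode re-application, impedance drift) on top of the per-subject
#'   shift. 0 disables it.
#' @param seed Master seed; all randomness flows from it via a deterministic
#'   sub-seed stream.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 3, n_sessions_per_subject = 3,
                        trials_per_task_per_session = 4,
                        trial_duration_s = 2, sampling_rate_hz = 512,
                        montage = default_montage(),
                        session_gain_log_sd = 0, seed = 1) {
  counts <- c(n_subjects, n_sessions_per_subject, trials_per_task_per_session)
  if (any(counts < 1)) stop("all cohort counts must be >= 1")
  if (sampling_rate_hz < 2 * max(synthesis_bands())) {
    stop("configuration error: sampling rate ", sampling_rate_hz,
         " Hz below Nyquist for ", max(synthesis_bands()), " Hz synthesis band")
  }
  structure(list(n_subjects = n_subjects,
                 n_sessions_per_subject = n_sessions_per_subject,
                 trials_per_task_per_session = trials_per_task_per_session,
                 trial_duration_s = trial_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 montage = montage,
                 session_gain_log_sd = session_gain_log_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw per-subject profiles with controllable subject shift
#'
#' Channel gains are log-normal (`sdlog = gain_log_sd`) and per-channel,
#' per-band baseline offsets are normal (`sd = baseline_offset_sd`, truncated
#' so powers stay positive), each drawn once per subject. Setting both SDs to
#' zero yields identical subjects — the control condition under which
#' cross-subject averaging should confer no benefit.
#'
#' @param spec A [cohort_spec()].
#' @param gain_log_sd SD of log channel gain (default 0.5, a strong shift).
#' @param baseline_offset_sd SD of additive baseline band-power offsets (µV²).
#' @param base_band_power Named numeric: population-level band power (µV²)
#'   per synthesis band.
#' @param noise_scale,background_scale,one_over_f_exponent Passed to
#'   [subject_profile()].
#' @return List of `n_subjects` [subject_profile()] objects (ids `S1`, `S2`, ...).
#' @export
sample_subject_profiles <- function(spec, gain_log_sd = 0.5,
                                    baseline_offset_sd = 0.5,
                                    base_band_power = c(mu = 4, beta = 2),
                                    noise_scale = 1, background_scale = 0.5,
                                    one_over_f_exponent = 1) {
  labels <- spec$montage$labels
  bands <- names(synthesis_bands())
  seeds <- split_seed(spec$seed, spec$n_subjects + 10L)
  lapply(seq_len(spec$n_subjects), function(s) {
    with_seed(seeds[s], {
      gains <- stats::setNames(exp(stats::rnorm(length(labels), 0, gain_log_sd)),
                               labels)
      base <- matrix(rep(base_band_power[bands], each = length(labels)),
                     nrow = length(labels),
                     dimnames = list(labels, bands))
      offs <- matrix(stats::rnorm(length(base), 0, baseline_offset_sd),
                     nrow = nrow(base))
      bbp <- pmax(base + offs, 0.1 * base)
      subject_profile(paste0("S", s), gains, bbp, noise_scale,
                      background_scale, one_over_f_exponent)
    })
  })
}

# 1/f-shaped Gaussian background, unit variance, via spectral shaping.
#' @keywords internal
#' @noRd
one_over_f_noise <- function(n, exponent) {
  x <- stats::rnorm(n)
  if (exponent == 0) return(x)
  xf <- stats::fft(x)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  shaped <- Re(stats::fft(xf * f^(-exponent / 2), inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Generate one synthetic EEG trial
#'
#' Per channel, the signal is a sum over synthesis bands of a sinusoid with a
#' random phase plus a 1/f background and white noise. The sinusoid amplitude
#' is set so that its band power (= amplitude²/2) equals
#' `baseline_band_power x band_modulation x channel_gain`; these analytic
#' band-power targets are attached as the `analytic_band_power` attribute
#' (channels x bands, µV²). The task annotation is constant over the trial.
#'
#' @param profile A [subject_profile()].
#' @param signature A [task_signature()].
#' @param duration_s Trial length (s).
#' @param rate_hz Sampling rate (Hz); must satisfy Nyquist for all bands.
#' @param montage An `eeg_montage`.
#' @param seed Integer seed; identical arguments + seed give bitwise-identical
#'   output.
#' @return An [eeg_recording()] with constant annotations and the
#'   `analytic_band_power` attribute.
#' @export
generate_trial <- function(profile, signature, duration_s, rate_hz,
                           montage = default_montage(), seed = 1) {
  bands <- synthesis_bands()
  if (rate_hz < 2 * max(bands)) {
    stop("configuration error: rate ", rate_hz, " Hz too low for ",
         max(bands), " Hz band")
  }
  labels <- montage$labels
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  power <- profile$baseline_band_power[labels, names(bands), drop = FALSE] *
    signature$band_modulation[labels, names(bands), drop = FALSE] *
    profile$channel_gain[labels]
  data <- with_seed(seed, {
    d <- matrix(0, length(labels), n, dimnames = list(labels, NULL))
    for (ci in seq_along(labels)) {
      sig <- numeric(n)
      for (bi in seq_along(bands)) {
        amp <- sqrt(2 * power[ci, bi])
        phase <- stats::runif(1, 0, 2 * pi)
        sig <- sig + amp * sin(2 * pi * bands[bi] * t + phase)
      }
      if (profile$background_scale > 0) {
        sig <- sig + profile$background_scale *
          one_over_f_noise(n, profile$one_over_f_exponent)
      }
      if (profile$noise_scale > 0) {
        sig <- sig + stats::rnorm(n, 0, profile$noise_scale)
      }
      d[ci, ] <- sig
    }
    d
  })
  rec <- eeg_recording(data, rate_hz, montage,
                       annotations = rep(signature$task_class, n))
  attr(rec, "analytic_band_power") <- power
  rec
}

#' Generate a full synthetic cohort of raw recordings
#'
#' Produces `n_subjects x n_sessions` sessions, each containing
#' `trials_per_task_per_session` trials of every task class (exact class
#' balance), deterministically from `spec$seed`. When the spec sets
#' `session_gain_log_sd > 0`, an additional per-channel log-normal gain is
#' drawn once per (subject, session) and multiplied into that session's
#' trials — the session-to-session variability that makes recordings from
#' the same subject drift between days. The manifest records every trial's
#' subject, session, class, trial seed and the analysis channels' analytic
#' band powers; each recording additionally carries the full
#' `analytic_band_power` matrix (inclusive of session gains).
#'
#' @param spec A [cohort_spec()].
#' @param profiles List of [subject_profile()] (default: drawn by
#'   [sample_subject_profiles()] with its default subject shift); length must
#'   equal `n_subjects` and subject ids must be unique.
#' @param signatures Named list of [task_signature()] per class (default
#'   [default_task_signatures()]).
#' @return A `synthetic_cohort`: list with `subjects` (per subject: id +
#'   sessions, each a list of [eeg_recording()]), `manifest` (data frame),
#'   `profiles`, `signatures`, `spec`.
#' @export
generate_cohort <- function(spec, profiles = NULL, signatures = NULL) {
  profiles <- profiles %||% sample_subject_profiles(spec)
  signatures <- signatures %||% default_task_signatures(spec$montage)
  if (length(profiles) != spec$n_subjects) {
    stop("need ", spec$n_subjects, " profiles, got ", length(profiles))
  }
  ids <- vapply(profiles, function(p) p$subject_id, "")
  if (anyDuplicated(ids)) stop("configuration error: duplicate subject_ids")
  stopifnot(setequal(names(signatures), task_classes()))

  n_trials <- spec$n_subjects * spec$n_sessions_per_subject *
    length(task_classes()) * spec$trials_per_task_per_session
  trial_seeds <- split_seed(spec$seed + 1L, n_trials)
  n_sess_total <- spec$n_subjects * spec$n_sessions_per_subject
  session_seeds <- split_seed(spec$seed + 2L, n_sess_total)

  manifest <- list()
  subjects <- vector("list", spec$n_subjects)
  k <- 0L
  for (s in seq_len(spec$n_subjects)) {
    sessions <- vector("list", spec$n_sessions_per_subject)
    for (ses in seq_len(spec$n_sessions_per_subject)) {
      sess_profile <- profiles[[s]]
      if (spec$session_gain_log_sd > 0) {
        labels <- spec$montage$labels
        g <- with_seed(session_seeds[(s - 1L) * spec$n_sessions_per_subject + ses],
                       exp(stats::rnorm(length(labels), 0, spec$session_gain_log_sd)))
        sess_profile$channel_gain <- sess_profile$channel_gain *
          stats::setNames(g, labels)
      }
      trials <- list()
      for (cls in task_classes()) {
        for (tr in seq_len(spec$trials_per_task_per_session)) {
          k <- k + 1L
          rec <- generate_trial(sess_profile, signatures[[cls]],
                                spec$trial_duration_s, spec$sampling_rate_hz,
                                spec$montage, seed = trial_seeds[k])
          trials[[length(trials) + 1L]] <- rec
          bp <- attr(rec, "analytic_band_power")
          bp <- bp[analysis_channels(), , drop = FALSE]
          bp_row <- as.data.frame(as.list(stats::setNames(
            as.vector(bp),
            paste(rep(rownames(bp), ncol(bp)),
                  rep(colnames(bp), each = nrow(bp)), sep = "_"))))
          manifest[[k]] <- cbind(data.frame(subject = ids[s], session = ses,
                                            class = cls, trial = tr,
                                            seed = trial_seeds[k]), bp_row)
        }
      }
      sessions[[ses]] <- trials
    }
    subjects[[s]] <- list(subject_id = ids[s], sessions = sessions)
  }
  structure(list(subjects = subjects,
                 manifest = do.call(rbind, manifest),
                 profiles = profiles, signatures = signatures, spec = spec),
            class = "synthetic_cohort")
}

#' Run raw cohort recordings through the feature pipeline
#'
#' Applies the surface Laplacian (optional, on by default for raw input) and
#' PSD feature extraction to every trial, concatenating trials within each
#' session into one labelled [psd_feature_matrix()].
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param cfg A [psd_config()].
#' @param laplacian Apply [surface_laplacian()] before feature extraction?
#' @return List of [subject_sessions()] objects, one per subject.
#' @export
cohort_features <- function(cohort, cfg = psd_config(), laplacian = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  lapply(cohort$subjects, function(subj) {
    sess <- lapply(seq_along(subj$sessions), function(i) {
      mats <- lapply(subj$sessions[[i]], function(rec) {
        if (laplacian) rec <- surface_laplacian(rec, cfg$channels)
        extract_psd(rec, cfg)
      })
      m <- rbind_psd(mats, subject_id = subj$subject_id)
      m$session_id <- as.character(i)
      m
    })
    subject_sessions(subj$subject_id, sess)
  })
}
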