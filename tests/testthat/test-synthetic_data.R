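test_that("noise-free single-band trials have the closed-form variance", {
  # mu rhythm only, modulation 1, gain 1: variance = amplitude^2/2 = power
  prof <- flat_profile(mu = 4, beta = 0, noise = 0, background = 0)
  rec <- generate_trial(prof, neutral_signature(), 2, 512, seed = 9)
  for (ch in c("C3", "Pz")) {
    x <- rec$data[ch, ]
    expect_lt(abs(mean(x^2) - 4), 1e-9)  # sinusoid power over whole periods
  }
  expect_equal(unique(rec$annotations), "left")
})

test_that("generation is bitwise deterministic in the seed", {
  prof <- flat_profile(noise = 1, background = 0.5)
  a <- generate_trial(prof, neutral_signature(), 1, 512, seed = 11)
  b <- generate_trial(prof, neutral_signature(), 1, 512, seed = 11)
  expect_identical(a$data, b$data)
  c <- generate_trial(prof, neutral_signature(), 1, 512, seed = 12)
  expect_false(identical(a$data, c$data))

  spec <- cohort_spec(trials_per_task_per_session = 1, trial_duration_s = 1, seed = 5)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$subjects[[1]]$sessions[[1]][[1]]$data,
                   co2$subjects[[1]]$sessions[[1]][[1]]$data)
  expect_identical(co1$manifest, co2$manifest)
})

test_that("left vs right signatures suppress mu on opposite central channels", {
  prof <- flat_profile(noise = 0.5, background = 0.5)
  sigs <- default_task_signatures()
  left <- generate_trial(prof, sigs$left, 10, 512, seed = 21)
  right <- generate_trial(prof, sigs$right, 10, 512, seed = 22)
  # analytic targets: left suppresses C4 mu, right suppresses C3 mu
  expect_lt(trial_band_power(left, "C4", 10), trial_band_power(left, "C3", 10))
  expect_lt(trial_band_power(right, "C3", 10), trial_band_power(right, "C4", 10))
  # realized band power matches the analytic manifest value within 5% at 10 s
  tgt <- attr(left, "analytic_band_power")
  expect_lt(abs(trial_band_power(left, "C4", 10) - tgt["C4", "mu"]) / tgt["C4", "mu"], 0.05)
})

test_that("realized band power approaches the analytic target as duration grows", {
  prof <- flat_profile(noise = 1, background = 0.5)
  sig <- default_task_signatures()$word
  err_at <- function(dur, seed) {
    rec <- generate_trial(prof, sig, dur, 512, seed = seed)
    tgt <- attr(rec, "analytic_band_power")
    mean(sapply(analysis_channels(), function(ch) {
      abs(trial_band_power(rec, ch, 10) - tgt[ch, "mu"]) / tgt[ch, "mu"]
    }))
  }
  short <- mean(sapply(1:3, function(s) err_at(2, s)))
  long <- mean(sapply(1:3, function(s) err_at(16, s + 10)))
  expect_lt(long, short)    # tolerance shrinks with duration
  expect_lt(long, 0.15)
})

test_that("cohorts have exact class balance and well-formed manifests", {
  spec <- cohort_spec(n_subjects = 3, n_sessions_per_subject = 3,
                      trials_per_task_per_session = 2, trial_duration_s = 1,
                      seed = 7)
  co <- generate_cohort(spec)
  expect_length(co$subjects, 3)
  expect_equal(nrow(co$manifest), 3 * 3 * 3 * 2)
  balance <- table(co$manifest$subject, co$manifest$class)
  expect_true(all(balance == 6))
  per_session <- table(co$manifest$session, co$manifest$class)
  expect_true(all(per_session == 3 * 2))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_spec(sampling_rate_hz = 30), "Nyquist")
  prof <- flat_profile()
  expect_error(generate_trial(prof, neutral_signature(), 1, 20), "too low")
  spec <- cohort_spec(n_subjects = 2, trial_duration_s = 1)
  profs <- list(flat_profile(id = "A"), flat_profile(id = "A"))
  expect_error(generate_cohort(spec, profiles = profs), "duplicate")
  expect_error(subject_profile("X", c(a = -1),
                               matrix(1, 1, 1, dimnames = list("a", "mu"))),
               "positive")
})

test_that("zero subject-shift profiles are identical across subjects", {
  spec <- cohort_spec(seed = 3)
  profs <- sample_subject_profiles(spec, gain_log_sd = 0, baseline_offset_sd = 0)
  expect_equal(profs[[1]]$channel_gain, profs[[2]]$channel_gain)
  expect_equal(profs[[1]]$baseline_band_power, profs[[3]]$baseline_band_power)
  shifted <- sample_subject_profiles(spec)
  expect_false(isTRUE(all.equal(shifted[[1]]$channel_gain,
                                shifted[[2]]$channel_gain)))
})
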