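# Shared fixtures, built in code at test time.

# A 4-electrode toy montage: center C with neighbors N1, N2, N3.
toy_montage <- function() {
  montage(c("C", "N1", "N2", "N3"),
          rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1)),
          neighbors = list(C = c("N1", "N2", "N3"),
                           N1 = "C", N2 = "C", N3 = "C"))
}

# Random labelled feature matrix with the given per-class row counts.
random_psd_matrix <- function(counts, n_features = 96, seed = 1,
                              subject_id = NA_character_) {
  set.seed(seed)
  labels <- rep(task_classes()[seq_along(counts)], counts)
  labels <- sample(labels)  # shuffled class order
  psd_feature_matrix(matrix(stats::runif(length(labels) * n_features),
                            length(labels), n_features),
                     labels, subject_id = subject_id)
}

# A flat-spectrum single-subject profile on the default montage.
flat_profile <- function(mu = 4, beta = 2, noise = 0, background = 0,
                         gains = 1, id = "S1") {
  mont <- default_montage()
  nl <- length(mont$labels)
  subject_profile(
    id,
    stats::setNames(rep(gains, length.out = nl), mont$labels),
    matrix(c(rep(mu, nl), rep(beta, nl)), nl, 2,
           dimnames = list(mont$labels, c("mu", "beta"))),
    noise_scale = noise, background_scale = background
  )
}

neutral_signature <- function(class = "left") {
  mont <- default_montage()
  task_signature(class, matrix(1, length(mont$labels), 2,
                               dimnames = list(mont$labels, c("mu", "beta"))))
}

# Welch band power of one channel of a recording over a whole trial,
# independent of extract_psd (oracle route).
trial_band_power <- function(rec, channel, f0, res = 2) {
  x <- rec$data[channel, ]
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / (n^2)
  freq <- (seq_len(n) - 1) * rec$rate_hz / n
  sel <- freq > f0 - res / 2 & freq <= f0 + res / 2
  2 * sum(p[sel])  # one-sided power in the band
}
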