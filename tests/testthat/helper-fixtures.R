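# Short-duration simulation config for fast unit tests.
quick_config <- function(seed = 1L, duration_s = 6, ...) {
  sim_config(duration_s = duration_s, seed = seed, ...)
}

# Clean acquisition chain: no mains, no motion (quantization still applies).
clean_config <- function(seed = 1L, duration_s = 6, ...) {
  sim_config(duration_s = duration_s, seed = seed, mains_amplitude = 0,
             motion_artifact_level = 0, ...)
}

test_catalog <- function() {
  read_activity_catalog(system.file("extdata", "activities.json",
                                    package = "affectsense"))
}

test_profile <- function(id = "user1") {
  user_profile(
    id,
    c(shoulders = "hard", arms = "hard", column = "hard", legs = "hard",
      feet = "hard", cognitive = "hard", dangerous_tools = "hard"))
}

# Amplitude of the single-frequency Fourier component of x at f_hz.
tone_amplitude <- function(x, fs, f_hz) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  2 * Mod(sum(x * exp(-2i * pi * f_hz * t))) / n
}

rms <- function(x) sqrt(mean(x^2))

# Loop-based brute-force evaluation of the six statistics, kept independent
# of the vectorised implementation.
brute_force_features <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  rho <- sqrt(sum((x - mu)^2) / (n - 1))
  afd <- 0
  for (i in seq_len(n - 1)) afd <- afd + abs(x[i + 1] - x[i])
  afd <- afd / (n - 1)
  asd <- 0
  for (i in seq_len(n - 2)) asd <- asd + abs(x[i + 2] - x[i])
  asd <- asd / (n - 2)
  z <- (x - mu) / rho
  afdn <- 0
  for (i in seq_len(n - 1)) afdn <- afdn + abs(z[i + 1] - z[i])
  afdn <- afdn / (n - 1)
  asdn <- 0
  for (i in seq_len(n - 2)) asdn <- asdn + abs(z[i + 2] - z[i])
  asdn <- asdn / (n - 2)
  c(mean = mu, std = rho, afd = afd, afdn = afdn, asd = asd, asdn = asdn)
}

# Naive threshold peak picker, independent of the simulator internals: local
# maxima above the midpoint between median and maximum.
naive_peak_periods <- function(x, fs) {
  thr <- (stats::median(x) + max(x)) / 2
  above <- x > thr
  n <- length(x)
  is_peak <- above & c(FALSE, x[-1] >= x[-n]) & c(x[-n] > x[-1], FALSE)
  idx <- which(is_peak)
  # collapse runs of neighbouring detections within 100 ms
  keep <- idx[c(TRUE, diff(idx) > 0.1 * fs)]
  diff(keep) / fs
}
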