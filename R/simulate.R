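#' Electrodermal voltage divider
#'
#' The skin, with resistance `RL` (mega-ohm order), forms a voltage divider
#' with the series resistor `R1` polarised at the supply voltage; the
#' acquisition system measures the voltage across `R1`:
#' `v = vref * R1 / (R1 + RL)`. The output is strictly decreasing in skin
#' resistance and bounded in (0, vref).
#'
#' @param skin_resistance_ohms Positive skin resistance(s) in ohms
#'   (vectorised).
#' @param config A [sim_config()] supplying `vref_volts` and
#'   `divider_r1_ohms`.
#' @return Voltage(s) across R1, in volts.
#' @examples
#' eda_divider_voltage(5e5, sim_config())   # equal resistors halve 3.3 V
#' @export
eda_divider_voltage <- function(skin_resistance_ohms, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(skin_resistance_ohms) || length(skin_resistance_ohms) < 1L ||
      any(!is.finite(skin_resistance_ohms)) || any(skin_resistance_ohms <= 0))
    abort_invalid("'skin_resistance_ohms' must be positive and finite")
  r1 <- config$divider_r1_ohms
  config$vref_volts * r1 / (r1 + skin_resistance_ohms)
}

#' Quantize a biosignal through the ADC model
#'
#' Samples are clipped to the converter's input range `[0, vref]` (real
#' converters saturate rather than fail) and rounded to the nearest multiple
#' of the conversion step `vref / 2^adc_bits`. The operation is idempotent.
#'
#' @param signal A [biosignal()] in volts.
#' @param config A [sim_config()].
#' @param codes If `TRUE`, return integer ADC codes (units `"counts"`)
#'   instead of voltages snapped to the code grid.
#' @return A quantized [biosignal()].
#' @export
quantize_adc <- function(signal, config, codes = FALSE) {
  stopifnot(inherits(signal, "biosignal"), inherits(config, "sim_config"))
  step <- adc_step(config)
  v <- pmin(pmax(signal$samples, 0), config$vref_volts)
  k <- round(v / step)
  out <- if (codes) k else k * step
  biosignal(out, signal$sampling_rate_hz, signal$channel,
            label = signal$label, units = if (codes) "counts" else "V")
}

# Beat onset times covering [0, duration] with log-normal-free Gaussian
# jitter on the RR intervals; extra beats beyond both edges so the rendered
# waveform has no boundary gap.
draw_beat_times <- function(heart_rate_bpm, hr_variability, duration_s) {
  rr <- 60 / heart_rate_bpm
  n <- ceiling((duration_s + 4) / rr) + 2L
  intervals <- rr * pmax(0.3, 1 + hr_variability * rnorm(n))
  cumsum(intervals) - 2 * rr
}

# Sum-of-Gaussians PQRST template rendered at each beat time. Component
# times for the P and T waves scale with the RR interval; widths are fixed.
# Peak amplitude of the R wave is 1.
render_ecg_wave <- function(t, beats, rr_mean) {
  scale <- rr_mean / 0.8
  comp <- list(P = c(mu = -0.22 * scale, sigma = 0.025, amp = 0.12),
               Q = c(mu = -0.030, sigma = 0.010, amp = -0.10),
               R = c(mu = 0.000, sigma = 0.012, amp = 1.00),
               S = c(mu = 0.030, sigma = 0.010, amp = -0.18),
               T = c(mu = 0.32 * scale, sigma = 0.060, amp = 0.28))
  fs <- 1 / (t[2] - t[1])
  y <- numeric(length(t))
  half <- ceiling(0.6 * scale * fs)
  for (b in beats) {
    i0 <- max(1L, floor((b - 0.45 * scale) * fs) + 1L)
    i1 <- min(length(t), ceiling((b + 0.65 * scale) * fs) + 1L)
    if (i0 > i1) next
    dt <- t[i0:i1] - b
    seg <- 0
    for (cp in comp)
      seg <- seg + cp["amp"] * exp(-((dt - cp["mu"])^2) / (2 * cp["sigma"]^2))
    y[i0:i1] <- y[i0:i1] + seg
  }
  y
}

# Pulse wave: a systolic peak plus a smaller delayed dicrotic wave per beat.
render_ppg_wave <- function(t, beats, rr_mean, amplitude) {
  scale <- rr_mean / 0.8
  fs <- 1 / (t[2] - t[1])
  y <- numeric(length(t))
  for (b in beats) {
    i0 <- max(1L, floor((b + 0.02) * fs) + 1L)
    i1 <- min(length(t), ceiling((b + 0.95 * scale) * fs) + 1L)
    if (i0 > i1) next
    dt <- t[i0:i1] - b
    y[i0:i1] <- y[i0:i1] +
      amplitude * (exp(-((dt - 0.22 * scale)^2) / (2 * 0.075^2)) +
                   0.35 * exp(-((dt - 0.45 * scale)^2) / (2 * 0.10^2)))
  }
  y
}

# Skin resistance over time: slowly drifting tonic level plus phasic
# skin-conductance responses (fast rise, exponential decay), combined on the
# conductance scale and mapped back to resistance.
render_eda_resistance <- function(t, params) {
  duration <- t[length(t)]
  r0 <- params$eda_tonic_level_ohms
  phase <- runif(1, 0, 2 * pi)
  tonic_r <- r0 * (1 + 0.05 * sin(2 * pi * t / 45 + phase))
  g <- 1 / tonic_r
  g0 <- 1 / r0
  n_scr <- rpois(1, params$eda_scr_rate_per_min / 60 * (duration + 10))
  if (n_scr > 0) {
    onsets <- runif(n_scr, -10, duration)
    amps <- runif(n_scr, 0.05, 0.15) * g0
    for (k in seq_len(n_scr)) {
      dt <- t - onsets[k]
      pos <- dt > 0
      g[pos] <- g[pos] +
        amps[k] * (1 - exp(-dt[pos] / 0.75)) * exp(-dt[pos] / 3)
    }
  }
  1 / g
}

add_contamination <- function(v, t, config) {
  if (config$mains_amplitude > 0)
    v <- v + config$mains_amplitude *
      sin(2 * pi * config$mains_freq_hz * t + runif(1, 0, 2 * pi))
  if (config$motion_artifact_level > 0)
    v <- v + config$motion_artifact_level * rnorm(length(v))
  v
}

sim_n_samples <- function(config) {
  n <- round(config$duration_s * config$sampling_rate_hz)
  if (n < 3)
    abort_invalid("duration too short: fewer than 3 samples")
  n
}

render_channel <- function(channel, params, config, beats = NULL) {
  n <- sim_n_samples(config)
  t <- (seq_len(n) - 1L) / config$sampling_rate_hz
  rr <- 60 / params$heart_rate_bpm
  v <- switch(channel,
    ECG = {
      if (is.null(beats))
        beats <- draw_beat_times(params$heart_rate_bpm, params$hr_variability,
                                 config$duration_s)
      # mid-rail offset after amplification; R peak around 2.6 V
      1.65 + 0.95 * render_ecg_wave(t, beats, rr)
    },
    PPG = {
      if (is.null(beats))
        beats <- draw_beat_times(params$heart_rate_bpm, params$hr_variability,
                                 config$duration_s)
      1.40 + render_ppg_wave(t, beats, rr, params$ppg_amplitude)
    },
    EDA = eda_divider_voltage(render_eda_resistance(t, params), config))
  add_contamination(v, t, config)
}

#' Simulate one physiological channel
#'
#' Renders a clean waveform for the requested channel from the emotion-class
#' physiology (`params`), passes it through the acquisition chain described
#' by `config` (EDA through the voltage divider; mains sinusoid and
#' broadband motion artifact added; 12-bit quantization), and returns it as
#' a labelled [biosignal()]. Deterministic given `config$seed`.
#'
#' @param channel `"ECG"`, `"PPG"` or `"EDA"`.
#' @param params An [emotion_class_params()].
#' @param config A [sim_config()].
#' @param quantize If `FALSE`, skip the ADC stage and return the analog
#'   voltage (used by tests isolating the quantizer).
#' @return A [biosignal()] carrying `params$label`.
#' @export
simulate_channel <- function(channel, params, config, quantize = TRUE) {
  channel <- match.arg(channel, CHANNELS)
  stopifnot(inherits(params, "emotion_class_params"),
            inherits(config, "sim_config"))
  v <- with_seed(config$seed + 97L * match(channel, CHANNELS),
                 render_channel(channel, params, config))
  out <- biosignal(v, config$sampling_rate_hz, channel, label = params$label)
  if (quantize) quantize_adc(out, config) else out
}

#' Simulate one three-channel recording
#'
#' Like [simulate_channel()] for all three channels at once, with ECG and
#' PPG sharing the same beat train (as they do physiologically).
#'
#' @inheritParams simulate_channel
#' @return A list with class `recording`: elements `ecg`, `ppg`, `eda`
#'   ([biosignal()]s), `label` and `seed`.
#' @export
simulate_recording <- function(params, config, quantize = TRUE) {
  stopifnot(inherits(params, "emotion_class_params"),
            inherits(config, "sim_config"))
  chans <- with_seed(config$seed, {
    beats <- draw_beat_times(params$heart_rate_bpm, params$hr_variability,
                             config$duration_s)
    list(ecg = render_channel("ECG", params, config, beats = beats),
         ppg = render_channel("PPG", params, config, beats = beats),
         eda = render_channel("EDA", params, config))
  })
  mk <- function(v, ch) {
    s <- biosignal(v, config$sampling_rate_hz, ch, label = params$label)
    if (quantize) quantize_adc(s, config) else s
  }
  structure(list(ecg = mk(chans$ecg, "ECG"), ppg = mk(chans$ppg, "PPG"),
                 eda = mk(chans$eda, "EDA"),
                 label = params$label, seed = config$seed),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> label=%s, seed=%d, %d samples/channel @ %g Hz\n",
              x$label, x$seed, length(x$ecg$samples),
              x$ecg$sampling_rate_hz))
  invisible(x)
}

#' Simulate a labelled multi-class dataset
#'
#' Generates `n_per_class` three-channel recordings for every class in
#' `class_params`. Per-recording seeds are derived deterministically from
#' `config$seed`, so the whole dataset is reproducible while recordings stay
#' mutually independent.
#'
#' @param class_params A list of [emotion_class_params()] with distinct
#'   labels (1 to 7 classes), e.g. [default_emotion_params()].
#' @param n_per_class Number of recordings per class (>= 1).
#' @param config A [sim_config()].
#' @return A list of `recording` objects of length
#'   `length(class_params) * n_per_class`.
#' @examples
#' cfg <- sim_config(duration_s = 4, seed = 3)
#' ds <- simulate_labeled_dataset(default_emotion_params()[1:2], 2, cfg)
#' length(ds)
#' @export
simulate_labeled_dataset <- function(class_params, n_per_class, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.list(class_params) || length(class_params) < 1L ||
      length(class_params) > 7L ||
      !all(vapply(class_params, inherits, logical(1), "emotion_class_params")))
    abort_invalid("'class_params' must be a list of 1-7 emotion_class_params")
  labels <- vapply(class_params, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    abort_invalid("duplicate labels in 'class_params'")
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L || n_per_class < 1)
    abort_invalid("'n_per_class' must be an integer >= 1")
  n_per_class <- as.integer(n_per_class)
  out <- vector("list", length(class_params) * n_per_class)
  i <- 0L
  for (p in class_params) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      rec_seed <- (config$seed + 7919 * i) %% 2147483647L
      cfg_i <- config
      cfg_i$seed <- as.integer(rec_seed)
      out[[i]] <- simulate_recording(p, cfg_i)
    }
  }
  out
}
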