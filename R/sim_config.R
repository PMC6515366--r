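#' Simulation configuration for the sensing chain
#'
#' Describes the acquisition chain the simulator emulates: sampling, the
#' electrodermal voltage divider (series resistor `divider_r1_ohms` polarised
#' at `vref_volts`), additive 50 Hz mains pickup, broadband EMG-like motion
#' artifact, and the analog-to-digital converter.
#'
#' The sampling rate must exceed twice the mains frequency so that the
#' contaminant the band-stop filter targets actually exists in-band.
#'
#' @param sampling_rate_hz Sampling rate in Hz (default 250).
#' @param duration_s Recording duration in seconds (default 10).
#' @param adc_bits ADC resolution in bits (default 12, step
#'   `vref_volts / 2^adc_bits` = 0.0008 V at the defaults).
#' @param vref_volts ADC reference / supply voltage (default 3.3 V).
#' @param divider_r1_ohms Series resistance of the EDA voltage divider
#'   (default 5e5 ohms).
#' @param mains_freq_hz Powerline frequency (default 50 Hz).
#' @param mains_amplitude Amplitude in volts of the mains sinusoid added to
#'   every channel (default 0.05).
#' @param motion_artifact_level Standard deviation in volts of broadband
#'   motion/EMG noise added to every channel (default 0.01).
#' @param seed Integer seed; all simulator randomness derives from it.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(duration_s = 4, seed = 7)
#' adc_step(cfg)
#' @export
sim_config <- function(sampling_rate_hz = 250, duration_s = 10,
                       adc_bits = 12L, vref_volts = 3.3,
                       divider_r1_ohms = 5e5, mains_freq_hz = 50,
                       mains_amplitude = 0.05, motion_artifact_level = 0.01,
                       seed = 1L) {
  num1 <- function(x, nm, positive = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (positive && x <= 0) || (!positive && x < 0))
      abort_invalid(sprintf("'%s' must be a single %s number", nm,
                            if (positive) "positive" else "non-negative"))
    as.numeric(x)
  }
  sampling_rate_hz <- num1(sampling_rate_hz, "sampling_rate_hz")
  duration_s <- num1(duration_s, "duration_s")
  vref_volts <- num1(vref_volts, "vref_volts")
  divider_r1_ohms <- num1(divider_r1_ohms, "divider_r1_ohms")
  mains_freq_hz <- num1(mains_freq_hz, "mains_freq_hz")
  mains_amplitude <- num1(mains_amplitude, "mains_amplitude", positive = FALSE)
  motion_artifact_level <- num1(motion_artifact_level, "motion_artifact_level",
                                positive = FALSE)
  if (!is.numeric(adc_bits) || length(adc_bits) != 1L || adc_bits < 1)
    abort_invalid("'adc_bits' must be an integer >= 1")
  if (sampling_rate_hz <= 2 * mains_freq_hz)
    abort_invalid("'sampling_rate_hz' must exceed 2 * mains_freq_hz")
  structure(
    list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
         adc_bits = as.integer(adc_bits), vref_volts = vref_volts,
         divider_r1_ohms = divider_r1_ohms, mains_freq_hz = mains_freq_hz,
         mains_amplitude = mains_amplitude,
         motion_artifact_level = motion_artifact_level,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> fs=%g Hz, %g s, %d-bit ADC @ %g V ",
                     "(step %.4g V), R1=%g ohm,\n  mains %g V @ %g Hz, ",
                     "motion %g V, seed %d\n"),
              x$sampling_rate_hz, x$duration_s, x$adc_bits, x$vref_volts,
              adc_step(x), x$divider_r1_ohms, x$mains_amplitude,
              x$mains_freq_hz, x$motion_artifact_level, x$seed))
  invisible(x)
}

#' ADC quantization step
#'
#' @param config A [sim_config()].
#' @return The conversion resolution `vref_volts / 2^adc_bits` in volts
#'   (0.0008 V at the 12-bit / 3.3 V defaults, after rounding to 4 decimals).
#' @export
adc_step <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$vref_volts / 2^config$adc_bits
}

#' Class-conditional physiology parameters for one emotion
#'
#' The simulator shifts heart rate, heart-rate variability, electrodermal
#' tone, skin-conductance-response rate and pulse amplitude per emotion so
#' that classifier recovery is testable. Two classes must differ on at least
#' one field or they are unlearnable; [default_emotion_params()] supplies a
#' separable-but-overlapping default set.
#'
#' @param label One of [EMOTION_LABELS].
#' @param heart_rate_bpm Mean heart rate, beats per minute.
#' @param hr_variability Relative standard deviation of beat-to-beat
#'   intervals (dimensionless, e.g. 0.05).
#' @param eda_tonic_level_ohms Baseline skin resistance in ohms (mega-ohm
#'   order for dry skin).
#' @param eda_scr_rate_per_min Mean number of phasic skin-conductance
#'   responses per minute.
#' @param ppg_amplitude Pulse-wave amplitude at the amplifier output, volts.
#'
#' @return An object of class `emotion_class_params`.
#' @export
emotion_class_params <- function(label, heart_rate_bpm, hr_variability,
                                 eda_tonic_level_ohms, eda_scr_rate_per_min,
                                 ppg_amplitude) {
  label <- match.arg(label, EMOTION_LABELS)
  if (heart_rate_bpm <= 0 || eda_tonic_level_ohms <= 0 || ppg_amplitude <= 0)
    abort_invalid("heart_rate_bpm, eda_tonic_level_ohms and ppg_amplitude must be positive")
  if (hr_variability < 0 || eda_scr_rate_per_min < 0)
    abort_invalid("hr_variability and eda_scr_rate_per_min must be non-negative")
  structure(
    list(label = label, heart_rate_bpm = heart_rate_bpm,
         hr_variability = hr_variability,
         eda_tonic_level_ohms = eda_tonic_level_ohms,
         eda_scr_rate_per_min = eda_scr_rate_per_min,
         ppg_amplitude = ppg_amplitude),
    class = "emotion_class_params")
}

#' Default per-emotion simulator parameters
#'
#' Sympathetic arousal (fear, anger, surprise) raises heart rate and
#' skin-conductance-response rate and lowers baseline skin resistance;
#' sadness does the opposite. Values are chosen to be separable but
#' overlapping across the seven classes.
#'
#' @return A named list of seven [emotion_class_params()], in
#'   [EMOTION_LABELS] order.
#' @export
default_emotion_params <- function() {
  p <- list(
    emotion_class_params("Afraid",    100, 0.08, 5.0e5, 12, 0.55),
    emotion_class_params("Angry",      95, 0.06, 6.0e5, 10, 0.70),
    emotion_class_params("Disgusted",  75, 0.04, 9.0e5,  5, 0.50),
    emotion_class_params("Happy",      80, 0.05, 8.0e5,  6, 0.65),
    emotion_class_params("Neutral",    65, 0.03, 1.2e6,  2, 0.50),
    emotion_class_params("Sad",        60, 0.02, 1.5e6,  1, 0.45),
    emotion_class_params("Surprised",  88, 0.07, 7.0e5,  8, 0.60))
  names(p) <- vapply(p, `[[`, character(1), "label")
  p
}
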