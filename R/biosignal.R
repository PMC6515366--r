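#' Construct a biosignal
#'
#' A `biosignal` is one uniformly sampled channel of physiological data:
#' the sample values (volts, unless quantized to integer ADC codes), the
#' sampling rate, the channel kind and an optional emotion label.
#'
#' @param samples Numeric vector of at least 3 samples (the second-difference
#'   statistics require N >= 3).
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param channel One of `"ECG"`, `"PPG"`, `"EDA"`.
#' @param label Optional emotion label (one of [EMOTION_LABELS]).
#' @param units Unit string, `"V"` by default (`"counts"` after integer
#'   quantization).
#'
#' @return An object of class `biosignal`.
#' @examples
#' x <- biosignal(sin(2 * pi * 1 * seq(0, 2, by = 1/250)), 250, "ECG")
#' x
#' @export
biosignal <- function(samples, sampling_rate_hz, channel,
                      label = NULL, units = "V") {
  if (!is.numeric(samples) || length(samples) < 3L)
    abort_invalid("'samples' must be a numeric vector with at least 3 samples")
  if (anyNA(samples) || any(!is.finite(samples)))
    abort_invalid("'samples' must be finite and non-missing")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    abort_invalid("'sampling_rate_hz' must be a single positive number")
  channel <- match.arg(channel, CHANNELS)
  if (!is.null(label)) label <- match.arg(label, EMOTION_LABELS)
  structure(
    list(samples = as.numeric(samples),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channel = channel,
         label = label,
         units = units),
    class = "biosignal")
}

#' @export
print.biosignal <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate_hz
  cat(sprintf("<biosignal> %s, %d samples @ %g Hz (%.2f s)%s [%s]\n",
              x$channel, length(x$samples), x$sampling_rate_hz, dur,
              if (is.null(x$label)) "" else paste0(", label=", x$label),
              x$units))
  invisible(x)
}

#' @export
length.biosignal <- function(x) length(x$samples)

#' Write a biosignal to a CSV file with a JSON sidecar
#'
#' The CSV has the two columns `time_s,value`; the sidecar (`<path>.json`)
#' records channel kind, sampling rate, label, units and, when given, the
#' seed the recording was simulated with.
#'
#' @param x A [biosignal()].
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @param seed Optional integer recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_biosignal <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "biosignal"))
  n <- length(x$samples)
  df <- data.frame(time_s = (seq_len(n) - 1L) / x$sampling_rate_hz,
                   value = x$samples)
  write.csv(df, path, row.names = FALSE)
  meta <- list(channel = x$channel,
               sampling_rate_hz = x$sampling_rate_hz,
               label = x$label,
               units = x$units,
               seed = seed)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a biosignal written by [write_biosignal()]
#'
#' @param path CSV file path (the `<path>.json` sidecar must exist).
#' @return A [biosignal()].
#' @export
read_biosignal <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    abort_invalid(sprintf("missing recording file or sidecar for '%s'", path))
  df <- read.csv(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  biosignal(df$value, meta$sampling_rate_hz, meta$channel,
            label = meta$label, units = if (is.null(meta$units)) "V" else meta$units)
}
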