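#' Design the powerline band-stop filter
#'
#' Digital Butterworth band-stop filter for removing mains interference
#' before feature extraction. The default (order 3, 48--52 Hz) targets the
#' 50 Hz European powerline frequency.
#'
#' The returned transfer function is normalised so the denominator's leading
#' coefficient is 1, and is checked for stability (all poles strictly inside
#' the unit circle).
#'
#' @param order Filter order (per band edge; default 3).
#' @param low_hz Lower stopband edge in Hz (default 48).
#' @param high_hz Upper stopband edge in Hz (default 52).
#' @param fs_hz Sampling rate in Hz.
#' @return An object of class `filter_spec`: response, family, order,
#'   cutoffs, sampling rate and the numerator/denominator coefficient
#'   vectors `b`, `a`.
#' @examples
#' spec <- design_bandstop(fs_hz = 250)
#' filter_response(spec, c(10, 50))
#' @export
design_bandstop <- function(order = 3L, low_hz = 48, high_hz = 52, fs_hz) {
  if (!is.numeric(order) || length(order) != 1L || order < 1)
    abort_invalid("'order' must be a positive integer")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    abort_invalid("'fs_hz' must be a single positive number")
  if (!(0 < low_hz && low_hz < high_hz && high_hz < fs_hz / 2))
    abort_invalid("cutoffs must satisfy 0 < low_hz < high_hz < fs_hz/2")
  bt <- signal::butter(as.integer(order), c(low_hz, high_hz) / (fs_hz / 2),
                       type = "stop")
  b <- as.numeric(bt$b) / bt$a[1]
  a <- as.numeric(bt$a) / bt$a[1]
  # poles of the transfer function in z
  poles <- polyroot(rev(a))
  if (any(Mod(poles) >= 1))
    abort_invalid("designed filter is unstable")  # not reachable for valid cutoffs
  structure(
    list(response = "bandstop", family = "Butterworth",
         order = as.integer(order), low_cutoff_hz = low_hz,
         high_cutoff_hz = high_hz, sampling_rate_hz = fs_hz,
         b = b, a = a),
    class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s %s order %d, %g-%g Hz @ fs=%g Hz\n",
              x$family, x$response, x$order, x$low_cutoff_hz,
              x$high_cutoff_hz, x$sampling_rate_hz))
  invisible(x)
}

#' Apply a filter with zero phase
#'
#' Forward--backward application of `spec` to a [biosignal()]: the signal is
#' extended at both ends by odd reflection over `3 * order` samples, the
#' filter is run forward and backward with steady-state initial conditions
#' (so a constant input maps to itself), and the extension is discarded.
#' Output length equals input length and the effective magnitude response is
#' `|H|^2` with zero phase shift.
#'
#' @param spec A [design_bandstop()] filter specification.
#' @param signal A [biosignal()] whose sampling rate matches `spec`.
#' @return The filtered [biosignal()].
#' @export
apply_filter <- function(spec, signal) {
  stopifnot(inherits(spec, "filter_spec"), inherits(signal, "biosignal"))
  if (!isTRUE(all.equal(spec$sampling_rate_hz, signal$sampling_rate_hz)))
    abort_invalid("filter and signal sampling rates differ")
  x <- signal$samples
  npad <- 3L * spec$order
  if (length(x) <= npad)
    abort_invalid("signal shorter than 3x the filter order")
  ext <- c(2 * x[1] - x[(npad + 1L):2L],
           x,
           2 * x[length(x)] - x[(length(x) - 1L):(length(x) - npad)])
  y <- zero_phase_pass(spec$b, spec$a, ext)
  out <- y[(npad + 1L):(npad + length(x))]
  biosignal(out, signal$sampling_rate_hz, signal$channel,
            label = signal$label, units = signal$units)
}

# One filter pass with initial conditions at the steady state of a step of
# the signal's first value, so constants map to constants with no transient.
steady_pass <- function(b, a, x) {
  g <- sum(b) / sum(a)  # DC gain
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1L),
                            init.y = rep(x[1] * g, length(a) - 1L)))
}

zero_phase_pass <- function(b, a, x) {
  fwd <- steady_pass(b, a, x)
  rev(steady_pass(b, a, rev(fwd)))
}

#' Magnitude response of a filter in dB
#'
#' Evaluates `20 * log10(|H(e^{i 2 pi f / fs})|)` directly from the
#' transfer-function coefficients at the requested frequencies (single
#' forward pass; zero-phase application squares the magnitude, i.e. doubles
#' the dB values).
#'
#' @param spec A [design_bandstop()] filter specification.
#' @param freqs_hz Frequencies in `[0, fs/2)`, in Hz; an empty vector yields
#'   an empty result.
#' @return Attenuations in dB (negative in the stopband).
#' @export
filter_response <- function(spec, freqs_hz) {
  stopifnot(inherits(spec, "filter_spec"))
  if (length(freqs_hz) == 0L) return(numeric(0))
  if (!is.numeric(freqs_hz) || any(freqs_hz < 0) ||
      any(freqs_hz >= spec$sampling_rate_hz / 2))
    abort_invalid("frequencies must lie in [0, fs/2)")
  w <- 2 * pi * freqs_hz / spec$sampling_rate_hz
  z <- exp(-1i * w)
  h <- vapply(z, function(zz) {
    num <- sum(spec$b * zz^(seq_along(spec$b) - 1L))
    den <- sum(spec$a * zz^(seq_along(spec$a) - 1L))
    Mod(num / den)
  }, numeric(1))
  20 * log10(h)
}

#' Serialize a filter specification to JSON
#'
#' Writes design parameters and coefficient arrays for provenance logging;
#' [read_filter_spec()] reads it back.
#'
#' @param spec A `filter_spec`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_spec <- function(spec, path) {
  stopifnot(inherits(spec, "filter_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_spec
#' @export
read_filter_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(response = x$response, family = x$family,
                 order = as.integer(x$order),
                 low_cutoff_hz = x$low_cutoff_hz,
                 high_cutoff_hz = x$high_cutoff_hz,
                 sampling_rate_hz = x$sampling_rate_hz,
                 b = as.numeric(x$b), a = as.numeric(x$a)),
            class = "filter_spec")
}
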