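#' Z-normalise a biosignal
#'
#' Centres the samples to mean 0 and scales them to sample standard
#' deviation 1 (the `1/(N-1)` normalisation, used consistently throughout
#' the feature set). The normalised statistics are undefined for constant
#' signals, which raise a degenerate-signal error for the caller to handle.
#'
#' @param signal A [biosignal()] with non-zero sample standard deviation.
#' @return The z-normalised [biosignal()] (units become `"z"`).
#' @export
znormalize <- function(signal) {
  stopifnot(inherits(signal, "biosignal"))
  s <- sd(signal$samples)
  if (s == 0)
    abort_degenerate("constant signal: z-normalisation undefined")
  biosignal((signal$samples - mean(signal$samples)) / s,
            signal$sampling_rate_hz, signal$channel,
            label = signal$label, units = "z")
}

#' The six per-channel statistics
#'
#' Computes, for one channel with samples `X_1..X_N`:
#'
#' * `mean`: the sample mean;
#' * `std`: the sample standard deviation (`1/(N-1)` normalisation);
#' * `afd`: mean absolute first difference,
#'   `sum(|X_{n+1} - X_n|) / (N-1)`, on the raw samples;
#' * `afdn`: the same on the z-normalised samples;
#' * `asd`: mean absolute second difference,
#'   `sum(|X_{n+2} - X_n|) / (N-2)`, on the raw samples;
#' * `asdn`: the same on the z-normalised samples.
#'
#' These are the classic statistical features used for emotion recognition
#' from physiological signals. The raw-scale statistics scale linearly with
#' the signal; the normalised ones are invariant under positive affine
#' transformations.
#'
#' @param signal A [biosignal()] with at least 3 samples.
#' @param partial If `TRUE`, a constant signal yields `NA` for `afdn`/`asdn`
#'   instead of an error (the other four statistics are always defined).
#' @return An object of class `channel_features`: a named numeric vector of
#'   the six statistics with the channel kind attached.
#' @examples
#' channel_features(biosignal(c(0, 1, 3), 10, "ECG"))
#' @export
channel_features <- function(signal, partial = FALSE) {
  stopifnot(inherits(signal, "biosignal"))
  x <- signal$samples
  n <- length(x)
  if (n < 3L)
    abort_invalid("at least 3 samples are required")
  out <- c(mean = mean(x),
           std = sd(x),
           afd = mean(abs(diff(x))),
           afdn = NA_real_,
           asd = mean(abs(diff(x, lag = 2L))),
           asdn = NA_real_)
  if (out[["std"]] > 0) {
    z <- (x - out[["mean"]]) / out[["std"]]
    out[["afdn"]] <- mean(abs(diff(z)))
    out[["asdn"]] <- mean(abs(diff(z, lag = 2L)))
  } else if (!partial) {
    abort_degenerate("constant signal: normalised differences undefined")
  }
  structure(out, channel = signal$channel, class = "channel_features")
}

#' @export
print.channel_features <- function(x, ...) {
  cat(sprintf("<channel_features> %s\n", attr(x, "channel")))
  print(unclass(x), ...)
  invisible(x)
}

#' Assemble the 18-dimensional classifier input
#'
#' Joins the six statistics of each channel into the fixed-order feature
#' vector the classifier consumes: ECG first, then PPG, then EDA, each in
#' the order mean, std, afd, afdn, asd, asdn. Channels are matched by the
#' kind recorded on each [channel_features()] object, not by argument
#' position.
#'
#' @param ... Exactly three `channel_features`, one per channel, in any
#'   order.
#' @param label Optional emotion label.
#' @return An object of class `feature_vector`: a named numeric vector of
#'   length 18 with an optional `label` attribute.
#' @export
assemble_vector <- function(..., label = NULL) {
  parts <- list(...)
  if (length(parts) != 3L ||
      !all(vapply(parts, inherits, logical(1), "channel_features")))
    abort_invalid("exactly three channel_features objects are required")
  kinds <- vapply(parts, attr, character(1), "channel")
  if (!setequal(kinds, CHANNELS))
    abort_invalid("one channel_features per channel (ECG, PPG, EDA) is required")
  names(parts) <- kinds
  vals <- unlist(lapply(CHANNELS, function(ch) {
    v <- unclass(parts[[ch]])
    names(v) <- paste(tolower(ch), names(v), sep = "_")
    v
  }))
  if (!is.null(label)) label <- match.arg(label, EMOTION_LABELS)
  structure(vals, label = label, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  lb <- attr(x, "label")
  cat(sprintf("<feature_vector> length %d%s\n", length(x),
              if (is.null(lb)) "" else paste0(", label=", lb)))
  print(unclass(x), ...)
  invisible(x)
}

#' Feature vector for one recording
#'
#' Convenience pipeline step: optionally band-stop-filters each channel of a
#' recording (the default, matching the processing order of the sensing
#' pipeline: clean first, then extract), then computes the per-channel
#' statistics and assembles the 18-dimensional vector.
#'
#' @param recording A `recording` from [simulate_recording()] (or any list
#'   with `ecg`, `ppg`, `eda` [biosignal()]s and a `label`).
#' @param filter_spec A [design_bandstop()] specification, or `NULL` to use
#'   the default design at the recording's sampling rate.
#' @param filtered If `FALSE`, compute features on the raw signals.
#' @return A [assemble_vector()] `feature_vector` carrying the recording's
#'   label.
#' @export
recording_features <- function(recording, filter_spec = NULL, filtered = TRUE) {
  sigs <- list(recording$ecg, recording$ppg, recording$eda)
  if (filtered) {
    if (is.null(filter_spec))
      filter_spec <- design_bandstop(fs_hz = sigs[[1]]$sampling_rate_hz)
    sigs <- lapply(sigs, function(s) apply_filter(filter_spec, s))
  }
  feats <- lapply(sigs, channel_features)
  assemble_vector(feats[[1]], feats[[2]], feats[[3]],
                  label = recording$label)
}

#' Feature vectors for a whole dataset
#'
#' @param dataset A list of recordings from [simulate_labeled_dataset()].
#' @inheritParams recording_features
#' @return A list of `feature_vector`s.
#' @export
dataset_features <- function(dataset, filter_spec = NULL, filtered = TRUE) {
  if (filtered && is.null(filter_spec) && length(dataset) > 0L)
    filter_spec <- design_bandstop(fs_hz = dataset[[1]]$ecg$sampling_rate_hz)
  lapply(dataset, recording_features, filter_spec = filter_spec,
         filtered = filtered)
}

#' Write feature vectors to a CSV table
#'
#' One row per vector: the 18 named feature columns plus a `label` column
#' (empty string when unlabelled). [read_feature_table()] reads it back.
#'
#' @param vectors A list of `feature_vector`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(vectors, path) {
  m <- do.call(rbind, lapply(vectors, unclass))
  df <- as.data.frame(m)
  df$label <- vapply(vectors, function(v) {
    lb <- attr(v, "label"); if (is.null(lb)) "" else lb
  }, character(1))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  labcol <- df$label
  df$label <- NULL
  lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, ])
    names(v) <- names(df)
    lb <- if (!is.null(labcol) && nzchar(labcol[i])) labcol[i] else NULL
    structure(v, label = lb, class = "feature_vector")
  })
}
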