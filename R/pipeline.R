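#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations so a whole run (simulate, filter,
#' featurise, train, recommend) is reproducible from one object plus its
#' seeds.
#'
#' @param sim A [sim_config()].
#' @param filter_params List with `order`, `low_hz`, `high_hz` for
#'   [design_bandstop()] (the sampling rate comes from `sim`).
#' @param model A [model_config()].
#' @param split A [split_spec()].
#' @param recommender A [recommender_config()].
#' @param n_per_class Recordings per class for simulation (default 60).
#' @param class_params Per-emotion simulator parameters (default
#'   [default_emotion_params()]).
#' @param output_dir Directory runs write into.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            filter_params = list(order = 3L, low_hz = 48,
                                                 high_hz = 52),
                            model = model_config(),
                            split = split_spec(),
                            recommender = recommender_config(),
                            n_per_class = 60L,
                            class_params = default_emotion_params(),
                            output_dir = tempfile("affectsense-run-")) {
  stopifnot(inherits(sim, "sim_config"), inherits(model, "model_config"),
            inherits(split, "split_spec"),
            inherits(recommender, "recommender_config"))
  # fail fast on an undesignable filter before anything is written
  design_bandstop(filter_params$order, filter_params$low_hz,
                  filter_params$high_hz, sim$sampling_rate_hz)
  structure(list(sim = sim, filter_params = filter_params, model = model,
                 split = split, recommender = recommender,
                 n_per_class = as.integer(n_per_class),
                 class_params = class_params,
                 output_dir = output_dir),
            class = "pipeline_config")
}

pipeline_filter <- function(config) {
  design_bandstop(config$filter_params$order, config$filter_params$low_hz,
                  config$filter_params$high_hz, config$sim$sampling_rate_hz)
}

#' Simulate a labelled dataset to disk
#'
#' Writes one CSV (+ JSON sidecar) per channel per recording under
#' `config$output_dir/recordings`, and a `manifest.json` listing every
#' recording with its label, derived seed and files. Re-running with the
#' same configuration reproduces the files byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list with `recordings` and the
#'   simulation parameters).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- file.path(config$output_dir, "recordings")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  ds <- simulate_labeled_dataset(config$class_params, config$n_per_class,
                                 config$sim)
  recs <- vector("list", length(ds))
  for (i in seq_along(ds)) {
    rec <- ds[[i]]
    stem <- sprintf("rec%04d", i)
    files <- character(3)
    for (k in seq_along(CHANNELS)) {
      ch <- tolower(CHANNELS[k])
      f <- file.path(dir, sprintf("%s_%s.csv", stem, ch))
      write_biosignal(rec[[ch]], f, seed = rec$seed)
      files[k] <- basename(f)
    }
    recs[[i]] <- list(id = stem, label = rec$label, seed = rec$seed,
                      files = files)
  }
  manifest <- list(n_per_class = config$n_per_class,
                   sampling_rate_hz = config$sim$sampling_rate_hz,
                   duration_s = config$sim$duration_s,
                   seed = config$sim$seed,
                   recordings = recs)
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

load_recorded_dataset <- function(dataset_dir) {
  manifest_path <- file.path(dataset_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json under ", dataset_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  lapply(manifest$recordings, function(r) {
    sigs <- lapply(unlist(r$files), function(f)
      read_biosignal(file.path(dataset_dir, "recordings", f)))
    names(sigs) <- vapply(sigs, function(s) tolower(s$channel), character(1))
    structure(list(ecg = sigs$ecg, ppg = sigs$ppg, eda = sigs$eda,
                   label = r$label, seed = r$seed),
              class = "recording")
  })
}

#' Train the classifier from a simulated-dataset directory
#'
#' Loads the recordings listed in the dataset's manifest, band-stop-filters
#' them, extracts the 18 features, splits 80/10/10, trains the network and
#' persists under `config$output_dir`: the model (`model.json`), the split
#' indices (`split_indices.csv`), the per-epoch metrics (`metrics.csv`) and
#' the feature table (`features.csv`).
#'
#' @param config A [pipeline_config()].
#' @param dataset_dir Directory produced by [run_simulation()] (defaults to
#'   `config$output_dir`).
#' @return A list with the trained `model`, the `split`, and `metrics`
#'   (the held-out `test` evaluation from [evaluate()]), invisibly.
#' @export
run_training <- function(config, dataset_dir = config$output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- load_recorded_dataset(dataset_dir)
  vectors <- dataset_features(ds, pipeline_filter(config))
  parts <- split_dataset(vectors, config$split)
  model <- train_model(parts$train, parts$validation, config$model)
  test_metrics <- evaluate(model, parts$test)

  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write_emotion_model(model, file.path(out, "model.json"))
  write_feature_table(vectors, file.path(out, "features.csv"))
  idx <- data.frame(
    index = c(parts$indices$train, parts$indices$test,
              parts$indices$validation),
    partition = rep(c("train", "test", "validation"),
                    times = lengths(parts$indices)))
  write.csv(idx[order(idx$index), ], file.path(out, "split_indices.csv"),
            row.names = FALSE)
  metrics <- cbind(model$history,
                   test_accuracy = c(rep(NA, nrow(model$history) - 1L),
                                     test_metrics$accuracy))
  write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
  invisible(list(model = model, split = parts, metrics = test_metrics))
}

#' Run the end-to-end operation demo
#'
#' Reproduces the assistant's operation flux on synthetic data: the user is
#' registered, the sensors are read (one simulated recording per round, with
#' the scripted true emotion), the classifier estimates the emotional state,
#' the recommender suggests and schedules an activity, and the user's
#' scripted accept/deny response is fed back, updating preferences and the
#' denial counter. Everything is appended to a structured event log
#' (written as JSON lines when `log_path` is given).
#'
#' @param model A trained `emotion_mlp` (a missing/untrained model is a
#'   state error).
#' @param catalog List of [activity()]s.
#' @param profile A [user_profile()].
#' @param config A [pipeline_config()]; its `sim` seed drives the per-round
#'   recordings.
#' @param true_emotions Character vector, one emotion label per round, the
#'   simulator should express.
#' @param responses Logical vector, one scripted accept/deny per round.
#' @param state A [recommender_state()] (fresh by default).
#' @param log_path Optional JSON-lines output path.
#' @return A list with the `events` log, final `profile` and `state`.
#' @export
run_demo <- function(model, catalog, profile, config = pipeline_config(),
                     true_emotions, responses,
                     state = recommender_state(config$recommender),
                     log_path = NULL) {
  if (!inherits(model, "emotion_mlp"))
    abort_state("a trained model is required for the demo")
  stopifnot(length(true_emotions) == length(responses))
  fspec <- pipeline_filter(config)
  events <- list(list(event = "registration", user_id = profile$id))
  log_event <- function(e) events[[length(events) + 1L]] <<- e

  for (round in seq_along(true_emotions)) {
    lbl <- match.arg(true_emotions[round], EMOTION_LABELS)
    cfg_i <- config$sim
    cfg_i$seed <- as.integer((config$sim$seed + 104729 * round) %% 2147483647)
    rec <- simulate_recording(config$class_params[[lbl]], cfg_i)
    log_event(list(event = "sensing", round = round, seed = cfg_i$seed,
                   true_label = lbl))
    est <- predict(model, recording_features(rec, fspec))
    log_event(list(event = "emotion_estimate", round = round,
                   label = est$argmax_label,
                   probabilities = as.list(est$probabilities)))
    sugg <- tryCatch(recommend(profile, catalog, est, state),
                     affectsense_invalid = function(e) NULL)
    if (is.null(sugg)) {
      log_event(list(event = "no_candidate", round = round))
      next
    }
    log_event(list(event = "suggestion", round = round,
                   activity_id = sugg$activity$id, score = sugg$score,
                   policy_fallback = sugg$policy_fallback))
    sched <- schedule_activity(sugg$activity, profile)
    if (sched$status == "scheduled") {
      profile <- sched$profile
      log_event(list(event = "scheduled", round = round,
                     start = format(sched$start, "%Y-%m-%dT%H:%M:%S"),
                     end = format(sched$end, "%Y-%m-%dT%H:%M:%S")))
    } else {
      log_event(list(event = "no_slot", round = round))
    }
    n_notif <- length(state$notifications)
    fb <- register_feedback(sugg$activity, responses[round], profile, state)
    profile <- fb$profile
    state <- fb$state
    log_event(list(event = "feedback", round = round,
                   activity_id = sugg$activity$id,
                   accepted = responses[round],
                   preference = unname(
                     profile$preferences[[sugg$activity$id]]),
                   denial_counter = unname(
                     state$denial_counters[[profile$id]])))
    if (length(state$notifications) > n_notif)
      log_event(list(event = "caregiver_notification", round = round,
                     reason = state$notifications[[
                       length(state$notifications)]]$reason))
  }
  if (!is.null(log_path)) {
    con <- file(log_path, open = "w")
    on.exit(close(con))
    for (e in events)
      writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA), con)
  }
  list(events = events, profile = profile, state = state)
}
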