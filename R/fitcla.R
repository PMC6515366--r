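#' @name fitcla
#' @title Health-profile-aware activity recommendation
#'
#' @description
#' The recommender scores each catalogued activity against a user's health
#' profile. Every activity rates its physical/cognitive impact per body or
#' ability feature on the ordinal scale none < light < mild < hard; the
#' user's profile records, per feature, the maximum impact they may safely
#' receive. Feature compatibilities are combined as a weighted sum capped at
#' 0.9, the remaining 0.1 being the learned user preference — so a fully
#' compatible activity the user is indifferent to scores exactly 0.9, and
#' the score is bounded by 1.
#'
#' Feedback drives two adaptations: each accept/deny nudges the per-activity
#' preference weight up/down by a learning step, and seven *consecutive*
#' denials of activities that closely fit the health profile trigger a
#' reweighting (the feature cap is decreased and the preference share
#' increased, keeping their sum at 1) plus a caregiver notification.
#'
#' Recommendations are also conditioned on the current emotional state:
#' high-intensity activities act as emotional boosters (suggested for flat
#' or sad states), low-intensity ones as de-stressers (suggested for
#' agitated states).
NULL

IMPACT_LEVELS <- c("none", "light", "mild", "hard")

#' Default ability/impact feature names
#'
#' Body regions, a cognitive-load rating and a binary dangerous-tools flag.
#' @return Character vector of feature names.
#' @export
default_feature_names <- function() {
  c("shoulders", "arms", "column", "legs", "feet", "cognitive",
    "dangerous_tools")
}

check_level <- function(x, nm) {
  if (!is.character(x) || length(x) != 1L || !(x %in% IMPACT_LEVELS))
    abort_invalid(sprintf("'%s' must be one of %s", nm,
                          paste(IMPACT_LEVELS, collapse = ", ")))
  x
}

#' Construct an activity
#'
#' @param id,name Identifier and display name.
#' @param impact_ratings Named character vector/list mapping feature names to
#'   impact levels (`"none"`, `"light"`, `"mild"`, `"hard"`); at least one
#'   feature must be rated. Unrated features count as `"none"` when scoring.
#' @param intensity_class `"high"` (emotional booster) or `"low"`
#'   (emotional de-stresser).
#' @param duration_min Positive duration in minutes.
#' @return An object of class `activity`.
#' @examples
#' activity("gard01", "Light gardening",
#'          c(shoulders = "mild", arms = "mild", column = "mild",
#'            legs = "light", feet = "light", cognitive = "mild",
#'            dangerous_tools = "hard"),
#'          intensity_class = "low", duration_min = 30)
#' @export
activity <- function(id, name, impact_ratings, intensity_class,
                     duration_min) {
  impact_ratings <- unlist(impact_ratings)
  if (length(impact_ratings) < 1L || is.null(names(impact_ratings)))
    abort_invalid("at least one named impact rating is required")
  for (f in names(impact_ratings)) check_level(impact_ratings[[f]], f)
  intensity_class <- match.arg(intensity_class, c("high", "low"))
  if (!is.numeric(duration_min) || duration_min <= 0)
    abort_invalid("'duration_min' must be positive")
  structure(list(id = as.character(id), name = as.character(name),
                 impact_ratings = impact_ratings,
                 intensity_class = intensity_class,
                 duration_min = as.numeric(duration_min)),
            class = "activity")
}

#' @export
print.activity <- function(x, ...) {
  cat(sprintf("<activity> %s (%s): %s intensity, %g min\n  impact: %s\n",
              x$id, x$name, x$intensity_class, x$duration_min,
              paste(names(x$impact_ratings), x$impact_ratings,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Construct a user profile
#'
#' @param id User identifier.
#' @param ability_ratings Named character vector mapping feature names to
#'   the maximum impact the user may safely receive (`"none"` to `"hard"`).
#' @param preferences Named numeric vector of per-activity preference
#'   weights in `[0, 1]` (empty by default; learned from feedback).
#' @param free_slots Data frame with `start` and `end` columns (POSIXct),
#'   sorted and non-overlapping, of the user's free time.
#' @return An object of class `user_profile`.
#' @export
user_profile <- function(id, ability_ratings, preferences = numeric(0),
                         free_slots = NULL) {
  ability_ratings <- unlist(ability_ratings)
  if (length(ability_ratings) < 1L || is.null(names(ability_ratings)))
    abort_invalid("at least one named ability rating is required")
  for (f in names(ability_ratings)) check_level(ability_ratings[[f]], f)
  preferences <- unlist(preferences)
  if (length(preferences) > 0L &&
      (any(preferences < 0) || any(preferences > 1)))
    abort_invalid("preference weights must lie in [0, 1]")
  if (is.null(free_slots))
    free_slots <- data.frame(start = as.POSIXct(character(0)),
                             end = as.POSIXct(character(0)))
  structure(list(id = as.character(id), ability_ratings = ability_ratings,
                 preferences = preferences, free_slots = free_slots),
            class = "user_profile")
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf("<user_profile> %s\n  tolerates: %s\n  %d preference(s), %d free slot(s)\n",
              x$id,
              paste(names(x$ability_ratings), x$ability_ratings,
                    sep = "=", collapse = ", "),
              length(x$preferences), nrow(x$free_slots)))
  invisible(x)
}

#' Recommender configuration
#'
#' The health-feature component of every score is capped at `feature_cap`
#' (default 0.9) and the user-preference component at `preference_share`
#' (default 0.1); the two always sum to 1. Feature weights start equal and
#' sum to the cap.
#'
#' @param feature_names Features the weights cover (default
#'   [default_feature_names()]).
#' @param feature_cap Maximum attainable health-feature score (default 0.9).
#' @param preference_share Weight of the user-preference term (default 0.1);
#'   must satisfy `feature_cap + preference_share = 1`.
#' @param denial_threshold Consecutive close-fit denials that trigger
#'   reweighting and a caregiver notification (default 7).
#' @param close_fit_min_score Health-feature score at or above which an
#'   activity is considered to closely fit the profile (default 0.7).
#' @param learning_step Preference increment/decrement per accept/deny
#'   feedback (default 0.05).
#' @param reweight_step Amount moved from `feature_cap` to
#'   `preference_share` when the denial threshold fires (default 0.05).
#' @return An object of class `recommender_config`.
#' @export
recommender_config <- function(feature_names = default_feature_names(),
                               feature_cap = 0.9, preference_share = 0.1,
                               denial_threshold = 7L,
                               close_fit_min_score = 0.7,
                               learning_step = 0.05, reweight_step = 0.05) {
  if (abs(feature_cap + preference_share - 1) > 1e-9)
    abort_invalid("feature_cap + preference_share must equal 1")
  if (feature_cap < 0 || preference_share < 0)
    abort_invalid("feature_cap and preference_share must be non-negative")
  if (close_fit_min_score < 0 || close_fit_min_score > feature_cap)
    abort_invalid("'close_fit_min_score' must lie in [0, feature_cap]")
  if (denial_threshold < 1)
    abort_invalid("'denial_threshold' must be >= 1")
  w <- rep(feature_cap / length(feature_names), length(feature_names))
  names(w) <- feature_names
  structure(list(feature_weights = w, feature_cap = feature_cap,
                 preference_share = preference_share,
                 denial_threshold = as.integer(denial_threshold),
                 close_fit_min_score = close_fit_min_score,
                 learning_step = learning_step,
                 reweight_step = reweight_step),
            class = "recommender_config")
}

#' Recommender state
#'
#' Mutable state threaded through [recommend()] and [register_feedback()]:
#' the live configuration (its weights change when reweighting fires),
#' per-user counters of consecutive close-fit denials, and the caregiver
#' notification log.
#'
#' @param config A [recommender_config()].
#' @return An object of class `recommender_state`.
#' @export
recommender_state <- function(config = recommender_config()) {
  stopifnot(inherits(config, "recommender_config"))
  structure(list(config = config,
                 denial_counters = integer(0),
                 notifications = list()),
            class = "recommender_state")
}

#' Compatibility between one impact rating and one tolerance
#'
#' Levels are ordinal (none < light < mild < hard). An impact within the
#' user's tolerance is fully compatible (1); beyond it, compatibility
#' decreases linearly with the ordinal gap (`1 - gap/3`). Binary features
#' such as `dangerous_tools` admit no partial credit: any excess impact
#' scores 0.
#'
#' @param activity_impact,user_tolerance Levels on the ordinal scale.
#' @param binary If `TRUE`, use the all-or-nothing rule.
#' @return A compatibility in `[0, 1]`.
#' @examples
#' feature_compatibility("mild", "light")   # gap 1 of 3 -> 2/3
#' @export
feature_compatibility <- function(activity_impact, user_tolerance,
                                  binary = FALSE) {
  ai <- match(check_level(activity_impact, "activity_impact"), IMPACT_LEVELS)
  ut <- match(check_level(user_tolerance, "user_tolerance"), IMPACT_LEVELS)
  if (ai <= ut) return(1)
  if (binary) return(0)
  1 - (ai - ut) / 3
}

#' Score an activity for a user
#'
#' `score = sum_f weight_f * compatibility_f + preference_share * preference`
#' over all configured features. Features the activity does not rate count
#' as zero impact (fully compatible); features the user's profile does not
#' rate are assumed tolerated at `"hard"`. The score lies in `[0, 1]` and
#' reaches `feature_cap` + `preference_share` only for a fully compatible,
#' maximally preferred activity.
#'
#' @param activity An [activity()]; rating a feature absent from the
#'   configured weights is an error.
#' @param profile A [user_profile()].
#' @param config A [recommender_config()].
#' @return A single numeric score.
#' @export
score_activity <- function(activity, profile, config = recommender_config()) {
  stopifnot(inherits(activity, "activity"), inherits(profile, "user_profile"),
            inherits(config, "recommender_config"))
  unknown <- setdiff(names(activity$impact_ratings),
                     names(config$feature_weights))
  if (length(unknown) > 0L)
    abort_invalid(sprintf("activity rates unconfigured feature(s): %s",
                          paste(unknown, collapse = ", ")))
  total <- 0
  for (f in names(config$feature_weights)) {
    impact <- if (f %in% names(activity$impact_ratings))
      activity$impact_ratings[[f]] else "none"
    tol <- if (f %in% names(profile$ability_ratings))
      profile$ability_ratings[[f]] else "hard"
    total <- total + config$feature_weights[[f]] *
      feature_compatibility(impact, tol, binary = (f == "dangerous_tools"))
  }
  pref <- if (activity$id %in% names(profile$preferences))
    profile$preferences[[activity$id]] else 0
  unname(total + config$preference_share * pref)
}

# health-feature component only (used for the close-fit test)
feature_score <- function(activity, profile, config) {
  pref_share <- config$preference_share
  s <- score_activity(activity, profile, config)
  pref <- if (activity$id %in% names(profile$preferences))
    profile$preferences[[activity$id]] else 0
  s - pref_share * pref
}

# label -> intensity filter of the boost/counteract policy
#' Emotion to activity-intensity policy
#'
#' Flat or low moods get high-intensity boosters; agitated negative states
#' get low-intensity de-stressers; positive, energised states are not
#' filtered.
#'
#' @param label One of [EMOTION_LABELS].
#' @return `"high"`, `"low"`, or `NA` (no filter).
#' @export
emotion_policy <- function(label) {
  label <- match.arg(label, EMOTION_LABELS)
  if (label %in% c("Sad", "Neutral")) return("high")
  if (label %in% c("Angry", "Afraid", "Disgusted")) return("low")
  NA_character_
}

#' Recommend an activity
#'
#' Filters the catalog by the boost/counteract emotion policy (falling back
#' to the unfiltered catalog, with a note, when the filter empties it), then
#' ranks by [score_activity()] under the state's live configuration. Ties
#' break towards the higher preference weight, then the lexicographically
#' smaller activity id. Deterministic.
#'
#' @param profile A [user_profile()].
#' @param catalog Non-empty list of [activity()]s.
#' @param emotion An `emotion_estimate` (or `NULL` to skip the policy
#'   filter).
#' @param state A [recommender_state()].
#' @return A list: `activity`, `score`, and `policy_fallback` (`TRUE` when
#'   the emotion filter emptied the catalog and the unfiltered ranking was
#'   used).
#' @export
recommend <- function(profile, catalog, emotion = NULL,
                      state = recommender_state()) {
  stopifnot(inherits(profile, "user_profile"),
            inherits(state, "recommender_state"))
  if (length(catalog) == 0L)
    abort_invalid("empty activity catalog")
  stopifnot(all(vapply(catalog, inherits, logical(1), "activity")))
  pool <- catalog
  fallback <- FALSE
  if (!is.null(emotion)) {
    stopifnot(inherits(emotion, "emotion_estimate"))
    want <- emotion_policy(emotion$argmax_label)
    if (!is.na(want)) {
      keep <- vapply(pool, function(a) a$intensity_class == want, logical(1))
      if (any(keep)) pool <- pool[keep] else fallback <- TRUE
    }
  }
  scores <- vapply(pool, score_activity, numeric(1),
                   profile = profile, config = state$config)
  prefs <- vapply(pool, function(a) {
    if (a$id %in% names(profile$preferences))
      profile$preferences[[a$id]] else 0
  }, numeric(1))
  ids <- vapply(pool, `[[`, character(1), "id")
  best <- order(-scores, -prefs, ids)[1L]
  list(activity = pool[[best]], score = scores[best],
       policy_fallback = fallback)
}

#' Register accept/deny feedback for a recommended activity
#'
#' Acceptance raises the user's preference weight for the activity by the
#' learning step (clipped to `[0, 1]`) and resets the consecutive-denial
#' counter. Denial lowers the preference; when the denied activity closely
#' fits the health profile (health-feature score at or above
#' `close_fit_min_score`), the counter increments, and on reaching the
#' denial threshold the configuration is reweighted — `feature_cap`
#' decreases by the reweight step, `preference_share` increases to keep the
#' sum at 1, feature weights are rescaled — the counter resets and a
#' caregiver notification is logged. Repeated thresholds re-apply the
#' reweighting.
#'
#' @param activity The recommended [activity()].
#' @param accepted Logical.
#' @param profile The [user_profile()] it was recommended to.
#' @param state The current [recommender_state()].
#' @param time Timestamp recorded on notifications (default [Sys.time()]).
#' @return A list with the updated `profile` and `state`.
#' @export
register_feedback <- function(activity, accepted, profile, state,
                              time = Sys.time()) {
  stopifnot(inherits(activity, "activity"),
            inherits(profile, "user_profile"),
            inherits(state, "recommender_state"),
            is.logical(accepted), length(accepted) == 1L)
  delta <- state$config$learning_step
  pref <- if (activity$id %in% names(profile$preferences))
    profile$preferences[[activity$id]] else 0
  uid <- profile$id
  counter <- if (uid %in% names(state$denial_counters))
    state$denial_counters[[uid]] else 0L
  if (accepted) {
    pref <- min(1, pref + delta)
    counter <- 0L
  } else {
    close_fit <- feature_score(activity, profile, state$config) >=
      state$config$close_fit_min_score
    pref <- max(0, pref - delta)
    if (close_fit) counter <- counter + 1L
    if (counter >= state$config$denial_threshold) {
      step <- min(state$config$reweight_step, state$config$feature_cap)
      cfg <- state$config
      old_cap <- cfg$feature_cap
      cfg$feature_cap <- old_cap - step
      cfg$preference_share <- cfg$preference_share + step
      cfg$feature_weights <- if (old_cap > 0)
        cfg$feature_weights * cfg$feature_cap / old_cap
      else cfg$feature_weights
      cfg$close_fit_min_score <- min(cfg$close_fit_min_score,
                                     cfg$feature_cap)
      state$config <- cfg
      counter <- 0L
      state$notifications[[length(state$notifications) + 1L]] <-
        list(time = format(time, "%Y-%m-%dT%H:%M:%S%z"),
             user_id = uid, reason = "re-weight")
    }
  }
  profile$preferences[[activity$id]] <- pref
  state$denial_counters[[uid]] <- counter
  list(profile = profile, state = state)
}

#' Schedule an activity in the user's free time
#'
#' Earliest-fit: the first free slot at least as long as the activity is
#' used and shrunk accordingly. The absence of a long-enough slot is a
#' signal, not an error.
#'
#' @param activity An [activity()].
#' @param profile A [user_profile()] whose `free_slots` are sorted and
#'   non-overlapping.
#' @return A list with `status` (`"scheduled"` or `"no_slot"`); when
#'   scheduled, also `start`, `end` and the updated `profile`.
#' @export
schedule_activity <- function(activity, profile) {
  stopifnot(inherits(activity, "activity"), inherits(profile, "user_profile"))
  slots <- profile$free_slots
  need <- activity$duration_min * 60
  for (i in seq_len(nrow(slots))) {
    len <- as.numeric(difftime(slots$end[i], slots$start[i], units = "secs"))
    if (len >= need) {
      start <- slots$start[i]
      end <- start + need
      if (len - need < 1e-9) {
        slots <- slots[-i, , drop = FALSE]
      } else {
        slots$start[i] <- end
      }
      profile$free_slots <- slots
      return(list(status = "scheduled", start = start, end = end,
                  profile = profile))
    }
  }
  list(status = "no_slot")
}

#' Read and write activity catalogs and user profiles as JSON
#'
#' The catalog is an array of activity documents (`id`, `name`,
#' `impact_ratings`, `intensity_class`, `duration_min`); the profile mirrors
#' [user_profile()] with free slots as ISO-8601 strings. A small
#' illustrative catalog ships with the package under
#' `system.file("extdata", "activities.json", package = "affectsense")`.
#'
#' @param path JSON file path.
#' @return `read_activity_catalog()`: a list of [activity()]s;
#'   `read_user_profile()`: a [user_profile()].
#' @export
read_activity_catalog <- function(path) {
  docs <- jsonlite::read_json(path)
  lapply(docs, function(d)
    activity(d$id, d$name, d$impact_ratings, d$intensity_class,
             d$duration_min))
}

#' @rdname read_activity_catalog
#' @param catalog A list of [activity()]s.
#' @export
write_activity_catalog <- function(catalog, path) {
  docs <- lapply(catalog, function(a)
    list(id = a$id, name = a$name,
         impact_ratings = as.list(a$impact_ratings),
         intensity_class = a$intensity_class,
         duration_min = a$duration_min))
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname read_activity_catalog
#' @export
read_user_profile <- function(path) {
  d <- jsonlite::read_json(path)
  slots <- if (length(d$free_slots) > 0L)
    data.frame(
      start = as.POSIXct(vapply(d$free_slots, `[[`, character(1), "start"),
                         format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      end = as.POSIXct(vapply(d$free_slots, `[[`, character(1), "end"),
                       format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  else NULL
  user_profile(d$id, d$ability_ratings,
               preferences = unlist(d$preferences),
               free_slots = slots)
}

#' @rdname read_activity_catalog
#' @param profile A [user_profile()].
#' @export
write_user_profile <- function(profile, path) {
  d <- list(id = profile$id,
            ability_ratings = as.list(profile$ability_ratings),
            preferences = as.list(profile$preferences),
            free_slots = lapply(seq_len(nrow(profile$free_slots)), function(i)
              list(start = format(profile$free_slots$start[i],
                                  "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   end = format(profile$free_slots$end[i],
                                "%Y-%m-%dT%H:%M:%S", tz = "UTC"))))
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Append caregiver notifications to a JSON-lines log
#'
#' @param state A [recommender_state()].
#' @param path Output file; one JSON object per line.
#' @return `path`, invisibly.
#' @export
write_notification_log <- function(state, path) {
  stopifnot(inherits(state, "recommender_state"))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (nt in state$notifications)
    writeLines(jsonlite::toJSON(nt, auto_unbox = TRUE), con)
  invisible(path)
}
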