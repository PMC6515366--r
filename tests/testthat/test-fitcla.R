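full_tolerance <- function() test_profile()

fully_compatible_activity <- function(id = "easy") {
  activity(id, "Easy activity",
           c(shoulders = "light", arms = "light", cognitive = "light"),
           intensity_class = "low", duration_min = 10)
}

test_that("ordinal feature compatibility with linear gap penalty", {
  expect_equal(feature_compatibility("light", "hard"), 1)
  expect_equal(feature_compatibility("hard", "none"), 0)
  expect_equal(feature_compatibility("mild", "light"), 2 / 3)
  expect_equal(feature_compatibility("none", "none"), 1)
  # binary features admit no partial credit
  expect_equal(feature_compatibility("mild", "light", binary = TRUE), 0)
  expect_equal(feature_compatibility("mild", "hard", binary = TRUE), 1)
  expect_error(feature_compatibility("severe", "hard"),
               class = "affectsense_invalid")
})

test_that("activity scores reach the caps exactly at the boundary cases", {
  cfg <- recommender_config()
  prof <- full_tolerance()
  act <- fully_compatible_activity()
  # fully compatible, indifferent user: exactly the feature cap
  expect_equal(score_activity(act, prof, cfg), 0.9)
  # maximal preference adds the remaining 0.1
  prof$preferences <- c(easy = 1.0)
  expect_equal(score_activity(act, prof, cfg), 1.0)
  # fully incompatible activity, indifferent user
  none_prof <- user_profile("u0", c(
    shoulders = "none", arms = "none", column = "none", legs = "none",
    feet = "none", cognitive = "none", dangerous_tools = "none"))
  hard_act <- activity("hard", "Too hard", c(
    shoulders = "hard", arms = "hard", column = "hard", legs = "hard",
    feet = "hard", cognitive = "hard", dangerous_tools = "hard"),
    intensity_class = "high", duration_min = 10)
  expect_equal(score_activity(hard_act, none_prof, cfg), 0)
  # rating a feature outside the configured weights is an error
  odd <- activity("odd", "Odd", c(balance = "mild"),
                  intensity_class = "low", duration_min = 5)
  expect_error(score_activity(odd, prof, cfg), class = "affectsense_invalid")
})

random_case <- function() {
  feats <- default_feature_names()
  act <- activity("r1", "Random",
                  stats::setNames(sample(c("none", "light", "mild", "hard"),
                                         length(feats), replace = TRUE), feats),
                  intensity_class = sample(c("high", "low"), 1),
                  duration_min = 10)
  prof <- user_profile("ru", stats::setNames(
    sample(c("none", "light", "mild", "hard"), length(feats), replace = TRUE),
    feats), preferences = stats::setNames(runif(1), "r1"))
  list(act = act, prof = prof)
}

test_that("scores are bounded and monotone in tolerance", {
  cfg <- recommender_config()
  set.seed(77)
  levels <- c("none", "light", "mild", "hard")
  for (i in 1:60) {
    cs <- random_case()
    s <- score_activity(cs$act, cs$prof, cfg)
    expect_gte(s, 0)
    expect_lte(s, 1)
    # raising one tolerance never decreases the score
    f <- sample(default_feature_names(), 1)
    cur <- match(cs$prof$ability_ratings[[f]], levels)
    if (cur < 4) {
      raised <- cs$prof
      raised$ability_ratings[[f]] <- levels[cur + 1]
      expect_gte(score_activity(cs$act, raised, cfg), s)
    }
  }
})

test_that("the score equals the cap only for full compatibility at zero preference", {
  cfg <- recommender_config()
  prof <- full_tolerance()
  act <- fully_compatible_activity()
  expect_equal(score_activity(act, prof, cfg), cfg$feature_cap)
  # any sub-tolerance feature pulls the score strictly below the cap
  prof$ability_ratings[["arms"]] <- "none"
  expect_lt(score_activity(act, prof, cfg), cfg$feature_cap)
})

test_that("recommendation ranks, breaks ties and applies the emotion policy", {
  prof <- full_tolerance()
  state <- recommender_state()
  one <- list(fully_compatible_activity("only"))
  r <- recommend(prof, one, NULL, state)
  expect_equal(r$activity$id, "only")

  # equal scores with unequal preferences: the higher preference wins.
  # 15 equal weights of 0.06 make a one-level gap cost exactly 0.02, which
  # a preference difference of 0.2 (x 0.1 share) compensates.
  feats <- paste0("f", 1:15)
  cfg15 <- recommender_config(feature_names = feats)
  st15 <- recommender_state(cfg15)
  p15 <- user_profile("u15", stats::setNames(rep("light", 15), feats),
                      preferences = c(a1 = 0.3, a2 = 0.1))
  a1 <- activity("a1", "Slightly hard",
                 stats::setNames(c("mild", rep("none", 14)), feats),
                 intensity_class = "low", duration_min = 10)
  a2 <- activity("a2", "Perfect fit",
                 stats::setNames(rep("none", 15), feats),
                 intensity_class = "low", duration_min = 10)
  expect_equal(score_activity(a1, p15, cfg15),
               score_activity(a2, p15, cfg15))
  r <- recommend(p15, list(a2, a1), NULL, st15)
  expect_equal(r$activity$id, "a1")

  # all else equal, ties resolve to the lexicographically smaller id
  b1 <- fully_compatible_activity("b1")
  b2 <- fully_compatible_activity("b2")
  r <- recommend(prof, list(b2, b1), NULL, state)
  expect_equal(r$activity$id, "b1")

  # counteract branch: Angry selects the low-intensity candidate
  lo <- fully_compatible_activity("lo")
  hi <- activity("hi", "High one",
                 c(shoulders = "light", arms = "light", cognitive = "light"),
                 intensity_class = "high", duration_min = 10)
  prof$preferences <- numeric(0)
  angry <- emotion_estimate(stats::setNames(
    c(0.05, 0.7, 0.05, 0.05, 0.05, 0.05, 0.05), EMOTION_LABELS))
  r <- recommend(prof, list(hi, lo), angry, state)
  expect_equal(r$activity$id, "lo")

  # boost branch: Sad selects the high-intensity candidate
  sad <- emotion_estimate(stats::setNames(
    c(0.05, 0.05, 0.05, 0.05, 0.05, 0.7, 0.05), EMOTION_LABELS))
  r <- recommend(prof, list(lo, hi), sad, state)
  expect_equal(r$activity$id, "hi")

  # the filter emptying the catalog falls back to the unfiltered ranking
  r <- recommend(prof, list(lo), sad, state)
  expect_true(r$policy_fallback)
  expect_equal(r$activity$id, "lo")

  expect_error(recommend(prof, list(), NULL, state),
               class = "affectsense_invalid")
})

test_that("the 7-denial threshold fires exactly on the 7th close-fit denial", {
  prof <- full_tolerance()
  state <- recommender_state()
  act <- fully_compatible_activity()   # feature score 0.9 >= close fit 0.7
  for (i in 1:6) {
    fb <- register_feedback(act, FALSE, prof, state)
    prof <- fb$profile; state <- fb$state
    expect_length(state$notifications, 0)
    expect_equal(unname(state$denial_counters[["user1"]]), i)
  }
  fb <- register_feedback(act, FALSE, prof, state)
  prof <- fb$profile; state <- fb$state
  expect_length(state$notifications, 1)
  expect_equal(state$notifications[[1]]$reason, "re-weight")
  expect_equal(state$notifications[[1]]$user_id, "user1")
  expect_equal(unname(state$denial_counters[["user1"]]), 0)
  expect_equal(state$config$feature_cap, 0.85)
  expect_equal(state$config$preference_share, 0.15)
  expect_equal(sum(state$config$feature_weights), 0.85)
})

test_that("an acceptance interrupts the consecutive-denial count", {
  prof <- full_tolerance()
  state <- recommender_state()
  act <- fully_compatible_activity()
  seqs <- c(rep(FALSE, 6), TRUE, rep(FALSE, 6))
  for (acc in seqs) {
    fb <- register_feedback(act, acc, prof, state)
    prof <- fb$profile; state <- fb$state
  }
  expect_length(state$notifications, 0)
  expect_equal(unname(state$denial_counters[["user1"]]), 6)
})

test_that("denials of poorly fitting activities never trigger reweighting", {
  prof <- user_profile("u2", c(
    shoulders = "none", arms = "none", column = "none", legs = "none",
    feet = "none", cognitive = "none", dangerous_tools = "none"))
  state <- recommender_state()
  hard_act <- activity("h", "Hard", c(
    shoulders = "hard", arms = "hard", column = "hard", legs = "hard",
    feet = "hard", cognitive = "hard"), intensity_class = "low",
    duration_min = 10)
  for (i in 1:20) {
    fb <- register_feedback(hard_act, FALSE, prof, state)
    prof <- fb$profile; state <- fb$state
  }
  expect_length(state$notifications, 0)
})

test_that("preference learning converges to 1 under repeated acceptance", {
  prof <- full_tolerance()
  state <- recommender_state()
  act <- fully_compatible_activity()
  delta <- state$config$learning_step
  n_needed <- ceiling(1 / delta)
  prefs <- numeric(n_needed + 5)
  for (i in seq_along(prefs)) {
    fb <- register_feedback(act, TRUE, prof, state)
    prof <- fb$profile; state <- fb$state
    prefs[i] <- prof$preferences[["easy"]]
  }
  expect_equal(prefs[n_needed], 1)
  expect_true(all(prefs <= 1))
  expect_true(all(diff(prefs[1:n_needed]) > 0))
})

test_that("weight conservation holds after arbitrary feedback sequences", {
  prof <- full_tolerance()
  state <- recommender_state()
  act <- fully_compatible_activity()
  set.seed(123)
  for (i in 1:500) {
    fb <- register_feedback(act, runif(1) < 0.3, prof, state)
    prof <- fb$profile; state <- fb$state
    expect_lt(abs(state$config$feature_cap +
                    state$config$preference_share - 1), 1e-9)
    expect_lt(abs(sum(state$config$feature_weights) -
                    state$config$feature_cap), 1e-9)
    expect_gte(state$config$feature_cap, 0)
  }
  expect_true(prof$preferences[["easy"]] >= 0 &&
                prof$preferences[["easy"]] <= 1)
})

test_that("scheduling takes the earliest sufficient slot and shrinks it", {
  base <- as.POSIXct("2026-01-05 09:00:00", tz = "UTC")
  prof <- full_tolerance()
  prof$free_slots <- data.frame(
    start = c(base, base + 3600),
    end = c(base + 600, base + 7200))
  act <- fully_compatible_activity()   # 10 min
  act30 <- activity("a30", "Longer", c(arms = "light"),
                    intensity_class = "low", duration_min = 30)

  # the 10-min activity fits the first (exactly 10-min) slot, consuming it
  s <- schedule_activity(act, prof)
  expect_equal(s$status, "scheduled")
  expect_equal(s$start, base)
  expect_equal(s$end, base + 600)
  expect_equal(nrow(s$profile$free_slots), 1)

  # the 30-min activity skips the short slot and shrinks the second
  s30 <- schedule_activity(act30, prof)
  expect_equal(s30$start, base + 3600)
  expect_equal(s30$end, base + 3600 + 1800)
  expect_equal(s30$profile$free_slots$start[2], base + 3600 + 1800)

  empty <- full_tolerance()
  expect_equal(schedule_activity(act, empty)$status, "no_slot")
})

test_that("catalog and profile JSON documents round-trip", {
  catalog <- test_catalog()
  expect_gte(length(catalog), 5)
  ids <- vapply(catalog, `[[`, character(1), "id")
  expect_true(all(c("gardening_light", "arms_raise") %in% ids))

  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "catalog.json")
  write_activity_catalog(catalog, cpath)
  back <- read_activity_catalog(cpath)
  expect_equal(back, catalog)

  prof <- full_tolerance()
  prof$preferences <- c(gardening_light = 0.4)
  prof$free_slots <- data.frame(
    start = as.POSIXct("2026-01-05 10:00:00", tz = "UTC"),
    end = as.POSIXct("2026-01-05 11:00:00", tz = "UTC"))
  ppath <- file.path(dir, "profile.json")
  write_user_profile(prof, ppath)
  pback <- read_user_profile(ppath)
  expect_equal(pback$ability_ratings, prof$ability_ratings)
  expect_equal(pback$preferences, prof$preferences)
  expect_equal(as.numeric(pback$free_slots$start),
               as.numeric(prof$free_slots$start))

  state <- recommender_state()
  state$notifications <- list(list(time = "2026-01-05T10:00:00+0000",
                                   user_id = "user1", reason = "re-weight"))
  lpath <- file.path(dir, "notifications.jsonl")
  write_notification_log(state, lpath)
  lines <- readLines(lpath)
  expect_length(lines, 1)
  expect_equal(jsonlite::fromJSON(lines[1])$reason, "re-weight")
})

test_that("recommender configuration enforces its invariants", {
  expect_error(recommender_config(feature_cap = 0.9, preference_share = 0.2),
               class = "affectsense_invalid")
  expect_error(recommender_config(close_fit_min_score = 0.95),
               class = "affectsense_invalid")
  expect_error(recommender_config(denial_threshold = 0),
               class = "affectsense_invalid")
  cfg <- recommender_config()
  expect_equal(sum(cfg$feature_weights), cfg$feature_cap)
  expect_equal(length(unique(cfg$feature_weights)), 1L)
})
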