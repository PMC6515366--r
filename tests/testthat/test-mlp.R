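# Small labelled feature sets for classifier tests, built from short
# simulated recordings.
small_vectors <- function(classes, n_per_class, seed, duration_s = 4, ...) {
  cfg <- sim_config(duration_s = duration_s, seed = seed, ...)
  ds <- simulate_labeled_dataset(default_emotion_params()[classes],
                                 n_per_class, cfg)
  dataset_features(ds)
}

test_that("the 80/10/10 split sizes and determinism", {
  vecs <- replicate(100, structure(stats::setNames(rnorm(18), paste0("f", 1:18)),
                                   label = "Happy", class = "feature_vector"),
                    simplify = FALSE)
  parts <- split_dataset(vecs, split_spec(seed = 3))
  expect_equal(lengths(parts[c("train", "test", "validation")]),
               c(train = 80L, test = 10L, validation = 10L))
  expect_equal(sort(unlist(parts$indices)), 1:100, ignore_attr = TRUE)

  parts2 <- split_dataset(vecs, split_spec(seed = 3))
  expect_identical(parts$indices, parts2$indices)
  parts3 <- split_dataset(vecs, split_spec(seed = 4))
  expect_false(identical(parts$indices, parts3$indices))

  small <- split_dataset(vecs[1:10], split_spec(seed = 1))
  expect_equal(lengths(small[c("train", "test", "validation")]),
               c(train = 8L, test = 1L, validation = 1L))

  unlabelled <- vecs
  attr(unlabelled[[5]], "label") <- NULL
  expect_error(split_dataset(unlabelled, split_spec()),
               class = "affectsense_invalid")
  expect_error(split_spec(0.8, 0.3, 0.1), class = "affectsense_invalid")
})

test_that("training on a single class collapses onto that class", {
  vecs <- small_vectors("Happy", 14, seed = 41)
  m <- train_model(vecs[1:10], vecs[11:14],
                   model_config(max_epochs = 150, seed = 2))
  expect_lt(min(m$history$val_mse), 0.01)
  est <- predict(m, vecs[[1]])
  expect_equal(est$argmax_label, "Happy")
  expect_gt(est$probabilities[["Happy"]], 0.9)
})

test_that("training history is finite and bounded by the epochs run", {
  vecs <- small_vectors(c("Happy", "Sad"), 10, seed = 42)
  parts <- split_dataset(vecs, split_spec(seed = 1))
  cfg <- model_config(max_epochs = 60, seed = 3)
  m <- train_model(parts$train, parts$validation, cfg)
  h <- m$history
  expect_true(all(is.finite(h$train_mse)))
  expect_true(all(is.finite(h$val_mse)))
  expect_lte(nrow(h), cfg$max_epochs)
  expect_equal(h$epoch, seq_len(nrow(h)))
  # training is deterministic given the seed
  m2 <- train_model(parts$train, parts$validation, cfg)
  expect_identical(m$params, m2$params)
  # train accuracy is at least the majority-class baseline
  tr_eval <- evaluate(m, parts$train)
  labels <- vapply(parts$train, function(v) attr(v, "label"), "")
  expect_gte(tr_eval$accuracy, max(table(labels)) / length(labels))
})

test_that("predictions are valid, deterministic probability vectors", {
  vecs <- small_vectors(c("Happy", "Afraid"), 8, seed = 43)
  m <- train_model(vecs[1:12], vecs[13:16],
                   model_config(max_epochs = 40, seed = 1))
  est <- predict(m, vecs[[1]])
  expect_s3_class(est, "emotion_estimate")
  expect_length(est$probabilities, 7)
  expect_true(all(est$probabilities >= 0))
  expect_lt(abs(sum(est$probabilities) - 1), 1e-6)
  est2 <- predict(m, vecs[[1]])
  expect_identical(est$probabilities, est2$probabilities)

  expect_error(predict(m, rnorm(17)), class = "affectsense_invalid")
  untrained <- structure(list(params = NULL), class = "emotion_mlp")
  expect_error(predict(untrained, rnorm(18)), class = "affectsense_state")
})

test_that("evaluation accuracy, mse and confusion counts are conserved", {
  vecs <- small_vectors(c("Happy", "Sad", "Angry"), 8, seed = 44)
  parts <- split_dataset(vecs, split_spec(seed = 2))
  m <- train_model(parts$train, parts$validation,
                   model_config(max_epochs = 120, seed = 5))
  ev <- evaluate(m, vecs)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(sum(ev$confusion), length(vecs))
  labels <- vapply(vecs, function(v) attr(v, "label"), "")
  expect_equal(rowSums(ev$confusion)[names(table(labels))],
               c(table(labels))[names(table(labels))], ignore_attr = TRUE)
  expect_error(evaluate(m, list()), class = "affectsense_invalid")
})

test_that("an uninformative uniform predictor scores near 1/7 on balanced data", {
  # zero weights make the softmax exactly uniform; on a balanced labelled
  # set the argmax rule then scores the chance level
  vecs <- unlist(lapply(EMOTION_LABELS, function(lb)
    replicate(1000, structure(stats::setNames(rnorm(18), paste0("f", 1:18)),
                              label = lb, class = "feature_vector"),
              simplify = FALSE)), recursive = FALSE)
  sizes <- c(18L, 4L, 7L)
  params <- list(W = list(matrix(0, 18, 4), matrix(0, 4, 7)),
                 b = list(rep(0, 4), rep(0, 7)))
  uniform <- structure(
    list(params = params, config = model_config(hidden_layers = 4L),
         feature_names = paste0("f", 1:18), label_order = EMOTION_LABELS,
         standardize = list(mean = rep(0, 18), sd = rep(1, 18)),
         best_epoch = 0L, history = data.frame()),
    class = "emotion_mlp")
  acc <- evaluate(uniform, vecs)$accuracy
  expect_gte(acc, 0.12)
  expect_lte(acc, 0.17)
})

test_that("motion artifact in the validation set does not raise accuracy", {
  deltas <- numeric(5)
  for (s in 1:5) {
    cfg_clean <- sim_config(duration_s = 4, seed = 100 + s,
                            motion_artifact_level = 0)
    cfg_noisy <- sim_config(duration_s = 4, seed = 100 + s,
                            motion_artifact_level = 0.25)
    train <- dataset_features(
      simulate_labeled_dataset(default_emotion_params(), 8, cfg_clean))
    val_cfg <- cfg_clean
    val_cfg$seed <- cfg_clean$seed + 5000L
    val_clean <- dataset_features(
      simulate_labeled_dataset(default_emotion_params(), 3, val_cfg))
    val_ncfg <- cfg_noisy
    val_ncfg$seed <- val_cfg$seed
    val_noisy <- dataset_features(
      simulate_labeled_dataset(default_emotion_params(), 3, val_ncfg))
    m <- train_model(train, val_clean,
                     model_config(max_epochs = 120, seed = s))
    deltas[s] <- evaluate(m, val_noisy)$accuracy -
      evaluate(m, val_clean)$accuracy
  }
  expect_lte(mean(deltas), 0)
})

test_that("models round-trip through the JSON persistence format", {
  vecs <- small_vectors(c("Neutral", "Surprised"), 8, seed = 45)
  m <- train_model(vecs[1:12], vecs[13:16],
                   model_config(max_epochs = 30, seed = 7))
  path <- file.path(withr::local_tempdir(), "model.json")
  write_emotion_model(m, path)
  back <- read_emotion_model(path)
  for (v in vecs[1:4])
    expect_equal(predict(back, v)$probabilities, predict(m, v)$probabilities,
                 tolerance = 1e-12)
  expect_equal(back$config$hidden_layers, m$config$hidden_layers)
  expect_equal(nrow(back$history), nrow(m$history))
})

test_that("model configuration validates its fields", {
  expect_error(model_config(hidden_layers = integer(0)),
               class = "affectsense_invalid")
  expect_error(model_config(dropout_rate = 1), class = "affectsense_invalid")
  expect_error(model_config(l2_penalty = -0.1), class = "affectsense_invalid")
  vecs <- small_vectors("Happy", 4, seed = 46, duration_s = 2)
  bad <- lapply(vecs, function(v) structure(unclass(v)[1:17], label = "Happy",
                                            class = "feature_vector"))
  expect_error(train_model(bad[1:3], bad[4], model_config()),
               class = "affectsense_invalid")
})
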