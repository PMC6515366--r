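#' Classifier configuration
#'
#' Configuration of the fully connected emotion classifier: 18 inputs, the
#' hidden stack, and 7 softmax outputs. The loss is the mean squared error
#' against one-hot targets (the quantity tracked by the training curves),
#' with cross-entropy available as an option. Training uses mini-batch Adam
#' with dropout and an L2 weight penalty — applied as decoupled weight decay
#' (the AdamW convention), so the penalty regularizes the weights without
#' being rescaled by Adam's adaptive step — and stops early when the
#' validation loss has not improved by more than `early_stop_min_delta` for
#' `patience` epochs.
#'
#' `early_stop_min_delta` defaults to 1e-3; a literal min-delta of 10 (which
#' on an MSE bounded by 1 disables early improvement detection entirely) can
#' be set explicitly for comparison.
#'
#' @param hidden_layers Integer vector of hidden layer widths (default
#'   `c(32, 64, 128, 64, 32)`).
#' @param dropout_rate Dropout probability on hidden activations during
#'   training, in `[0, 1)` (default 0.2).
#' @param l2_penalty Coefficient of the L2 weight penalty (default 0.01).
#' @param early_stop_min_delta Minimum validation-loss improvement counted
#'   as progress (default 1e-3).
#' @param max_epochs Maximum training epochs (default 300).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 32).
#' @param patience Epochs without improvement before stopping (default 20).
#' @param loss `"mse"` (default) or `"cross_entropy"`.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout masks.
#' @return An object of class `model_config`.
#' @export
model_config <- function(hidden_layers = c(32L, 64L, 128L, 64L, 32L),
                         dropout_rate = 0.2, l2_penalty = 0.01,
                         early_stop_min_delta = 1e-3, max_epochs = 300L,
                         learning_rate = 1e-3, batch_size = 32L,
                         patience = 20L, loss = c("mse", "cross_entropy"),
                         seed = 1L) {
  if (!is.numeric(hidden_layers) || length(hidden_layers) < 1L ||
      any(hidden_layers < 1))
    abort_invalid("'hidden_layers' must be a vector of sizes >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort_invalid("'dropout_rate' must be in [0, 1)")
  if (l2_penalty < 0)
    abort_invalid("'l2_penalty' must be non-negative")
  loss <- match.arg(loss)
  structure(
    list(hidden_layers = as.integer(hidden_layers),
         dropout_rate = dropout_rate, l2_penalty = l2_penalty,
         early_stop_monitor = "validation loss",
         early_stop_min_delta = early_stop_min_delta,
         max_epochs = as.integer(max_epochs),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         patience = as.integer(patience), loss = loss,
         seed = as.integer(seed)),
    class = "model_config")
}

#' Dataset split specification
#'
#' The canonical split assigns 80% of recordings to training, 10% to test
#' and 10% to validation, at random. Partition sizes are `round(fraction *
#' n)` for test and validation, with the rounding remainder absorbed into
#' the training partition.
#'
#' @param train_fraction,test_fraction,validation_fraction Fractions summing
#'   to 1 (defaults 0.8 / 0.1 / 0.1).
#' @param seed Integer seed for the random assignment.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, test_fraction = 0.1,
                       validation_fraction = 0.1, seed = 1L) {
  if (abs(train_fraction + test_fraction + validation_fraction - 1) > 1e-9)
    abort_invalid("split fractions must sum to 1")
  if (min(train_fraction, test_fraction, validation_fraction) < 0)
    abort_invalid("split fractions must be non-negative")
  structure(list(train_fraction = train_fraction,
                 test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split labelled feature vectors into train / test / validation
#'
#' @param vectors A list of at least 10 labelled `feature_vector`s.
#' @param spec A [split_spec()].
#' @return A list with elements `train`, `test`, `validation` (disjoint
#'   lists of feature vectors covering the input) and `indices` (the
#'   permutation positions of each partition in the input, for provenance).
#' @examples
#' \dontrun{
#' parts <- split_dataset(vectors, split_spec(seed = 1))
#' lengths(parts[c("train", "test", "validation")])
#' }
#' @export
split_dataset <- function(vectors, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (length(vectors) < 10L)
    abort_invalid("at least 10 vectors are required to split")
  has_label <- vapply(vectors, function(v) !is.null(attr(v, "label")),
                      logical(1))
  if (!all(has_label))
    abort_invalid("all vectors must be labelled")
  n <- length(vectors)
  n_test <- round(spec$test_fraction * n)
  n_val <- round(spec$validation_fraction * n)
  n_train <- n - n_test - n_val
  perm <- with_seed(spec$seed, sample.int(n))
  idx <- list(train = sort(perm[seq_len(n_train)]),
              test = sort(perm[n_train + seq_len(n_test)]),
              validation = sort(perm[n_train + n_test + seq_len(n_val)]))
  list(train = vectors[idx$train], test = vectors[idx$test],
       validation = vectors[idx$validation], indices = idx)
}

# list of feature_vectors -> design matrix + one-hot targets
vectors_to_matrices <- function(vectors, require_labels = TRUE) {
  if (length(vectors) == 0L)
    abort_invalid("empty partition")
  lens <- lengths(vectors)
  if (any(lens != 18L))
    abort_invalid("feature vectors must have length 18")
  X <- do.call(rbind, lapply(vectors, unclass))
  labels <- vapply(vectors, function(v) {
    lb <- attr(v, "label")
    if (is.null(lb)) NA_character_ else lb
  }, character(1))
  if (require_labels && anyNA(labels))
    abort_invalid("all vectors must be labelled")
  Y <- matrix(0, nrow(X), length(EMOTION_LABELS),
              dimnames = list(NULL, EMOTION_LABELS))
  if (!anyNA(labels)) Y[cbind(seq_len(nrow(X)), match(labels, EMOTION_LABELS))] <- 1
  list(X = X, Y = Y, labels = labels)
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(params, X, dropout_rate = 0, training = FALSE) {
  L <- length(params$W)
  acts <- vector("list", L + 1L)
  masks <- vector("list", L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(X), length(params$b[[l]]), byrow = TRUE)
    if (l < L) {
      h <- relu(z)
      if (training && dropout_rate > 0) {
        m <- matrix(stats::rbinom(length(h), 1L, 1 - dropout_rate),
                    nrow(h)) / (1 - dropout_rate)
        h <- h * m
        masks[[l]] <- m
      }
      acts[[l + 1L]] <- h
    } else {
      acts[[l + 1L]] <- softmax_rows(z)
    }
  }
  list(acts = acts, masks = masks)
}

# Gradient of the batch data loss w.r.t. weights and biases. For the MSE
# loss the softmax Jacobian is applied explicitly; for cross-entropy the
# combined gradient at the pre-softmax layer is P - Y. The L2 penalty is
# applied as decoupled weight decay in the update step, not here: coupling
# it into the adaptively rescaled gradient would let the decay direction
# dominate the small per-entry MSE gradient and collapse the network.
mlp_backward <- function(params, fwd, Y, loss) {
  L <- length(params$W)
  P <- fwd$acts[[L + 1L]]
  nb <- nrow(Y)
  if (loss == "mse") {
    dP <- 2 * (P - Y) / (nb * ncol(Y))
    dZ <- P * (dP - rowSums(dP * P))
  } else {
    dZ <- (P - Y) / nb
  }
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$acts[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dH <- dZ %*% t(params$W[[l]])
      if (!is.null(fwd$masks[[l - 1L]])) dH <- dH * fwd$masks[[l - 1L]]
      dZ <- dH * (fwd$acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

batch_loss <- function(params, X, Y, loss) {
  P <- mlp_forward(params, X)$acts[[length(params$W) + 1L]]
  if (loss == "mse") mean((P - Y)^2)
  else -mean(rowSums(Y * log(pmax(P, 1e-12))))
}

#' Train the emotion classifier
#'
#' Fits the fully connected 18-input / 7-output network on the training
#' partition, monitoring the validation loss for early stopping and keeping
#' the weights of the best validation epoch. Deterministic given
#' `config$seed`. Inputs are standardised with training-set statistics
#' (stored in the model and re-applied at prediction time).
#'
#' @param train,validation Non-empty lists of labelled length-18
#'   `feature_vector`s.
#' @param config A [model_config()].
#' @return An object of class `emotion_mlp` with elements `params` (weights),
#'   `config`, `feature_names`, `label_order`, `standardize` (column means
#'   and sds) and `history` (a data frame with one row per epoch run:
#'   `epoch`, `train_mse`, `val_mse`, `val_accuracy`).
#' @export
train_model <- function(train, validation, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  tr <- vectors_to_matrices(train)
  va <- vectors_to_matrices(validation)
  mu <- colMeans(tr$X)
  sdev <- apply(tr$X, 2L, sd)
  sdev[sdev == 0] <- 1
  Xtr <- sweep(sweep(tr$X, 2L, mu), 2L, sdev, "/")
  Xva <- sweep(sweep(va$X, 2L, mu), 2L, sdev, "/")

  sizes <- c(ncol(Xtr), config$hidden_layers, length(EMOTION_LABELS))
  state <- with_seed(config$seed, {
    params <- list(W = vector("list", length(sizes) - 1L),
                   b = vector("list", length(sizes) - 1L))
    for (l in seq_along(params$W)) {
      params$W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                              sizes[l], sizes[l + 1L])
      params$b[[l]] <- rep(0, sizes[l + 1L])
    }
    adam <- list(mW = lapply(params$W, function(w) w * 0),
                 vW = lapply(params$W, function(w) w * 0),
                 mb = lapply(params$b, function(b) b * 0),
                 vb = lapply(params$b, function(b) b * 0))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    best <- list(val = Inf, params = params, epoch = 0L)
    wait <- 0L
    hist <- list(train_mse = numeric(0), val_mse = numeric(0),
                 val_accuracy = numeric(0))
    n <- nrow(Xtr)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        ii <- ord[start:min(start + config$batch_size - 1L, n)]
        fwd <- mlp_forward(params, Xtr[ii, , drop = FALSE],
                           dropout_rate = config$dropout_rate,
                           training = TRUE)
        gr <- mlp_backward(params, fwd, tr$Y[ii, , drop = FALSE],
                           config$loss)
        step <- step + 1L
        corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
        decay <- config$learning_rate * 2 * config$l2_penalty
        for (l in seq_along(params$W)) {
          adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * gr$W[[l]]
          adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * gr$W[[l]]^2
          params$W[[l]] <- params$W[[l]] - config$learning_rate * corr *
            adam$mW[[l]] / (sqrt(adam$vW[[l]]) + eps) - decay * params$W[[l]]
          adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * gr$b[[l]]
          adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * gr$b[[l]]^2
          params$b[[l]] <- params$b[[l]] - config$learning_rate * corr *
            adam$mb[[l]] / (sqrt(adam$vb[[l]]) + eps)
        }
      }
      tr_mse <- mean((mlp_forward(params, Xtr)$acts[[length(params$W) + 1L]] -
                        tr$Y)^2)
      Pva <- mlp_forward(params, Xva)$acts[[length(params$W) + 1L]]
      va_mse <- mean((Pva - va$Y)^2)
      va_acc <- mean(max.col(Pva, ties.method = "first") ==
                       max.col(va$Y, ties.method = "first"))
      hist$train_mse <- c(hist$train_mse, tr_mse)
      hist$val_mse <- c(hist$val_mse, va_mse)
      hist$val_accuracy <- c(hist$val_accuracy, va_acc)
      # early stopping on the monitored validation loss
      va_loss <- if (config$loss == "mse") va_mse else
        batch_loss(params, Xva, va$Y, "cross_entropy")
      if (va_loss < best$val - config$early_stop_min_delta) {
        best <- list(val = va_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    list(params = best$params, hist = hist, best_epoch = best$epoch)
  })
  structure(
    list(params = state$params, config = config,
         feature_names = colnames(tr$X),
         label_order = EMOTION_LABELS,
         standardize = list(mean = mu, sd = sdev),
         best_epoch = state$best_epoch,
         history = data.frame(epoch = seq_along(state$hist$train_mse),
                              train_mse = state$hist$train_mse,
                              val_mse = state$hist$val_mse,
                              val_accuracy = state$hist$val_accuracy)),
    class = "emotion_mlp")
}

#' @export
print.emotion_mlp <- function(x, ...) {
  cat(sprintf(paste0("<emotion_mlp> 18-[%s]-7, %d epochs run, best epoch %d",
                     " (val %s %.4g)\n"),
              paste(x$config$hidden_layers, collapse = "-"),
              nrow(x$history), x$best_epoch, x$config$loss,
              min(x$history$val_mse)))
  invisible(x)
}

# raw-matrix class probabilities (dropout disabled)
predict_probs <- function(model, X) {
  Xs <- sweep(sweep(X, 2L, model$standardize$mean), 2L,
              model$standardize$sd, "/")
  mlp_forward(model$params, Xs)$acts[[length(model$params$W) + 1L]]
}

#' Predict the emotion for one feature vector
#'
#' Inference is deterministic: dropout is disabled and the stored
#' standardisation is applied.
#'
#' @param object A trained `emotion_mlp`.
#' @param vector A length-18 `feature_vector` (or bare numeric vector).
#' @param ... Unused.
#' @return An object of class `emotion_estimate`: `probabilities` (named,
#'   non-negative, summing to 1 over the seven labels) and `argmax_label`.
#' @export
predict.emotion_mlp <- function(object, vector, ...) {
  if (is.null(object$params) || length(object$params$W) == 0L)
    abort_state("model has no trained weights")
  v <- as.numeric(unclass(vector))
  if (length(v) != 18L)
    abort_invalid("feature vector must have length 18")
  p <- drop(predict_probs(object, matrix(v, 1L)))
  names(p) <- object$label_order
  emotion_estimate(p)
}

#' Construct an emotion estimate
#'
#' @param probabilities Named non-negative vector over the seven labels,
#'   summing to 1 (within 1e-6).
#' @return An object of class `emotion_estimate` with `probabilities` and
#'   `argmax_label`.
#' @export
emotion_estimate <- function(probabilities) {
  if (length(probabilities) != 7L || is.null(names(probabilities)) ||
      !setequal(names(probabilities), EMOTION_LABELS))
    abort_invalid("'probabilities' must be named by the seven emotion labels")
  probabilities <- probabilities[EMOTION_LABELS]
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-6)
    abort_invalid("probabilities must be non-negative and sum to 1")
  structure(list(probabilities = probabilities,
                 argmax_label = EMOTION_LABELS[which.max(probabilities)]),
            class = "emotion_estimate")
}

#' @export
print.emotion_estimate <- function(x, ...) {
  cat(sprintf("<emotion_estimate> %s\n", x$argmax_label))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Evaluate the classifier on a labelled partition
#'
#' @param model A trained `emotion_mlp`.
#' @param partition Non-empty list of labelled `feature_vector`s.
#' @return A list: `accuracy` (fraction of correct argmax predictions),
#'   `mse` (mean squared error of the probabilities against one-hot
#'   targets) and `confusion` (7 x 7 matrix, true labels in rows).
#' @export
evaluate <- function(model, partition) {
  stopifnot(inherits(model, "emotion_mlp"))
  mm <- vectors_to_matrices(partition)
  P <- predict_probs(model, mm$X)
  pred <- model$label_order[max.col(P, ties.method = "first")]
  conf <- table(factor(mm$labels, levels = EMOTION_LABELS),
                factor(pred, levels = EMOTION_LABELS))
  list(accuracy = mean(pred == mm$labels),
       mse = mean((P - mm$Y)^2),
       confusion = unclass(conf))
}

#' Persist a trained classifier as JSON
#'
#' The file stores the configuration, feature and label order, the input
#' standardisation and all weights as JSON number arrays;
#' [read_emotion_model()] restores an identical predictor.
#'
#' @param model A trained `emotion_mlp`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_emotion_model <- function(model, path) {
  stopifnot(inherits(model, "emotion_mlp"))
  obj <- list(config = unclass(model$config),
              feature_names = model$feature_names,
              label_order = model$label_order,
              standardize = model$standardize,
              best_epoch = model$best_epoch,
              weights = lapply(model$params$W, function(w)
                list(dim = dim(w), values = as.numeric(w))),
              biases = model$params$b,
              history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_emotion_model
#' @export
read_emotion_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- vector("list", length(x$biases))
  for (l in seq_along(W))
    W[[l]] <- matrix(x$weights$values[[l]], x$weights$dim[[l]][1],
                     x$weights$dim[[l]][2])
  cfg <- x$config
  config <- model_config(hidden_layers = cfg$hidden_layers,
                         dropout_rate = cfg$dropout_rate,
                         l2_penalty = cfg$l2_penalty,
                         early_stop_min_delta = cfg$early_stop_min_delta,
                         max_epochs = cfg$max_epochs,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size,
                         patience = cfg$patience, loss = cfg$loss,
                         seed = cfg$seed)
  structure(
    list(params = list(W = W, b = x$biases),
         config = config,
         feature_names = x$feature_names,
         label_order = x$label_order,
         standardize = list(mean = unlist(x$standardize$mean),
                            sd = unlist(x$standardize$sd)),
         best_epoch = x$best_epoch,
         history = as.data.frame(x$history)),
    class = "emotion_mlp")
}
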