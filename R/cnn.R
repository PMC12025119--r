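# User-facing CNN classifier: configuration, construction, training,
# prediction, data splitting and one-hot encoding.

#' CNN model configuration
#'
#' The classifier is a small convolutional network: three conv stages
#' (8, 16, 32 filters of 3x3, ReLU, L2 weight penalty, batch
#' normalization, 2x2 max-pooling), global average pooling, dropout, and a
#' two-unit dense head with sigmoid activation trained on one-hot labels
#' with element-wise binary cross-entropy (optionally focal loss). Inputs
#' are rescaled from 0..255 to \[0, 1\]. Optimizer, learning rate, batch
#' size, dropout, L2 strength and early-stopping patience are exposed here
#' with documented defaults; spatial input size is configurable (must be a
#' multiple of 8) with 512 x 512 the reference resolution and smaller sizes
#' available for desk-scale runs.
#'
#' @param input_shape Integer triple (H, W, 3); H and W multiples of 8.
#' @param conv_filters Strictly increasing filter counts (default 8,16,32).
#' @param l2_coeff L2 penalty on conv/dense weights (default 1e-4).
#' @param dropout_rate Dropout on the pooled features (default 0.3).
#' @param epochs Training epochs (default 100).
#' @param batch_size Minibatch size (default 16).
#' @param loss "binary_crossentropy" (default) or "focal".
#' @param focal_gamma Focusing exponent for focal loss (default 2).
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping, best weights restored (default 10).
#' @param class_weighting Apply per-class weights N/(2*N_c) (default TRUE).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param head "sigmoid" (default, matching the two-unit sigmoid head) or
#'   "softmax" for comparison.
#' @param rescale Divide input pixels by 255 (default TRUE).
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_shape = c(512L, 512L, 3L),
                         conv_filters = c(8L, 16L, 32L),
                         l2_coeff = 1e-4, dropout_rate = 0.3,
                         epochs = 100L, batch_size = 16L,
                         loss = c("binary_crossentropy", "focal"),
                         focal_gamma = 2, early_stopping_patience = 10L,
                         class_weighting = TRUE, learning_rate = 1e-3,
                         head = c("sigmoid", "softmax"), rescale = TRUE,
                         seed = 42L) {
  loss <- match.arg(loss)
  head <- match.arg(head)
  stopifnot(length(input_shape) == 3, input_shape[3] == 3,
            input_shape[1] %% 8 == 0, input_shape[2] %% 8 == 0,
            length(conv_filters) == 3, all(diff(conv_filters) > 0),
            l2_coeff >= 0, dropout_rate >= 0, dropout_rate < 1,
            epochs >= 1, batch_size >= 1)
  structure(list(input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 l2_coeff = l2_coeff, dropout_rate = dropout_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 focal_gamma = focal_gamma,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 class_weighting = isTRUE(class_weighting),
                 learning_rate = learning_rate, head = head,
                 rescale = isTRUE(rescale), seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained CNN
#'
#' Initializes weights deterministically from `config$seed` (He-normal for
#' conv stages, Glorot for the dense head; batch-norm gamma 1, beta 0).
#'
#' @param config A [model_config()] object.
#' @return An object of class `roh_cnn` (untrained).
#' @export
build_cnn <- function(config = model_config()) {
  set.seed(config$seed)
  cins <- c(3L, config$conv_filters[1:2])
  stages <- lapply(1:3, function(s) {
    fan_in <- 9L * cins[s]
    Fn <- config$conv_filters[s]
    list(W = matrix(stats::rnorm(fan_in * Fn, sd = sqrt(2 / fan_in)),
                    fan_in, Fn),
         b = rep(0, Fn), gamma = rep(1, Fn), beta = rep(0, Fn))
  })
  c3 <- config$conv_filters[3]
  dense <- list(W = matrix(stats::rnorm(c3 * 2, sd = sqrt(2 / (c3 + 2))),
                           c3, 2),
                b = rep(0, 2))
  structure(list(config = config,
                 params = list(stages = stages, dense = dense),
                 bn = lapply(config$conv_filters, function(f) {
                   list(rm = rep(0, f), rv = rep(1, f))
                 }),
                 classes = NULL, history = NULL, trained = FALSE),
            class = "roh_cnn")
}

#' Count trainable weights per layer
#'
#' @param model An `roh_cnn` object.
#' @return Named integer vector: weights + biases per conv stage and for
#'   the dense head (batch-norm scale/shift counted separately).
#' @export
count_parameters <- function(model) {
  st <- vapply(model$params$stages, function(s) length(s$W) + length(s$b),
               numeric(1))
  c(conv1 = st[1], conv2 = st[2], conv3 = st[3],
    bn = sum(vapply(model$params$stages,
                    function(s) length(s$gamma) + length(s$beta),
                    numeric(1))),
    dense = length(model$params$dense$W) + length(model$params$dense$b))
}

#' One-hot encode a two-class label vector
#'
#' @param labels Character/factor vector with exactly two distinct values.
#' @param classes Optional explicit class order; default sorted unique.
#' @return n x 2 indicator matrix with the class names as colnames; rows
#'   sum to 1.
#' @export
encode_onehot <- function(labels, classes = NULL) {
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(classes) != 2) {
    stop_rohcnn("exactly two classes required, got ", length(classes))
  }
  if (!all(labels %in% classes)) stop_rohcnn("label outside class set")
  y <- cbind(as.numeric(labels == classes[1]),
             as.numeric(labels == classes[2]))
  colnames(y) <- classes
  y
}

#' Decode a one-hot matrix back to labels
#'
#' @param y Indicator matrix from [encode_onehot()].
#' @return Character vector of labels.
#' @export
decode_onehot <- function(y) {
  colnames(y)[max.col(y, ties.method = "first")]
}

#' Stratified train/validation/test split
#'
#' Allocates each class proportionally to the three subsets with
#' largest-remainder rounding (remainder ties resolved in train, validation,
#' test order), then assigns shuffled class members. Deterministic given
#' `seed`; the three index sets are disjoint and cover all samples.
#'
#' @param labels Label vector.
#' @param ratios Numeric triple summing to 1 (default 0.7, 0.2, 0.1).
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
stratified_split <- function(labels, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop_rohcnn("ratios must sum to 1")
  set.seed(seed)
  out <- list(train = integer(), validation = integer(), test = integer())
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    ideal <- n * ratios
    base <- floor(ideal)
    rem <- ideal - base
    extra <- n - sum(base)
    if (extra > 0) {
      take <- order(-rem, seq_along(rem))[seq_len(extra)]
      base[take] <- base[take] + 1
    }
    cuts <- cumsum(base)
    out$train <- c(out$train, idx[seq_len(base[1])])
    out$validation <- c(out$validation,
                        idx[seq_len(base[2]) + cuts[1]])
    out$test <- c(out$test, idx[seq_len(base[3]) + cuts[2]])
  }
  lapply(out, sort)
}

#' Per-class training weights
#'
#' `w_c = N / (2 * N_c)` so that `sum_c w_c * N_c = N`.
#'
#' @param y One-hot label matrix.
#' @return Named numeric vector of two class weights.
#' @export
class_weights <- function(y) {
  nc <- colSums(y)
  if (any(nc == 0)) stop_rohcnn("a class has no training samples")
  stats::setNames(nrow(y) / (2 * nc), colnames(y))
}

#' Classification loss on predicted probabilities
#'
#' Element-wise binary cross-entropy or focal loss, averaged over the two
#' output units and the batch, with optional per-sample weights. With
#' `gamma = 0` and unit weights the focal loss reduces exactly to
#' cross-entropy.
#'
#' @param probs n x 2 matrix of predicted probabilities.
#' @param targets n x 2 one-hot matrix.
#' @param loss "binary_crossentropy" or "focal".
#' @param gamma Focal focusing exponent.
#' @param sample_weights Optional per-row weights.
#' @return Scalar mean loss.
#' @export
cnn_loss <- function(probs, targets, loss = "binary_crossentropy",
                     gamma = 2, sample_weights = NULL) {
  loss_values(probs, targets, loss, gamma, sample_weights)
}

#' Train the CNN
#'
#' Minimizes element-wise binary cross-entropy (or focal loss) with Adam,
#' per-class weights `N/(2*N_c)` when class weighting is on, minibatches,
#' and early stopping on the validation loss with best-weight restoration.
#' Fully reproducible for a fixed `config$seed` on one device.
#'
#' @param model An untrained `roh_cnn` from [build_cnn()].
#' @param x_train Pixel array (H, W, 3, N) with values 0..255.
#' @param y_train One-hot label matrix (N x 2) from [encode_onehot()].
#' @param x_val,y_val Validation images and one-hot labels.
#' @param verbose Print per-epoch progress (default FALSE).
#' @return The trained `roh_cnn`, with `history` (per-epoch train/validation
#'   loss and accuracy) and `classes` filled in.
#' @export
train_cnn <- function(model, x_train, y_train, x_val, y_val,
                      verbose = FALSE) {
  cfg <- model$config
  n <- dim(x_train)[4]
  if (is.null(n) || n == 0) stop_rohcnn("empty training set")
  stopifnot(nrow(y_train) == n, dim(x_train)[1] == cfg$input_shape[1],
            dim(x_train)[2] == cfg$input_shape[2])
  model$classes <- colnames(y_train)
  cw <- if (cfg$class_weighting) class_weights(y_train) else c(1, 1)
  wv <- as.numeric(y_train %*% cw)

  set.seed(cfg$seed + 1L)
  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, bn = model$bn, wait = 0L)
  hist <- vector("list", cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_hit <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x_train[, , , bi, drop = FALSE]
      yb <- y_train[bi, , drop = FALSE]
      fw <- nn_forward(model, xb, training = TRUE)
      model <- fw$model
      dlog <- loss_grad_logits(fw$probs, yb, cfg$loss, cfg$focal_gamma,
                               wv[bi])
      bw <- nn_backward(model, fw$cache, dlog, training = TRUE)
      upd <- adam_step(model$params, bw$grads, opt, cfg$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss_values(fw$probs, yb, cfg$loss,
                                       cfg$focal_gamma, wv[bi]) * length(bi)
      ep_hit <- ep_hit + sum(max.col(fw$probs, "first") ==
                               max.col(yb, "first"))
    }
    vp <- predict_proba(model, x_val)
    val_loss <- loss_values(vp, y_val, cfg$loss, cfg$focal_gamma)
    val_acc <- mean(max.col(vp, "first") == max.col(y_val, "first"))
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n,
                             accuracy = ep_hit / n, val_loss = val_loss,
                             val_accuracy = val_acc)
    if (verbose) {
      message(sprintf("epoch %d loss %.4f acc %.3f val_loss %.4f val_acc %.3f",
                      ep, ep_loss / n, ep_hit / n, val_loss, val_acc))
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = model$params, bn = model$bn,
                   wait = 0L)
    } else {
      best$wait <- best$wait + 1L
      if (best$wait >= cfg$early_stopping_patience) break
    }
  }
  model$params <- best$params
  model$bn <- best$bn
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$trained <- TRUE
  model
}

#' Predict class probabilities
#'
#' Inference-mode forward pass (batch-norm running statistics, no dropout),
#' in chunks to bound memory.
#'
#' @param model An `roh_cnn`.
#' @param x Pixel array (H, W, 3, N).
#' @return N x 2 matrix of probabilities (each unit's sigmoid output
#'   in \[0, 1\]).
#' @export
predict_proba <- function(model, x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[1] == model$config$input_shape[1],
            dim(x)[2] == model$config$input_shape[2])
  n <- dim(x)[4]
  out <- matrix(0, n, 2)
  colnames(out) <- model$classes
  for (start in seq(1, n, by = model$config$batch_size)) {
    bi <- start:min(start + model$config$batch_size - 1L, n)
    out[bi, ] <- nn_forward(model, x[, , , bi, drop = FALSE],
                            training = FALSE, keep_cache = FALSE)$probs
  }
  out
}

#' Predict class labels
#'
#' Argmax over the two output probabilities; exact ties go to the first
#' (sorted) class.
#'
#' @param model A trained `roh_cnn`.
#' @param x Pixel array (H, W, 3, N) or a probability matrix.
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(model, x) {
  if (!isTRUE(model$trained)) stop_rohcnn("model is not trained")
  probs <- if (is.matrix(x)) x else predict_proba(model, x)
  cls <- model$classes %||% colnames(probs)
  cls[max.col(probs, ties.method = "first")]
}
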