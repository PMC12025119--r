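test_that("stratified split allocates 70:20:10 per class", {
  labels <- c(rep("A", 100), rep("B", 50))
  sp <- stratified_split(labels, seed = 3)
  counts <- sapply(sp, function(idx) table(factor(labels[idx], c("A", "B"))))
  expect_equal(unname(counts["A", ]), c(70, 20, 10))
  expect_equal(unname(counts["B", ]), c(35, 10, 5))
  expect_identical(stratified_split(labels, seed = 3), sp)
  expect_error(stratified_split(labels, ratios = c(0.5, 0.5, 0.5)), "sum")
})

test_that("splits partition the samples for arbitrary label mixes", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(20:120, 1)
    labels <- sample(c("u", "v"), n, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(labels)) < 2) next
    sp <- stratified_split(labels, seed = i)
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(anyDuplicated(all_idx), 0L)
    for (cl in c("u", "v")) {
      n_cl <- sum(labels == cl)
      got <- vapply(sp, function(idx) sum(labels[idx] == cl), numeric(1))
      expect_true(all(abs(got - n_cl * c(0.7, 0.2, 0.1)) <= 1))
    }
  }
})

test_that("one-hot encoding is a sorted-class indicator with round-trip", {
  y <- encode_onehot(c("A", "B", "A"))
  expect_equal(unname(y), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(colnames(y), c("A", "B"))
  expect_true(all(rowSums(y) == 1))
  expect_equal(decode_onehot(y), c("A", "B", "A"))
  expect_error(encode_onehot(c("A", "A")), "two classes")
  expect_error(encode_onehot(c("A", "B", "C")), "two classes")
})

test_that("the first conv stage holds 224 trainable weights", {
  m <- build_cnn(model_config(input_shape = c(16L, 16L, 3L)))
  expect_equal(unname(count_parameters(m)[["conv1"]]), 8 * (3 * 3 * 3) + 8)
})

test_that("forward output is a probability pair per image", {
  cfg <- tiny_model_config(side = 16L)
  m <- build_cnn(cfg)
  x <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3, 1))
  m$trained <- TRUE; m$classes <- c("a", "b")
  p <- predict_proba(m, x)
  expect_equal(dim(p), c(1L, 2L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("identical seeds give identical initial weights and training", {
  cfg <- tiny_model_config(side = 16L, epochs = 2L, seed = 12L)
  m1 <- build_cnn(cfg); m2 <- build_cnn(cfg)
  expect_identical(m1$params, m2$params)
  fx <- solid_images(6, side = 16L, seed = 2)
  y <- encode_onehot(fx$labels)
  t1 <- train_cnn(m1, fx$images, y, fx$images[, , , 1:4, drop = FALSE],
                  y[1:4, ])
  t2 <- train_cnn(m2, fx$images, y, fx$images[, , , 1:4, drop = FALSE],
                  y[1:4, ])
  expect_identical(t1$params, t2$params)
  expect_identical(t1$history, t2$history)
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(31)
  cfg <- model_config(input_shape = c(8L, 8L, 3L), dropout_rate = 0,
                      l2_coeff = 1e-3, seed = 5L)
  m <- build_cnn(cfg)
  X <- array(runif(8 * 8 * 3 * 3, 0, 255), c(8, 8, 3, 3))
  y <- encode_onehot(c("a", "b", "a"))
  loss_of <- function(m) {
    fw <- rohcnn:::nn_forward(m, X, training = TRUE, keep_cache = FALSE)
    l2 <- cfg$l2_coeff *
      (sum(vapply(m$params$stages, function(s) sum(s$W^2), numeric(1))) +
         sum(m$params$dense$W^2))
    rohcnn:::loss_values(fw$probs, y) + l2
  }
  fw <- rohcnn:::nn_forward(m, X, training = TRUE, keep_cache = TRUE)
  dlog <- rohcnn:::loss_grad_logits(fw$probs, y)
  bw <- rohcnn:::nn_backward(m, fw$cache, dlog, training = TRUE,
                             need_input_grad = TRUE)
  rel_err <- function(a, b) abs(a - b) / pmax(abs(a) + abs(b), 1e-8)

  probes <- list(
    list(get = function() bw$grads$stages[[1]]$W,
         set = function(m, i, e) {
           m$params$stages[[1]]$W[i] <- m$params$stages[[1]]$W[i] + e; m
         }),
    list(get = function() bw$grads$stages[[2]]$gamma,
         set = function(m, i, e) {
           m$params$stages[[2]]$gamma[i] <- m$params$stages[[2]]$gamma[i] + e; m
         }),
    list(get = function() bw$grads$stages[[3]]$W,
         set = function(m, i, e) {
           m$params$stages[[3]]$W[i] <- m$params$stages[[3]]$W[i] + e; m
         }),
    list(get = function() bw$grads$dense$W,
         set = function(m, i, e) {
           m$params$dense$W[i] <- m$params$dense$W[i] + e; m
         }))
  for (pr in probes) {
    g <- pr$get()
    for (i in sample(length(g), 4)) {
      num <- (loss_of(pr$set(m, i, 1e-5)) - loss_of(pr$set(m, i, -1e-5))) /
        2e-5
      expect_lt(rel_err(num, g[i]), 1e-5)
    }
  }
  # gradient with respect to the input pixels (saliency path)
  for (i in sample(length(X), 3)) {
    Xp <- X; Xp[i] <- Xp[i] + 1e-3
    Xm <- X; Xm[i] <- Xm[i] - 1e-3
    fp <- rohcnn:::nn_forward(m, Xp, training = TRUE, keep_cache = FALSE)
    fm <- rohcnn:::nn_forward(m, Xm, training = TRUE, keep_cache = FALSE)
    num <- (rohcnn:::loss_values(fp$probs, y) -
              rohcnn:::loss_values(fm$probs, y)) / 2e-3
    expect_lt(rel_err(num, bw$dinput[i]), 1e-4)
  }
})

test_that("focal loss with gamma 0 and unit weights equals cross-entropy", {
  set.seed(6)
  p <- matrix(runif(40, 0.01, 0.99), 20, 2)
  y <- encode_onehot(sample(c("a", "b"), 20, replace = TRUE))
  expect_equal(cnn_loss(p, y, "focal", gamma = 0),
               cnn_loss(p, y, "binary_crossentropy"), tolerance = 1e-6)
  g1 <- rohcnn:::loss_grad_logits(p, y, "focal", gamma = 0)
  g2 <- rohcnn:::loss_grad_logits(p, y, "binary_crossentropy")
  expect_equal(g1, g2, tolerance = 1e-6)
})

test_that("class weights satisfy sum(w_c * N_c) = N", {
  y <- encode_onehot(c(rep("a", 30), rep("b", 10)))
  w <- class_weights(y)
  expect_equal(sum(w * colSums(y)), nrow(y))
  expect_equal(unname(w), c(40 / 60, 40 / 20))
})

test_that("rescaling by 1/255 equals feeding [0,1] images directly", {
  cfg <- tiny_model_config(side = 16L)
  m <- build_cnn(cfg)
  x255 <- array(runif(16 * 16 * 3 * 2, 0, 255), c(16, 16, 3, 2))
  p1 <- rohcnn:::nn_forward(m, x255, training = FALSE)$probs
  m$config$rescale <- FALSE
  p2 <- rohcnn:::nn_forward(m, x255 / 255, training = FALSE)$probs
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("label decoding follows argmax with first-class tie-break", {
  m <- list(trained = TRUE, classes = c("a", "b"))
  class(m) <- "roh_cnn"
  expect_equal(predict_labels(m, rbind(c(0.9, 0.2))), "a")
  expect_equal(predict_labels(m, rbind(c(0.5, 0.5))), "a")
  set.seed(2)
  probs <- matrix(runif(200), 100, 2)
  got <- predict_labels(m, probs)
  expect_equal(got, c("a", "b")[max.col(probs, "first")])
  expect_error(predict_labels(list(trained = FALSE), probs), "not trained")
})

test_that("a separable two-colour problem is learnt to perfect validation accuracy", {
  fx <- solid_images(10, side = 32L, seed = 44)
  y <- encode_onehot(fx$labels)
  sp <- stratified_split(fx$labels, c(0.6, 0.4, 0), seed = 9)
  cfg <- tiny_model_config(side = 32L, epochs = 30L, seed = 10L)
  m <- train_cnn(build_cnn(cfg), fx$images[, , , sp$train, drop = FALSE],
                 y[sp$train, ], fx$images[, , , sp$validation, drop = FALSE],
                 y[sp$validation, ])
  expect_equal(max(m$history$val_accuracy), 1)
  pred <- predict_labels(m, fx$images[, , , sp$validation, drop = FALSE])
  expect_equal(mean(pred == fx$labels[sp$validation]), 1)
})

test_that("training on permuted labels stays at chance level", {
  set.seed(55)
  accs <- vapply(1:3, function(s) {
    fx <- solid_images(10, side = 16L, seed = s)
    lab <- sample(fx$labels)  # break the image-label link
    y <- encode_onehot(lab)
    sp <- stratified_split(lab, c(0.5, 0.25, 0.25), seed = s)
    cfg <- tiny_model_config(side = 16L, epochs = 8L, seed = s)
    m <- train_cnn(build_cnn(cfg), fx$images[, , , sp$train, drop = FALSE],
                   y[sp$train, ], fx$images[, , , sp$validation, drop = FALSE],
                   y[sp$validation, ])
    pred <- predict_labels(m, fx$images[, , , sp$test, drop = FALSE])
    mean(pred == lab[sp$test])
  }, numeric(1))
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})
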