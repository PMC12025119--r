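test_that("k-fold indices partition the data with balanced strata", {
  labels <- rep(c("a", "b"), c(60, 40))
  folds <- kfold_indices(labels, k = 10, seed = 2)
  expect_length(folds, 10)
  expect_equal(sort(unlist(folds)), seq_along(labels))
  per_class <- sapply(folds, function(f) sum(labels[f] == "a"))
  expect_true(all(per_class == 6))
  expect_true(all(lengths(folds) == 10))

  f2 <- kfold_indices(rep("x", 100), k = 10, seed = 1, stratified = FALSE)
  expect_true(all(lengths(f2) == 10))
  expect_error(kfold_indices(c("a", "b"), k = 5), "exceeds")

  set.seed(12)
  for (i in 1:20) {
    n <- sample(25:80, 1)
    labels <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.6, 0.4))
    k <- sample(3:6, 1)
    folds <- kfold_indices(labels, k, seed = i)
    expect_equal(sort(unlist(folds)), seq_len(n))
    for (cl in c("a", "b")) {
      cnt <- vapply(folds, function(f) sum(labels[f] == cl), numeric(1))
      expect_lte(diff(range(cnt)), 1)
    }
  }
})

test_that("upsampling balances classes without leaving the input set", {
  labels <- rep(c("maj", "min"), c(30, 10))
  idx <- seq_along(labels)
  up <- upsample_balance(idx, labels, seed = 5)
  expect_equal(sum(labels[up] == "maj"), 30)
  expect_equal(sum(labels[up] == "min"), 30)
  expect_true(all(up %in% idx))

  balanced <- upsample_balance(1:20, rep(c("a", "b"), 10), seed = 1)
  expect_equal(sort(balanced), 1:20)
  expect_error(upsample_balance(1:5, rep("a", 5)), "both classes")

  # restricted to a subset: augmented indices never escape it
  sub <- c(1:5, 31:40)
  up2 <- upsample_balance(sub, labels, seed = 2)
  expect_true(all(up2 %in% sub))
})

test_that("rank-statistic AUC matches exhaustive pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6),
                       c("pos", "pos", "neg", "pos"), "pos"), 2 / 3)
  expect_equal(roc_auc(c(5, 4, 3, 2), c("p", "p", "n", "n"), "p"), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("p", "n"), 5), "p"), 0.5)
  set.seed(3)
  for (i in 1:10) {
    sc <- round(runif(20), 1)  # force some ties
    lab <- sample(c("p", "n"), 20, replace = TRUE)
    if (length(unique(lab)) < 2) next
    pos <- which(lab == "p"); neg <- which(lab == "n")
    pairs <- outer(sc[pos], sc[neg], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(sc, lab, "p"), mean(pairs))
    skip_if_not_installed("pROC")
    expect_equal(roc_auc(sc, lab, "p"),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("n", "p"),
                                                direction = "<", quiet = TRUE))))
  }
})

test_that("PCA scores match the full-SVD oracle", {
  set.seed(17)
  x <- matrix(rnorm(10 * 50), 10, 50)
  sc <- pca_project(x, 9)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  # reconstruction from all components reproduces the centred matrix
  expect_equal(sc %*% t(attr(sc, "rotation")), xc, tolerance = 1e-8)
  # scores match the SVD scores up to column signs
  for (j in 1:9) {
    expect_equal(min(sum((sc[, j] - sv$u[, j] * sv$d[j])^2),
                     sum((sc[, j] + sv$u[, j] * sv$d[j])^2)), 0,
                 tolerance = 1e-12)
  }
  # orthonormal loadings, diagonal score covariance
  rot <- attr(sc, "rotation")
  expect_equal(crossprod(rot), diag(9), tolerance = 1e-8)
  cv <- crossprod(sc) / (nrow(x) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)

  # rank-1 input has exactly one nonzero singular value
  r1 <- outer(rnorm(8), rnorm(30))
  sc1 <- pca_project(r1, 5)
  vars <- apply(sc1, 2, stats::var)
  expect_gt(vars[1], 1e-6)
  expect_lt(max(vars[-1]), 1e-10)
  expect_error(pca_project(x, 10), "n_components")
})

test_that("held-out projection uses the training centre and rotation", {
  set.seed(23)
  xtr <- matrix(rnorm(12 * 40), 12, 40)
  fit <- pca_project(xtr, 5)
  xnew <- matrix(rnorm(3 * 40), 3, 40)
  proj <- pca_apply(xnew, fit)
  manual <- sweep(xnew, 2, colMeans(xtr)) %*% attr(fit, "rotation")
  expect_equal(proj, manual)
})

test_that("the PCA+logistic baseline separates a separable image set", {
  fx <- solid_images(15, side = 16L, seed = 70)
  res <- logistic_baseline_cv(fx$images, fx$labels, k = 5,
                              n_components = 5, seed = 3)
  expect_length(res$fold_auc, 5)
  expect_equal(res$mean_auc, 1)
})

test_that("no validation-fold information leaks into the baseline fit", {
  set.seed(41)
  n <- 40
  x <- matrix(rnorm(n * 30), n, 30)
  labels <- rep(c("a", "b"), each = n / 2)
  folds <- kfold_indices(labels, k = 4, seed = 6)
  val <- folds[[1]]
  tr <- setdiff(seq_len(n), val)

  fit_params <- function(xx, lab) {
    fit <- pca_project(xx[tr, , drop = FALSE], 5)
    up <- upsample_balance(tr, lab, seed = 9)
    sc <- fit[match(up, tr), , drop = FALSE]
    gl <- glmnet::glmnet(sc, factor(lab[up]), family = "binomial",
                         alpha = 0, lambda = 1e-2, standardize = FALSE)
    list(center = attr(fit, "center"), rot = attr(fit, "rotation"),
         beta = as.numeric(gl$beta), a0 = gl$a0)
  }
  lab2 <- labels
  lab2[val] <- sample(labels[val])      # corrupt validation labels
  x2 <- x
  x2[val, ] <- x2[val, ] + rnorm(length(val) * 30, sd = 5)  # corrupt pixels
  p1 <- fit_params(x, labels)
  p2 <- fit_params(x2, lab2)
  expect_identical(p1, p2)
})

test_that("CNN cross-validation returns per-fold metrics on shared folds", {
  fx <- solid_images(16, side = 16L, seed = 81)
  cfg <- tiny_model_config(side = 16L, epochs = 10L, seed = 2L)
  res <- cv_cnn(fx$images, fx$labels, cfg, k = 4, seed = 7)
  expect_length(res$fold_metrics, 4)
  expect_equal(sort(unlist(res$folds)), seq_len(32))
  accs <- vapply(res$fold_metrics, `[[`, numeric(1), "accuracy")
  expect_true(all(accs == 1))  # separable fixture
  expect_true(all(c("mean", "sd") %in% rownames(res$aggregate)))

  base <- logistic_baseline_cv(fx$images, fx$labels, k = 4, seed = 7,
                               n_components = 5)
  expect_identical(base$folds, res$folds)
})

test_that("corrupting a validation fold does not change CNN training", {
  fx <- solid_images(8, side = 16L, seed = 91)
  labels <- fx$labels
  folds <- kfold_indices(labels, k = 4, seed = 5)
  val <- folds[[1]]
  tr_all <- setdiff(seq_along(labels), val)
  inner <- stratified_split(labels[tr_all], c(0.875, 0.125, 0), seed = 6)
  tr <- tr_all[inner$train]; es <- tr_all[inner$validation]
  cfg <- tiny_model_config(side = 16L, epochs = 3L, seed = 8L)
  y <- encode_onehot(labels)

  train_on <- function(images) {
    train_cnn(build_cnn(cfg), images[, , , tr, drop = FALSE], y[tr, ],
              images[, , , es, drop = FALSE], y[es, ])$params
  }
  corrupted <- fx$images
  corrupted[, , , val] <- 255 - corrupted[, , , val]
  expect_identical(train_on(fx$images), train_on(corrupted))
})
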