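# Stratified k-fold cross-validation of the CNN and the PCA + logistic
# regression baseline with minority upsampling and rank-based ROC-AUC.

#' Stratified k-fold validation indices
#'
#' Shuffles each class and deals members round-robin into k folds, so
#' per-class counts across folds differ by at most one. The folds
#' partition the full index set.
#'
#' @param labels Label vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param stratified Stratify by class (default TRUE).
#' @return List of k disjoint integer index vectors (validation sets).
#' @export
kfold_indices <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (k > n) stop_rohcnn("k exceeds the number of samples")
  set.seed(seed)
  folds <- vector("list", k)
  groups <- if (stratified) split(seq_len(n), as.character(labels)) else list(seq_len(n))
  for (g in groups) {
    g <- g[sample.int(length(g))]
    f <- rep(seq_len(k), length.out = length(g))
    for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], g[f == j])
  }
  lapply(folds, sort)
}

#' Balance classes by upsampling the minority with replacement
#'
#' Applied to training indices only; every returned index exists in the
#' input, so no information can leak in from outside the given set.
#'
#' @param indices Integer index vector (training portion).
#' @param labels Label vector for the full dataset.
#' @param seed Integer seed.
#' @return Augmented index multiset with equal class counts.
#' @export
upsample_balance <- function(indices, labels, seed = 1L) {
  lab <- as.character(labels[indices])
  tab <- table(lab)
  if (length(tab) < 2) stop_rohcnn("both classes must be present")
  set.seed(seed)
  target <- max(tab)
  out <- indices
  for (cl in names(tab)) {
    need <- target - tab[[cl]]
    if (need > 0) {
      pool <- indices[lab == cl]
      out <- c(out, sample(pool, need, replace = TRUE))
    }
  }
  out
}

#' ROC-AUC by the Mann-Whitney rank statistic
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted 1/2.
#'
#' @param scores Numeric vector of predicted scores for the positive class.
#' @param labels Label vector.
#' @param positive_class The positive class label.
#' @return Scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive_class) {
  pos <- labels == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_rohcnn("need both classes for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Project flattened images onto principal components
#'
#' Columns of the returned score matrix are projections of the
#' column-centred data onto its top right singular vectors (exact economy
#' SVD; for p >> n computed through the eigendecomposition of the n x n
#' Gram matrix). Components are orthonormal in feature space and scores
#' have diagonal covariance.
#'
#' @param x n x p numeric matrix (rows = flattened images).
#' @param n_components Number of components c <= min(n - 1, p).
#' @return n x c score matrix with attributes `center` (column means) and
#'   `rotation` (p x c orthonormal loadings) so held-out data can be
#'   projected with [pca_apply()].
#' @export
pca_project <- function(x, n_components) {
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop_rohcnn("need at least 2 rows")
  if (n_components > min(n - 1, p)) {
    stop_rohcnn("n_components exceeds min(n-1, p)")
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  if (p > n) {
    G <- tcrossprod(xc)            # n x n
    eg <- eigen(G, symmetric = TRUE)
    keep <- seq_len(n_components)
    d <- sqrt(pmax(eg$values[keep], 0))
    u <- eg$vectors[, keep, drop = FALSE]
    ok <- d > 1e-12
    v <- matrix(0, p, n_components)
    v[, ok] <- crossprod(xc, u[, ok, drop = FALSE]) /
      rep(d[ok], each = p)
  } else {
    sv <- svd(xc, nu = 0, nv = n_components)
    v <- sv$v
    d <- sv$d[seq_len(n_components)]
  }
  scores <- xc %*% v
  attr(scores, "center") <- ctr
  attr(scores, "rotation") <- v
  scores
}

#' Project new data with a fitted PCA
#'
#' @param x New n x p matrix.
#' @param fit Score matrix returned by [pca_project()] (carries the
#'   centering and rotation).
#' @return Score matrix for `x`.
#' @export
pca_apply <- function(x, fit) {
  sweep(x, 2, attr(fit, "center")) %*% attr(fit, "rotation")
}

#' PCA + logistic-regression baseline under k-fold cross-validation
#'
#' Per fold: images are flattened to vectors; centering and PCA are fitted
#' on the training portion only; the training portion is upsampled to class
#' balance; a ridge-regularized logistic model (glmnet, alpha = 0) is fitted
#' on the scores; the held-out fold is projected with the training PCA and
#' scored. Performance is rank-based ROC-AUC per fold.
#'
#' @param images Pixel array (H, W, 3, N) or an N x p matrix of already
#'   flattened images.
#' @param labels Label vector (two classes).
#' @param k Folds (default 10).
#' @param n_components PCA components (default 50, capped at n_train - 1).
#' @param seed Integer seed (fold assignment shared with [cv_cnn()]).
#' @param lambda Ridge penalty (default 1e-2).
#' @param folds Optional explicit fold list from [kfold_indices()].
#' @return List with `fold_auc` (numeric k-vector), `mean_auc`, `sd_auc`,
#'   `positive_class`, and `folds`.
#' @export
logistic_baseline_cv <- function(images, labels, k = 10L, n_components = 50L,
                                 seed = 1L, lambda = 1e-2, folds = NULL) {
  x <- if (is.matrix(images)) images else
    t(matrix(images, prod(dim(images)[1:3]), dim(images)[4]))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_rohcnn("two classes required")
  positive <- classes[2]
  if (is.null(folds)) folds <- kfold_indices(labels, k, seed)
  seeds <- derive_seeds(seed, paste0("fold", seq_along(folds)))
  fold_auc <- vapply(seq_along(folds), function(j) {
    val <- folds[[j]]
    tr <- setdiff(seq_len(nrow(x)), val)
    nc <- min(n_components, length(tr) - 1L)
    fit <- pca_project(x[tr, , drop = FALSE], nc)
    tr_up <- upsample_balance(tr, labels, seed = seeds[j])
    # rows of the upsampled training set, in fitted-score space
    sc_tr <- fit[match(tr_up, tr), , drop = FALSE]
    gl <- glmnet::glmnet(sc_tr, factor(labels[tr_up], levels = classes),
                         family = "binomial", alpha = 0, lambda = lambda,
                         standardize = FALSE)
    sc_val <- pca_apply(x[val, , drop = FALSE], fit)
    pr <- as.numeric(stats::predict(gl, sc_val, type = "response"))
    roc_auc(pr, labels[val], positive)
  }, numeric(1))
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
       sd_auc = stats::sd(fold_auc), positive_class = positive,
       folds = folds)
}

#' k-fold cross-validation of the CNN
#'
#' A fresh model is built per fold and trained on the remaining folds
#' (an internal stratified slice of the training portion serves as the
#' early-stopping validation set); metrics are computed on the held-out
#' fold. Fold assignments are identical to the baseline's for the same
#' seed, enabling paired comparison.
#'
#' @param images Pixel array (H, W, 3, N).
#' @param labels Label vector (two classes).
#' @param config [model_config()] used for every fold.
#' @param k Folds (default 10).
#' @param seed Fold-assignment seed (default 1).
#' @param folds Optional explicit fold list.
#' @return List of class `cv_result`: `fold_metrics` (list of
#'   `metrics_report`), `histories`, `aggregate` (mean and sd per metric),
#'   `folds`.
#' @export
cv_cnn <- function(images, labels, config = model_config(), k = 10L,
                   seed = 1L, folds = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  y <- encode_onehot(labels, classes)
  if (is.null(folds)) folds <- kfold_indices(labels, k, seed)
  fold_metrics <- vector("list", length(folds))
  histories <- vector("list", length(folds))
  for (j in seq_along(folds)) {
    val <- folds[[j]]
    tr_all <- setdiff(seq_len(length(labels)), val)
    # internal early-stopping split: 1/8 of the training portion
    inner <- stratified_split(labels[tr_all], c(0.875, 0.125, 0),
                              seed = seed + j)
    tr <- tr_all[inner$train]
    es <- tr_all[inner$validation]
    cfg <- config
    cfg$seed <- config$seed + j
    mdl <- build_cnn(cfg)
    mdl <- train_cnn(mdl, images[, , , tr, drop = FALSE],
                     y[tr, , drop = FALSE],
                     images[, , , es, drop = FALSE], y[es, , drop = FALSE])
    pred <- predict_labels(mdl, images[, , , val, drop = FALSE])
    cm <- confusion_matrix(pred, labels[val], classes)
    fold_metrics[[j]] <- classification_metrics(cm)
    histories[[j]] <- mdl$history
  }
  agg <- sapply(c("accuracy", "sensitivity", "specificity", "ppv", "npv"),
                function(m) {
                  v <- vapply(fold_metrics, function(r) r[[m]], numeric(1))
                  c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
                })
  structure(list(fold_metrics = fold_metrics, histories = histories,
                 aggregate = agg, folds = folds),
            class = "cv_result")
}
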