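# Internal neural-network machinery for the ROH-map classifier.
#
# Convolutions use the im2col formulation so the inner loop is a BLAS
# matrix product. Activations travel as matrices with rows ordered
# (image b outer, column-major spatial index inner) and one column per
# channel; pooling reshapes to (H, W, C, B) arrays. The gradient of a
# same-padded 3x3 convolution with respect to its input is itself a
# same-padded 3x3 convolution with the spatially flipped, channel-
# transposed kernels, so backward reuses im2col too. All of this is
# verified against finite-difference gradients in the test suite.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

.im2col_cache <- new.env(parent = emptyenv())

# Gather index matrix (H*W x 9*C) into a zero-padded (H+2, W+2, C) volume.
# Column order: channel outer, then dx, then dy.
im2col_index <- function(H, W, C) {
  key <- paste(H, W, C, sep = "_")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  H2 <- H + 2L; W2 <- W + 2L
  ys <- rep(seq_len(H), W)
  xs <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * C)
  j <- 0L
  for (c in seq_len(C)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        j <- j + 1L
        idx[, j] <- (ys + dy) + (xs + dx - 1L) * H2 +
          (c - 1L) * H2 * W2
      }
    }
  }
  .im2col_cache[[key]] <- idx
  idx
}

# A: (H, W, C, B) array -> (B*H*W) x (9*C) patch matrix.
im2col <- function(A) {
  d <- dim(A); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  H2 <- H + 2L; W2 <- W + 2L
  Ap <- array(0, c(H2, W2, C, B))
  Ap[2:(H + 1L), 2:(W + 1L), , ] <- A
  apv <- as.vector(Ap)
  idx <- im2col_index(H, W, C)
  HW <- H * W
  X <- matrix(0, B * HW, 9L * C)
  per_img <- H2 * W2 * C
  for (b in seq_len(B)) {
    X[(b - 1L) * HW + seq_len(HW), ] <- apv[idx + (b - 1L) * per_img]
  }
  X
}

# (B*H*W) x C matrix <-> (H, W, C, B) array.
mat_to_arr <- function(Z, H, W, B) {
  C <- ncol(Z)
  HW <- H * W
  A <- array(0, c(H, W, C, B))
  for (b in seq_len(B)) {
    A[, , , b] <- array(Z[(b - 1L) * HW + seq_len(HW), ], c(H, W, C))
  }
  A
}

arr_to_mat <- function(A) {
  d <- dim(A); HW <- d[1] * d[2]
  Z <- matrix(0, HW * d[4], d[3])
  for (b in seq_len(d[4])) {
    Z[(b - 1L) * HW + seq_len(HW), ] <- matrix(A[, , , b], HW, d[3])
  }
  Z
}

# Flip the 3x3 kernels spatially and swap in/out channels:
# Wm is (9*Cin) x F; result is (9*F) x Cin.
rot_weights <- function(Wm, Cin, Fn) {
  Wrot <- matrix(0, 9L * Fn, Cin)
  for (c in seq_len(Cin)) {
    for (f in seq_len(Fn)) {
      Wrot[(f - 1L) * 9L + (1:9), c] <- rev(Wm[(c - 1L) * 9L + (1:9), f])
    }
  }
  Wrot
}

bcast <- function(v, n) rep(v, each = n)

bn_forward <- function(Z, gamma, beta, stats, training) {
  n <- nrow(Z)
  if (training) {
    mu <- colMeans(Z)
    xc <- Z - bcast(mu, n)
    v <- colMeans(xc * xc)
    sd <- sqrt(v + BN_EPS)
    xhat <- xc / bcast(sd, n)
    stats$rm <- BN_MOMENTUM * stats$rm + (1 - BN_MOMENTUM) * mu
    stats$rv <- BN_MOMENTUM * stats$rv + (1 - BN_MOMENTUM) * v
    list(out = xhat * bcast(gamma, n) + bcast(beta, n),
         cache = list(xhat = xhat, sd = sd), stats = stats)
  } else {
    sd <- sqrt(stats$rv + BN_EPS)
    xhat <- (Z - bcast(stats$rm, n)) / bcast(sd, n)
    list(out = xhat * bcast(gamma, n) + bcast(beta, n),
         cache = list(xhat = xhat, sd = sd), stats = stats)
  }
}

bn_backward <- function(dout, gamma, cache, training) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * bcast(gamma, n)
  if (training) {
    dZ <- (dxhat - bcast(colMeans(dxhat), n) -
             cache$xhat * bcast(colMeans(dxhat * cache$xhat), n)) /
      bcast(cache$sd, n)
  } else {
    dZ <- dxhat / bcast(cache$sd, n)
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(A) {
  d <- dim(A)
  if (d[1] %% 2L || d[2] %% 2L) stop_rohcnn("pooling needs even spatial dims")
  o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
  p1 <- seq(1L, d[2], 2L); p2 <- seq(2L, d[2], 2L)
  A11 <- A[o1, p1, , , drop = FALSE]; A21 <- A[o2, p1, , , drop = FALSE]
  A12 <- A[o1, p2, , , drop = FALSE]; A22 <- A[o2, p2, , , drop = FALSE]
  P <- array(pmax(A11, A21, A12, A22), dim(A11))
  M11 <- A11 == P
  M21 <- (A21 == P) & !M11
  M12 <- (A12 == P) & !M11 & !M21
  M22 <- !M11 & !M21 & !M12
  list(out = P, masks = list(M11, M21, M12, M22), in_dim = d)
}

maxpool_backward <- function(dP, cache) {
  d <- cache$in_dim
  o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
  p1 <- seq(1L, d[2], 2L); p2 <- seq(2L, d[2], 2L)
  dA <- array(0, d)
  dA[o1, p1, , ] <- dP * cache$masks[[1]]
  dA[o2, p1, , ] <- dA[o2, p1, , , drop = FALSE] + dP * cache$masks[[2]]
  dA[o1, p2, , ] <- dA[o1, p2, , , drop = FALSE] + dP * cache$masks[[3]]
  dA[o2, p2, , ] <- dA[o2, p2, , , drop = FALSE] + dP * cache$masks[[4]]
  dA
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Full forward pass. X: (H, W, 3, B) pixel array. Returns probabilities,
# logits and (when keep_cache) everything backward needs.
nn_forward <- function(model, X, training = FALSE, keep_cache = training,
                       drop_mask = NULL) {
  cfg <- model$config
  B <- dim(X)[4]
  A <- if (cfg$rescale) X / 255 else X
  caches <- vector("list", 3L)
  for (s in 1:3) {
    d <- dim(A)
    Xc <- im2col(A)
    st <- model$params$stages[[s]]
    Z <- Xc %*% st$W
    Z <- Z + bcast(st$b, nrow(Z))
    relu_mask <- Z > 0
    Zr <- Z * relu_mask
    bn <- bn_forward(Zr, st$gamma, st$beta, model$bn[[s]], training)
    if (training) model$bn[[s]] <- bn$stats
    Aarr <- mat_to_arr(bn$out, d[1], d[2], B)
    pool <- maxpool_forward(Aarr)
    if (keep_cache) {
      caches[[s]] <- list(Xc = Xc, relu_mask = relu_mask, bn = bn$cache,
                          pool = pool, H = d[1], W = d[2], Cin = d[3])
    }
    A <- pool$out
  }
  d3 <- dim(A)
  G <- t(matrix(colMeans(matrix(A, d3[1] * d3[2], d3[3] * B)), d3[3], B))
  if (training && cfg$dropout_rate > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(
        stats::rbinom(length(G), 1L, 1 - cfg$dropout_rate) /
          (1 - cfg$dropout_rate), nrow(G), ncol(G))
    }
    Gd <- G * drop_mask
  } else {
    drop_mask <- NULL
    Gd <- G
  }
  logits <- Gd %*% model$params$dense$W
  logits <- logits + bcast(model$params$dense$b, B)
  probs <- if (cfg$head == "softmax") {
    e <- exp(logits - apply(logits, 1, max))
    e / rowSums(e)
  } else {
    sigmoid(logits)
  }
  list(probs = probs, logits = logits, model = model,
       cache = if (keep_cache) {
         list(stages = caches, G = G, Gd = Gd, drop_mask = drop_mask,
              gap_dim = d3, B = B)
       })
}

# Backward pass from dlogits. Returns parameter gradients (same shape as
# model$params) and, when need_input_grad, the gradient w.r.t. the raw
# input pixels.
nn_backward <- function(model, cache, dlogits, training = TRUE,
                        need_input_grad = FALSE) {
  cfg <- model$config
  B <- cache$B
  l2 <- cfg$l2_coeff
  dWd <- t(cache$Gd) %*% dlogits + 2 * l2 * model$params$dense$W
  dbd <- colSums(dlogits)
  dGd <- dlogits %*% t(model$params$dense$W)
  dG <- if (!is.null(cache$drop_mask)) dGd * cache$drop_mask else dGd
  d3 <- cache$gap_dim
  HW3 <- d3[1] * d3[2]
  dA <- array(rep(as.vector(t(dG)) / HW3, each = HW3), c(d3[1], d3[2], d3[3], B))
  grads <- list(stages = vector("list", 3L),
                dense = list(W = dWd, b = dbd))
  dinput <- NULL
  for (s in 3:1) {
    cc <- cache$stages[[s]]
    st <- model$params$stages[[s]]
    dP <- maxpool_backward(dA, cc$pool)
    dBNout <- arr_to_mat(dP)
    bb <- bn_backward(dBNout, st$gamma, cc$bn, training)
    dZ <- bb$dZ * cc$relu_mask
    grads$stages[[s]] <- list(W = t(cc$Xc) %*% dZ + 2 * l2 * st$W,
                              b = colSums(dZ),
                              gamma = bb$dgamma, beta = bb$dbeta)
    if (s > 1 || need_input_grad) {
      Fn <- ncol(st$W)
      dZarr <- mat_to_arr(dZ, cc$H, cc$W, B)
      Wrot <- rot_weights(st$W, cc$Cin, Fn)
      dAmat <- im2col(dZarr) %*% Wrot
      dA <- mat_to_arr(dAmat, cc$H, cc$W, B)
      if (s == 1 && need_input_grad) {
        dinput <- if (cfg$rescale) dA / 255 else dA
      }
    }
  }
  list(grads = grads, dinput = dinput)
}

# Element-wise classification loss on sigmoid/softmax outputs.
# targets: one-hot matrix; sample_weights: per-row weights (default 1).
loss_values <- function(probs, targets, loss = "binary_crossentropy",
                        gamma = 2, sample_weights = NULL) {
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  if (loss == "binary_crossentropy") {
    el <- -(targets * log(p) + (1 - targets) * log(1 - p))
  } else if (loss == "focal") {
    q <- targets * p + (1 - targets) * (1 - p)
    el <- -(1 - q)^gamma * log(q)
  } else stop_rohcnn("unknown loss: ", loss)
  per_sample <- rowMeans(el)
  if (!is.null(sample_weights)) per_sample <- per_sample * sample_weights
  mean(per_sample)
}

# Gradient of the mean loss with respect to the logits (sigmoid head).
loss_grad_logits <- function(probs, targets, loss = "binary_crossentropy",
                             gamma = 2, sample_weights = NULL) {
  B <- nrow(probs); K <- ncol(probs)
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  if (loss == "binary_crossentropy") {
    g <- probs - targets
  } else {
    q <- targets * p + (1 - targets) * (1 - p)
    s <- 2 * targets - 1
    g <- s * (gamma * q * (1 - q)^gamma * log(q) - (1 - q)^(gamma + 1))
  }
  if (!is.null(sample_weights)) g <- g * sample_weights
  g / (B * K)
}

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps), m = m2, v = v2)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
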