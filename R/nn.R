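## Minimal convolutional-network engine used by the defect classifier.
## Convolutions are expressed as im2col gathers followed by BLAS matrix
## multiplies; backpropagation is written out by hand. Sample layouts:
## a batch is a matrix (N, C*H*W) with flat column index
## i + (j-1)*H + (c-1)*H*W  (i along x, fastest; channel-major blocks).

## Gather-index matrix for a valid (no padding, stride 1) KxK convolution:
## IDX[o, m] is the flat input column feeding output position o through
## kernel tap m, with o = oi + (oj-1)*Ho and m = ki + (kj-1)*K + (c-1)*K^2.
im2col_index <- function(C, H, W, K) {
  Ho <- H - K + 1L; Wo <- W - K + 1L
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, Ho * Wo, C * K * K)
  m <- 0L
  for (c in seq_len(C)) for (kj in seq_len(K)) for (ki in seq_len(K)) {
    m <- m + 1L
    idx[, m] <- (oi + ki - 1L) + (oj + kj - 2L) * H + (c - 1L) * H * W
  }
  idx
}

## Forward pass through one conv+ReLU layer.
## X: (N, C*H*W); returns pre-activation Z and activated output laid out
## as the next layer's input matrix (N, F*Ho*Wo).
conv_forward <- function(X, W, b, idx) {
  N <- nrow(X); P <- nrow(idx); M <- ncol(idx)
  G <- X[, as.vector(idx), drop = FALSE]      # (N, P*M), m-major blocks
  dim(G) <- c(N * P, M)                       # row = n + (o-1)*N
  Z <- G %*% W                                # (N*P, F)
  Z <- sweep(Z, 2L, b, "+")
  A <- Z * (Z > 0)
  F <- ncol(W)
  out <- A
  dim(out) <- c(N, P * F)                     # col = o + (f-1)*P
  list(out = out, Z = Z, G = G)
}

## Backward through conv+ReLU. d_out: (N, P*F) gradient w.r.t. layer
## output. Returns gradients and (optionally) d_input.
conv_backward <- function(d_out, cache, W, idx, N, need_dx = TRUE, in_cols = NULL) {
  P <- nrow(idx); M <- ncol(idx); F <- ncol(W)
  dA <- d_out
  dim(dA) <- c(N * P, F)
  dZ <- dA * (cache$Z > 0)
  dW <- crossprod(cache$G, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (need_dx) {
    dG <- tcrossprod(dZ, W)                   # (N*P, M)
    dX <- matrix(0, N, in_cols)
    for (m in seq_len(M)) {
      cols <- idx[, m]
      dX[, cols] <- dX[, cols] + matrix(dG[, m], N, P)
    }
  }
  list(dW = dW, db = db, dX = dX)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## Mean cross-entropy of predicted probabilities against integer class
## indices. A perfect one-hot prediction contributes 0; a uniform 3-class
## prediction contributes log(3).
cross_entropy <- function(prob, y_idx) {
  p <- prob[cbind(seq_along(y_idx), y_idx)]
  -mean(log(pmax(p, 1e-300)))
}

glorot_normal <- function(nin, nout, fan_in, fan_out) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (fan_in + fan_out))), nin, nout)
}

## Architecture constructor: two 3x3 valid convolutions with `features`
## maps each (9 -> 7 -> 5, no pooling), a fully connected ReLU layer, and
## a 3-class softmax output. Biases start at zero, weights Glorot normal.
nn_init <- function(side = 9L, channels = 2L, features = 32L, fc = 100L,
                    classes = 3L, K = 3L) {
  H1 <- side; H2 <- side - K + 1L; H3 <- H2 - K + 1L
  flat <- features * H3 * H3
  list(
    W1 = glorot_normal(channels * K^2, features,
                       channels * K^2, features * K^2),
    b1 = numeric(features),
    W2 = glorot_normal(features * K^2, features,
                       features * K^2, features * K^2),
    b2 = numeric(features),
    W3 = glorot_normal(flat, fc, flat, fc),
    b3 = numeric(fc),
    W4 = glorot_normal(fc, classes, fc, classes),
    b4 = numeric(classes),
    idx1 = im2col_index(channels, H1, H1, K),
    idx2 = im2col_index(features, H2, H2, K),
    dims = list(side = side, channels = channels, features = features,
                fc = fc, classes = classes, K = K,
                in_cols = channels * H1 * H1, mid_cols = features * H2 * H2,
                flat = flat)
  )
}

## Full forward pass. drop_mask: NULL for inference (dropout disabled) or
## an inverted-dropout mask for the FC hidden layer during training.
nn_forward <- function(par, X, drop_mask = NULL) {
  c1 <- conv_forward(X, par$W1, par$b1, par$idx1)
  c2 <- conv_forward(c1$out, par$W2, par$b2, par$idx2)
  Z3 <- sweep(c2$out %*% par$W3, 2L, par$b3, "+")
  A3 <- Z3 * (Z3 > 0)
  if (!is.null(drop_mask)) A3 <- A3 * drop_mask
  Z4 <- sweep(A3 %*% par$W4, 2L, par$b4, "+")
  list(prob = softmax_rows(Z4), c1 = c1, c2 = c2, Z3 = Z3, A3 = A3)
}

## Backward pass for mean cross-entropy; returns parameter gradients.
nn_backward <- function(par, fw, X, y_idx, drop_mask = NULL) {
  N <- nrow(X)
  dZ4 <- fw$prob
  dZ4[cbind(seq_len(N), y_idx)] <- dZ4[cbind(seq_len(N), y_idx)] - 1
  dZ4 <- dZ4 / N
  gW4 <- crossprod(fw$A3, dZ4)
  gb4 <- colSums(dZ4)
  dA3 <- tcrossprod(dZ4, par$W4)
  if (!is.null(drop_mask)) dA3 <- dA3 * drop_mask
  dZ3 <- dA3 * (fw$Z3 > 0)
  gW3 <- crossprod(fw$c2$out, dZ3)
  gb3 <- colSums(dZ3)
  d2 <- tcrossprod(dZ3, par$W3)               # (N, flat)
  g2 <- conv_backward(d2, fw$c2, par$W2, par$idx2, N,
                      need_dx = TRUE, in_cols = par$dims$mid_cols)
  g1 <- conv_backward(g2$dX, fw$c1, par$W1, par$idx1, N, need_dx = FALSE)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

nn_sgd_step <- function(par, grads, lr) {
  for (nm in names(grads)) par[[nm]] <- par[[nm]] - lr * grads[[nm]]
  par
}
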