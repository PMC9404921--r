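# Internal neural-network engine.
#
# Activations are 3-D arrays with dim (L, C, n): time position (fastest), channel,
# batch sample. Convolutions are realized as one BLAS matrix product per layer
# via an im2col gather; gradients are exact analytic backprop, verified against
# finite differences in the test suite.

# x: (L, C, n); W: (k*C) x F; b: length F. Valid convolution, lowered to one
# GEMM through the compiled im2col gather.
conv1d_forward <- function(x, W, b, k) {
  d <- dim(x); L <- d[1]; C <- d[2]; n <- d[3]
  L_out <- L - k + 1L
  M <- im2col_cpp(x, L, C, n, k)
  Y <- M %*% W
  out <- gemm_to_act_cpp(Y, b, L_out, ncol(W), n)
  dim(out) <- c(L_out, ncol(W), n)
  list(out = out, cache = list(M = M, in_dim = d, k = k))
}

conv1d_backward <- function(dout, W, cache) {
  d <- dim(dout)
  dY <- act_to_gemm_cpp(dout, d[1], d[2], d[3])
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  dx <- col2im_cpp(dM, cache$in_dim[1], cache$in_dim[2], cache$in_dim[3], cache$k)
  dim(dx) <- cache$in_dim
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_backward <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

# Non-overlapping max pooling along the time axis; truncates the remainder.
maxpool_forward <- function(x, p) {
  d <- dim(x)
  r <- maxpool_fwd_cpp(x, d[1], d[2], d[3], p)
  out <- r$out
  dim(out) <- c(d[1] %/% p, d[2], d[3])
  list(out = out, cache = list(arg = r$arg, p = p, in_dim = d))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- maxpool_bwd_cpp(dout, cache$arg, d[1], d[2], d[3], cache$p)
  dim(dx) <- d
  dx
}

# Inverted dropout; draws the mask from the ambient RNG stream.
dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, mask) {
  if (is.null(mask)) return(dout)
  dout * mask
}

# (L, F, n) -> n x (L*F) matrix, one flattened row per batch sample.
flatten_forward <- function(x) {
  d <- dim(x)
  list(out = t(matrix(x, nrow = d[1] * d[2], ncol = d[3])), cache = d)
}

flatten_backward <- function(dout, in_dim) {
  array(t(dout), in_dim)
}

# Dense layer on row-matrix input: h (n x d_in) %*% W (d_in x d_out) + b.
dense_forward <- function(h, W, b) {
  Y <- h %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(out = Y, cache = h)
}

dense_backward <- function(dout, W, h) {
  list(dh = tcrossprod(dout, W), dW = crossprod(h, dout), db = colSums(dout))
}

# Glorot-uniform initialization for a fan_in x fan_out weight matrix.
glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(prod(dims), -lim, lim), dims[1], dims[2])
}

# ---------------------------------------------------------------------------
# Adam optimizer over a named list of parameter arrays.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
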