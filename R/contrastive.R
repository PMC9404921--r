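#' Encoder configuration
#'
#' The 1-D CNN encoder `f(.)`: three convolutional blocks, each a single
#' convolution (ReLU) followed by max-pooling and dropout, with filter counts
#' rising 32 -> 64 -> 128 while kernel widths shrink 32 -> 16 -> 8; then a
#' per-time-position dense layer of 80 units with an L2 weight penalty, and a
#' flattening layer. Only this encoder transfers to the downstream classifier.
#'
#' @param input_length Segment length in samples.
#' @param filters Filter counts per block.
#' @param kernels Kernel widths per block (strictly decreasing).
#' @param pool_size Max-pooling width per block.
#' @param dropout_rate Dropout fraction after each pooling layer.
#' @param dense_units Units of the per-position dense layer.
#' @param l2_coeff L2 weight-penalty coefficient on the dense layer.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(input_length,
                           filters = c(32L, 64L, 128L),
                           kernels = c(32L, 16L, 8L),
                           pool_size = 4L,
                           dropout_rate = 0.1,
                           dense_units = 80L,
                           l2_coeff = 3.0) {
  if (length(filters) != length(kernels)) {
    stop("`filters` and `kernels` must have equal length", call. = FALSE)
  }
  if (any(diff(kernels) >= 0)) stop("`kernels` must be strictly decreasing", call. = FALSE)
  if (dense_units <= 0) stop("`dense_units` must be positive", call. = FALSE)
  cfg <- structure(
    list(n_blocks = length(filters), filters = as.integer(filters),
         kernels = as.integer(kernels), pool_size = as.integer(pool_size),
         dropout_rate = dropout_rate, dense_units = as.integer(dense_units),
         l2_coeff = l2_coeff, input_length = as.integer(input_length)),
    class = "encoder_config")
  encoder_shapes(cfg)  # errors early if input is too short for a block
  cfg
}

#' Layer-by-layer shape manifest of an encoder configuration
#'
#' @param cfg An [encoder_config()].
#' @return A list with per-layer weight shapes (`c(kernel, in_channels,
#'   filters)` for convolutions), the time-length after each block, and the
#'   flattened representation width `h_dim`.
#' @export
encoder_shapes <- function(cfg) {
  L <- cfg$input_length
  C <- 1L
  layers <- list()
  for (b in seq_len(cfg$n_blocks)) {
    k <- cfg$kernels[b]
    if (L < k) {
      stop(sprintf("input too short for block %d: length %d < kernel %d", b, L, k),
           call. = FALSE)
    }
    L <- L - k + 1L
    layers[[sprintf("conv%d", b)]] <- c(kernel = k, in_channels = C, filters = cfg$filters[b])
    C <- cfg$filters[b]
    L <- L %/% cfg$pool_size
    if (L < 1L) {
      stop(sprintf("input too short for block %d: pooled length reaches 0", b), call. = FALSE)
    }
  }
  layers[["dense"]] <- c(kernel = 1L, in_channels = C, filters = cfg$dense_units)
  list(layers = layers, final_length = L, h_dim = L * cfg$dense_units)
}

#' Projection head configuration
#'
#' A single fully connected layer with softmax activation mapping the encoder
#' representation `h` to the contrast space `z` used by the NT-Xent loss. A
#' linear head is available behind `activation = "linear"` for ablation.
#'
#' @param units Output dimension (default 256).
#' @param activation `"softmax"` (default) or `"linear"`.
#' @return An object of class `projection_config`.
#' @export
projection_config <- function(units = 256L, activation = c("softmax", "linear")) {
  if (units <= 0) stop("`units` must be positive", call. = FALSE)
  structure(list(units = as.integer(units), activation = match.arg(activation)),
            class = "projection_config")
}

#' Training configuration
#'
#' @param learning_rate Adam step size (> 0). Upstream pretraining uses 1e-4,
#'   downstream fine-tuning 1e-3.
#' @param batch_size Minibatch size; contrastive training needs >= 2.
#' @param epochs Number of passes over the data.
#' @param temperature NT-Xent temperature tau (> 0).
#' @param seed Integer RNG seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L, epochs = 20L,
                         temperature = 0.1, seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (temperature <= 0) stop("`temperature` must be positive", call. = FALSE)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), temperature = temperature,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---------------------------------------------------------------------------

.init_encoder_params <- function(cfg) {
  sh <- encoder_shapes(cfg)
  params <- list()
  for (nm in names(sh$layers)) {
    s <- sh$layers[[nm]]
    fan_in <- s[["kernel"]] * s[["in_channels"]]
    params[[paste0(nm, "_W")]] <- glorot(fan_in, s[["filters"]],
                                         dims = c(fan_in, s[["filters"]]))
    params[[paste0(nm, "_b")]] <- numeric(s[["filters"]])
  }
  params
}

#' Build encoder weights
#'
#' Glorot-uniform weight initialization (zero biases), deterministic given
#' `seed`.
#'
#' @param cfg An [encoder_config()].
#' @param seed Integer seed; `NULL` draws from the ambient RNG stream.
#' @return An object of class `encoder_weights` holding the config, a named
#'   list of parameter arrays, and the shape manifest.
#' @export
build_encoder <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "encoder_config"))
  params <- with_seed(seed, .init_encoder_params(cfg))
  structure(list(config = cfg, params = params, shapes = encoder_shapes(cfg)),
            class = "encoder_weights")
}

# Forward pass through the encoder. x: n x L matrix. Returns h (n x h_dim)
# and, when with_cache, the per-layer caches needed for backprop.
.encoder_fwd <- function(params, cfg, x, train = FALSE, with_cache = FALSE) {
  n <- nrow(x)
  a <- array(t(x), c(ncol(x), 1L, n))
  caches <- list()
  for (b in seq_len(cfg$n_blocks)) {
    nm <- sprintf("conv%d", b)
    cf <- conv1d_forward(a, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]],
                         cfg$kernels[b])
    rf <- relu_forward(cf$out)
    pf <- maxpool_forward(rf$out, cfg$pool_size)
    df <- dropout_forward(pf$out, cfg$dropout_rate, train)
    a <- df$out
    if (with_cache) caches[[nm]] <- list(conv = cf$cache, relu = rf$cache,
                                         pool = pf$cache, drop = df$cache)
  }
  cf <- conv1d_forward(a, params$dense_W, params$dense_b, 1L)
  rf <- relu_forward(cf$out)
  ff <- flatten_forward(rf$out)
  if (with_cache) caches$dense <- list(conv = cf$cache, relu = rf$cache, flat = ff$cache)
  list(h = ff$out, caches = caches)
}

# Backward pass; dh is n x h_dim. Returns named gradients matching params.
.encoder_bwd <- function(params, cfg, caches, dh) {
  grads <- list()
  da <- flatten_backward(dh, caches$dense$flat)
  da <- relu_backward(da, caches$dense$relu)
  cb <- conv1d_backward(da, params$dense_W, caches$dense$conv)
  grads$dense_W <- cb$dW; grads$dense_b <- cb$db
  da <- cb$dx
  for (b in rev(seq_len(cfg$n_blocks))) {
    nm <- sprintf("conv%d", b)
    cc <- caches[[nm]]
    da <- dropout_backward(da, cc$drop)
    da <- maxpool_backward(da, cc$pool)
    da <- relu_backward(da, cc$relu)
    cb <- conv1d_backward(da, params[[paste0(nm, "_W")]], cc$conv)
    grads[[paste0(nm, "_W")]] <- cb$dW; grads[[paste0(nm, "_b")]] <- cb$db
    da <- cb$dx
  }
  grads
}

#' Encoder forward pass
#'
#' @param w An `encoder_weights` object from [build_encoder()] or
#'   [pretrain()].
#' @param segs A [segment_set()] or an n x L numeric matrix whose row length
#'   matches `w$config$input_length`.
#' @param train_mode Activate dropout (stochastic); the default `FALSE` is
#'   deterministic evaluation.
#' @return An n x h_dim matrix of representations `h`.
#' @export
encoder_forward <- function(w, segs, train_mode = FALSE) {
  stopifnot(inherits(w, "encoder_weights"))
  x <- if (inherits(segs, "segment_set")) segs$segments else as.matrix(segs)
  if (ncol(x) != w$config$input_length) {
    stop(sprintf("segment length %d does not match encoder input length %d",
                 ncol(x), w$config$input_length), call. = FALSE)
  }
  .encoder_fwd(w$params, w$config, x, train = train_mode)$h
}

#' Build projection-head weights
#'
#' @param pcfg A [projection_config()].
#' @param h_dim Encoder representation width.
#' @param seed Integer seed; `NULL` draws from the ambient stream.
#' @return An object of class `projection_weights`.
#' @export
build_projection <- function(pcfg, h_dim, seed = 1L) {
  stopifnot(inherits(pcfg, "projection_config"))
  params <- with_seed(seed, list(proj_W = glorot(h_dim, pcfg$units),
                                 proj_b = numeric(pcfg$units)))
  structure(list(config = pcfg, params = params), class = "projection_weights")
}

#' Projection head forward pass
#'
#' Maps representations `h` to contrast-space vectors `z = softmax(W h + b)`
#' (rows sum to 1 and are elementwise positive under the softmax head).
#'
#' @param p A `projection_weights` object.
#' @param h_matrix n x h_dim matrix of representations.
#' @return n x units matrix of projected vectors.
#' @export
projection_forward <- function(p, h_matrix) {
  stopifnot(inherits(p, "projection_weights"))
  u <- dense_forward(as.matrix(h_matrix), p$params$proj_W, p$params$proj_b)$out
  if (p$config$activation == "softmax") softmax_rows(u) else u
}

#' Contrastive batch embedding
#'
#' Wraps a 2N x d matrix of projected vectors with the pairing convention:
#' rows (2k-1, 2k) are the positive pair (`Zx`, `Zx'`) for sample k.
#'
#' @param Z 2N x d numeric matrix with even row count; rows must be finite
#'   and non-zero.
#' @return An object of class `contrastive_batch`.
#' @export
contrastive_batch <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) %% 2L != 0L) stop("row count must be even (2N)", call. = FALSE)
  if (any(!is.finite(Z))) stop("embedding rows must be finite", call. = FALSE)
  if (any(rowSums(Z * Z) == 0)) stop("embedding rows must be non-zero", call. = FALSE)
  structure(list(Z = Z, N = nrow(Z) %/% 2L), class = "contrastive_batch")
}

#' Cosine similarity between two vectors
#'
#' `sim(z1, z2) = (z1 . z2) / (||z1|| ||z2||)`, in \[-1, 1\].
#'
#' @param z1,z2 Non-zero numeric vectors of equal length.
#' @return A scalar similarity.
#' @export
cosine_sim <- function(z1, z2) {
  n1 <- sqrt(sum(z1^2)); n2 <- sqrt(sum(z2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for zero vectors", call. = FALSE)
  sum(z1 * z2) / (n1 * n2)
}

#' NT-Xent contrastive loss
#'
#' Normalized temperature-scaled cross-entropy over a batch of 2N projected
#' vectors. For each anchor, the positive is its paired view and the
#' denominator runs over the 2N - 1 other vectors (the positive plus
#' 2(N - 1) negatives), with cosine similarity scaled by temperature `tau`;
#' the returned value is the mean loss over all 2N anchors. With N = 1 the
#' denominator equals the numerator and the loss is exactly 0.
#'
#' @param batch A [contrastive_batch()] or a 2N x d matrix with pairing rows
#'   (2k-1, 2k).
#' @param tau Temperature (> 0).
#' @param return_grad Also return the gradient of the mean loss with respect
#'   to the embedding matrix `Z`.
#' @return The mean loss (non-negative scalar), or a list `(loss, grad)` when
#'   `return_grad = TRUE`.
#' @export
nt_xent_loss <- function(batch, tau = 0.1, return_grad = FALSE) {
  if (!inherits(batch, "contrastive_batch")) batch <- contrastive_batch(batch)
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  Z <- batch$Z
  n2 <- nrow(Z)
  norms <- sqrt(rowSums(Z * Z))
  Zn <- Z / norms
  S <- tcrossprod(Zn)
  logits <- S / tau
  partner <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)

  losses <- numeric(n2)
  if (return_grad) G <- matrix(0, n2, n2)
  for (a in seq_len(n2)) {
    row <- logits[a, -a]
    lse <- log_sum_exp(row)
    losses[a] <- -logits[a, partner[a]] + lse
    if (return_grad) {
      w <- exp(logits[a, ] - lse)
      w[a] <- 0
      w[partner[a]] <- w[partner[a]] - 1
      G[a, ] <- w / (tau * n2)
    }
  }
  loss <- mean(losses)
  if (!return_grad) return(loss)

  dZn <- (G + t(G)) %*% Zn
  proj <- rowSums(dZn * Zn)
  dZ <- (dZn - Zn * proj) / norms
  list(loss = loss, grad = dZ)
}

#' Contrastive pretraining of the encoder (upstream task)
#'
#' SimCLR-style siamese training: each minibatch row `x` is paired with an
#' altered view `x'` produced by the augmentation spec (fresh random draws
#' every epoch; branch 1 receives `x` unaltered). Both branches share the
#' encoder and projection head, and the NT-Xent loss over the interleaved
#' 2N embeddings is minimized with Adam. Ground-truth labels are never read.
#'
#' @param segs A non-empty [segment_set()] (labels unused).
#' @param spec An [augmentation_spec()].
#' @param ecfg An [encoder_config()]; defaults to the standard architecture at
#'   the segment length of `segs`.
#' @param pcfg A [projection_config()].
#' @param tcfg A [train_config()]; `batch_size` must be >= 2 (otherwise there
#'   are no negatives).
#' @return A list with `weights` (`encoder_weights`, transferable
#'   downstream), `projection` (`projection_weights`), and `loss_history`
#'   (per-epoch mean NT-Xent loss, length `epochs`).
#' @export
pretrain <- function(segs, spec,
                     ecfg = encoder_config(input_length = ncol(segs$segments)),
                     pcfg = projection_config(),
                     tcfg = train_config(learning_rate = 1e-4, batch_size = 32L,
                                         epochs = 20L)) {
  stopifnot(inherits(segs, "segment_set"), inherits(spec, "augmentation_spec"))
  if (nrow(segs$segments) < 2L) stop("need at least 2 segments", call. = FALSE)
  if (tcfg$batch_size < 2L) {
    stop("contrastive training needs `batch_size` >= 2 (no negatives otherwise)",
         call. = FALSE)
  }
  X <- segs$segments
  n <- nrow(X)
  sh <- encoder_shapes(ecfg)

  with_seed(tcfg$seed, {
    params <- c(.init_encoder_params(ecfg),
                build_projection(pcfg, sh$h_dim, seed = NULL)$params)
    opt <- adam_init(params)
    loss_history <- numeric(tcfg$epochs)

    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      ep_losses <- c()
      for (start in seq.int(1L, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(n, start + tcfg$batch_size - 1L)]
        if (length(idx) < 2L) next
        xb <- X[idx, , drop = FALSE]
        xp <- apply_ops_matrix(spec$ops, xb)
        B <- nrow(xb)
        xcat <- matrix(0, 2L * B, ncol(X))
        xcat[seq(1L, 2L * B, 2L), ] <- xb
        xcat[seq(2L, 2L * B, 2L), ] <- xp

        fwd <- .encoder_fwd(params, ecfg, xcat, train = TRUE, with_cache = TRUE)
        u <- dense_forward(fwd$h, params$proj_W, params$proj_b)$out
        z <- if (pcfg$activation == "softmax") softmax_rows(u) else u
        nt <- nt_xent_loss(z, tau = tcfg$temperature, return_grad = TRUE)
        ep_losses <- c(ep_losses, nt$loss)

        du <- if (pcfg$activation == "softmax") {
          z * (nt$grad - rowSums(nt$grad * z))
        } else nt$grad
        pb <- dense_backward(du, params$proj_W, fwd$h)
        grads <- .encoder_bwd(params, ecfg, fwd$caches, pb$dh)
        grads$proj_W <- pb$dW
        grads$proj_b <- pb$db
        grads$dense_W <- grads$dense_W + 2 * ecfg$l2_coeff * params$dense_W

        st <- adam_step(params, grads, opt, lr = tcfg$learning_rate)
        params <- st$params
        opt <- st$state
      }
      loss_history[ep] <- mean(ep_losses)
    }

    enc_names <- as.vector(vapply(names(sh$layers),
                                  function(nm) paste0(nm, c("_W", "_b")),
                                  character(2)))
    list(
      weights = structure(list(config = ecfg, params = params[enc_names],
                               shapes = sh), class = "encoder_weights"),
      projection = structure(list(config = pcfg,
                                  params = params[c("proj_W", "proj_b")]),
                             class = "projection_weights"),
      loss_history = loss_history
    )
  })
}
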