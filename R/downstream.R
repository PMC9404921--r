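#' Build the downstream stress classifier
#'
#' The classifier reuses the encoder architecture verbatim (weight transfer
#' requires identical topology) and adds a freshly initialized fully
#' connected head with `n_classes` units and softmax activation. When `init`
#' is a pretrained `encoder_weights`, the encoder arrays are copied
#' bit-for-bit; the projection head is never transferred.
#'
#' @param ecfg An [encoder_config()].
#' @param n_classes Number of target classes (>= 2).
#' @param init Either `"random"` or an `encoder_weights` object whose shapes
#'   match `ecfg`.
#' @param seed Integer seed for the fresh initializations.
#' @return An object of class `ecg_classifier` with provenance
#'   `"pretrained"` or `"random-init"`.
#' @export
build_classifier <- function(ecfg, n_classes, init = "random", seed = 1L) {
  stopifnot(inherits(ecfg, "encoder_config"))
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  sh <- encoder_shapes(ecfg)

  if (inherits(init, "encoder_weights")) {
    for (fld in c("input_length", "filters", "kernels", "pool_size", "dense_units")) {
      if (!identical(init$config[[fld]], ecfg[[fld]])) {
        stop(sprintf("pretrained encoder disagrees with the configuration on `%s`", fld),
             call. = FALSE)
      }
    }
    ref <- .init_encoder_params(ecfg)  # shape reference only
    for (nm in names(ref)) {
      got <- init$params[[nm]]
      if (is.null(got) || !identical(dim(got) %||% length(got),
                                     dim(ref[[nm]]) %||% length(ref[[nm]]))) {
        stop(sprintf("pretrained weights do not match the configuration at layer '%s'", nm),
             call. = FALSE)
      }
    }
    enc <- structure(list(config = ecfg, params = init$params, shapes = sh),
                     class = "encoder_weights")
    provenance <- "pretrained"
    head <- with_seed(seed, list(head_W = glorot(sh$h_dim, n_classes),
                                 head_b = numeric(n_classes)))
  } else {
    wb <- with_seed(seed, {
      p <- .init_encoder_params(ecfg)
      list(enc = p, head = list(head_W = glorot(sh$h_dim, n_classes),
                                head_b = numeric(n_classes)))
    })
    enc <- structure(list(config = ecfg, params = wb$enc, shapes = sh),
                     class = "encoder_weights")
    head <- wb$head
    provenance <- "random-init"
  }

  structure(list(encoder = enc, head = head, n_classes = as.integer(n_classes),
                 classes = NULL, provenance = provenance),
            class = "ecg_classifier")
}

#' Fine-tune the classifier on labeled segments
#'
#' Minimizes categorical cross-entropy with Adam over minibatches. By default
#' every layer is trainable (fine-tuning); `freeze_encoder = TRUE` gives the
#' linear-evaluation protocol in which only the head is updated.
#'
#' @param model An [build_classifier()] model.
#' @param train A labeled [segment_set()] covering at least two classes.
#' @param tcfg A [train_config()] (downstream defaults: learning rate 1e-3,
#'   batch 128).
#' @param freeze_encoder Update only the classification head.
#' @return A list with the trained `model` (its `$classes` records the label
#'   alphabet, sorted ascending) and `loss_history` of length `epochs`.
#' @export
finetune <- function(model, train,
                     tcfg = train_config(learning_rate = 1e-3, batch_size = 128L,
                                         epochs = 250L),
                     freeze_encoder = FALSE) {
  stopifnot(inherits(model, "ecg_classifier"), inherits(train, "segment_set"))
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L) stop("training labels must cover at least 2 classes", call. = FALSE)
  if (length(classes) > model$n_classes) {
    stop("training set has more classes than the model head", call. = FALSE)
  }
  ecfg <- model$encoder$config
  X <- train$segments
  y <- match(train$labels, classes)
  n <- nrow(X)

  with_seed(tcfg$seed, {
    params <- c(model$encoder$params, model$head)
    opt <- adam_init(params)
    loss_history <- numeric(tcfg$epochs)

    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      ep_losses <- c()
      for (start in seq.int(1L, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(n, start + tcfg$batch_size - 1L)]
        xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        B <- nrow(xb)

        fwd <- .encoder_fwd(params, ecfg, xb, train = TRUE, with_cache = !freeze_encoder)
        logits <- dense_forward(fwd$h, params$head_W, params$head_b)$out
        p <- softmax_rows(logits)
        picked <- p[cbind(seq_len(B), yb)]
        ep_losses <- c(ep_losses, -mean(log(pmax(picked, 1e-12))))

        dlogits <- p
        dlogits[cbind(seq_len(B), yb)] <- dlogits[cbind(seq_len(B), yb)] - 1
        dlogits <- dlogits / B
        hb <- dense_backward(dlogits, params$head_W, fwd$h)
        grads <- list(head_W = hb$dW, head_b = hb$db)
        if (!freeze_encoder) {
          eg <- .encoder_bwd(params, ecfg, fwd$caches, hb$dh)
          eg$dense_W <- eg$dense_W + 2 * ecfg$l2_coeff * params$dense_W
          grads <- c(grads, eg)
        }

        st <- adam_step(params[names(grads)], grads, opt, lr = tcfg$learning_rate)
        params[names(grads)] <- st$params
        opt <- st$state
      }
      loss_history[ep] <- mean(ep_losses)
    }

    model$encoder$params <- params[names(model$encoder$params)]
    model$head <- params[c("head_W", "head_b")]
    model$classes <- classes
    list(model = model, loss_history = loss_history)
  })
}

#' Predict class probabilities and labels for segments
#'
#' Deterministic evaluation-mode forward pass; probability rows sum to 1 and
#' predicted labels are the row argmax with ties broken toward the lowest
#' class index. Results are independent of `batch_size` (used only to bound
#' memory).
#'
#' @param object A fine-tuned `ecg_classifier`.
#' @param segs A [segment_set()] or n x L matrix matching the model input
#'   length.
#' @param batch_size Inference chunk size.
#' @param ... Unused.
#' @return A list with `prob` (n x n_classes matrix) and `labels` (predicted
#'   condition codes).
#' @export
predict.ecg_classifier <- function(object, segs, batch_size = 512L, ...) {
  x <- if (inherits(segs, "segment_set")) segs$segments else as.matrix(segs)
  if (ncol(x) != object$encoder$config$input_length) {
    stop("segment length does not match the model input length", call. = FALSE)
  }
  n <- nrow(x)
  prob <- matrix(0, n, object$n_classes)
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    h <- .encoder_fwd(object$encoder$params, object$encoder$config,
                      x[idx, , drop = FALSE], train = FALSE)$h
    logits <- dense_forward(h, object$head$head_W, object$head$head_b)$out
    prob[idx, ] <- softmax_rows(logits)
  }
  cls <- object$classes %||% (seq_len(object$n_classes) - 1L)
  pred_idx <- max.col(prob, ties.method = "first")
  list(prob = prob, labels = cls[pmin(pred_idx, length(cls))])
}
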