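#' Training configuration
#'
#' Defaults are the published schedule: Adam with learning rate 1e-4,
#' batch size 48, 100 epochs, class-weighted cross-entropy with
#' coefficients 0.25 (LVI-negative) and 0.75 (LVI-positive), random
#' three-axis flip augmentation, and final-model selection at the epoch of
#' least training loss.  `min_val_loss` is offered as an alternative
#' checkpoint rule because train-loss selection invites overfitting; it is
#' never substituted silently.
#'
#' @param loss_weights length-2 positive vector `(w_neg, w_pos)`.
#' @param learning_rate Adam step size.
#' @param batch_size cases per step; clamped to the data set size.
#' @param epochs training epochs.
#' @param seed master seed (initialisation, shuffling, augmentation).
#' @param checkpoint_rule `"min_train_loss"` or `"min_val_loss"`.
#' @param augment apply random flips each epoch.
#' @return Object of class `train_config`.
#' @export
train_config <- function(loss_weights = c(0.25, 0.75), learning_rate = 1e-4,
                         batch_size = 48L, epochs = 100L, seed = 1L,
                         checkpoint_rule = c("min_train_loss", "min_val_loss"),
                         augment = TRUE) {
  stopifnot(length(loss_weights) == 2, all(loss_weights > 0),
            batch_size >= 1, epochs >= 1, learning_rate >= 0)
  structure(list(loss_weights = loss_weights,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint_rule = match.arg(checkpoint_rule),
                 augment = isTRUE(augment)),
            class = "train_config")
}

#' Class-weighted cross-entropy
#'
#' `mean_i( -w_{y_i} log p_i[y_i] )` with probabilities clamped at 1e-12.
#' At equal weights this is the standard cross-entropy scaled by the
#' common weight.
#'
#' @param probs 2 x n matrix of class probabilities (columns sum to 1), or
#'   a length-2 vector for a single case.
#' @param labels 0/1 vector.
#' @param weights length-2 positive vector `(w_neg, w_pos)`.
#' @return Mean loss (scalar).
#' @export
weighted_cross_entropy <- function(probs, labels, weights = c(0.25, 0.75)) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 2)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n <- ncol(probs)
  if (length(labels) != n) stop("label / probability length mismatch")
  idx <- cbind(labels + 1L, seq_len(n))
  p <- pmax(probs[idx], 1e-12)
  mean(-weights[labels + 1L] * log(p))
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gname <- grads[[nm]]
    if (is.null(gname)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gname
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gname^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.flip_batch <- function(images, masks) {
  d <- dim(images)
  for (i in seq_len(d[5])) {
    m <- masks[i, ]
    if (!any(m)) next
    i1 <- if (m[1]) rev(seq_len(d[2])) else seq_len(d[2])
    i2 <- if (m[2]) rev(seq_len(d[3])) else seq_len(d[3])
    i3 <- if (m[3]) rev(seq_len(d[4])) else seq_len(d[4])
    images[, , , , i] <- images[, i1, i2, i3, i]
  }
  images
}

#' Train a network
#'
#' Mini-batch Adam on class-weighted cross-entropy with per-epoch random
#' shuffling and on-the-fly flip augmentation.  Fully deterministic given
#' `cfg$seed`.  Records per-epoch mean training loss (and validation loss
#' if validation data are supplied) and restores, before returning, the
#' parameter snapshot selected by the checkpoint rule.
#'
#' @param model an untrained (or warm) `pcmm_network`.
#' @param data list with `images` (3, s, s, s, n), `priors` (k x n matrix
#'   or NULL for the image-only ablation) and `labels` (0/1).
#' @param cfg a [train_config()].
#' @param validation optional list of the same layout used for
#'   per-epoch validation loss (required for `checkpoint_rule =
#'   "min_val_loss"`).
#' @return List with `model` (at the selected checkpoint) and `history`
#'   (class `train_history`).
#' @export
train_model <- function(model, data, cfg, validation = NULL) {
  n <- length(data$labels)
  if (n < 1) stop("empty training set")
  if (cfg$checkpoint_rule == "min_val_loss" && is.null(validation))
    stop("min_val_loss checkpointing requires validation data")
  bs <- min(cfg$batch_size, n)
  set.seed(cfg$seed)
  adam <- .adam_init(model$params)
  train_loss <- val_loss <- numeric(cfg$epochs)
  best <- list(metric = Inf, params = model$params,
               bn_mean = model$bn_mean, bn_var = model$bn_var, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      nb <- length(idx)
      masks <- if (cfg$augment) matrix(runif(3 * nb) < 0.5, nb, 3)
               else matrix(FALSE, nb, 3)
      xb <- cpp_gather_flip(data$images, idx, masks)
      pb <- if (is.null(data$priors)) NULL
            else data$priors[, idx, drop = FALSE]
      yb <- data$labels[idx]
      fw <- .net_forward(model, xb, pb, training = TRUE, keep_cache = TRUE)
      loss <- weighted_cross_entropy(fw$probs, yb, cfg$loss_weights)
      if (!is.finite(loss))
        stop(sprintf(
          "non-finite loss at epoch %d (lr %.2g, batch mean %.3g, sd %.3g)",
          ep, cfg$learning_rate, mean(xb), sd(xb)))
      losses <- c(losses, loss)
      # update BN running statistics
      mom <- model$bn_momentum
      model$bn_mean <- (1 - mom) * model$bn_mean + mom * fw$cache$bn$mu
      model$bn_var <- (1 - mom) * model$bn_var + mom * fw$cache$bn$va
      if (cfg$learning_rate > 0) {
        onehot <- matrix(0, 2, nb)
        onehot[cbind(yb + 1L, seq_len(nb))] <- 1
        dlogits <- sweep(fw$probs - onehot, 2,
                         cfg$loss_weights[yb + 1L], "*") / nb
        grads <- .net_backward(model, fw$cache, dlogits)
        upd <- .adam_step(model$params, grads, adam, cfg$learning_rate)
        model$params <- upd$params
        adam <- upd$state
      }
    }
    train_loss[ep] <- mean(losses)
    if (!is.null(validation)) {
      fv <- .net_forward(model, validation$images, validation$priors,
                         training = FALSE)
      val_loss[ep] <- weighted_cross_entropy(fv$probs, validation$labels,
                                             cfg$loss_weights)
    }
    metric <- if (cfg$checkpoint_rule == "min_val_loss") val_loss[ep]
              else train_loss[ep]
    if (metric < best$metric) {
      best <- list(metric = metric, params = model$params,
                   bn_mean = model$bn_mean, bn_var = model$bn_var,
                   epoch = ep)
    }
  }
  history <- structure(list(
    train_loss = train_loss,
    val_loss = if (is.null(validation)) NULL else val_loss,
    checkpoint_rule = cfg$checkpoint_rule,
    checkpoint_epoch = best$epoch, epochs = cfg$epochs, seed = cfg$seed
  ), class = "train_history")
  model$params <- best$params
  model$bn_mean <- best$bn_mean
  model$bn_var <- best$bn_var
  list(model = model, history = history)
}

#' Select the checkpoint epoch from a training history
#'
#' Returns the argmin epoch of the rule's loss curve; ties break toward
#' the earlier epoch.
#'
#' @param history a `train_history`.
#' @param rule `"min_train_loss"` (default) or `"min_val_loss"`.
#' @return Integer epoch index.
#' @export
select_checkpoint <- function(history,
                              rule = c("min_train_loss", "min_val_loss")) {
  rule <- match.arg(rule)
  curve <- if (rule == "min_val_loss") history$val_loss else history$train_loss
  if (is.null(curve) || length(curve) == 0) stop("empty history")
  which.min(curve)   # which.min takes the first (earliest) minimum
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("training history: %d epochs, final loss %.4f, checkpoint @ epoch %d (%s)\n",
              x$epochs, x$train_loss[x$epochs], x$checkpoint_epoch,
              x$checkpoint_rule))
  invisible(x)
}

#' @export
plot.train_history <- function(x, ...) {
  plot(seq_along(x$train_loss), x$train_loss, type = "l",
       xlab = "epoch", ylab = "loss", ...)
  if (!is.null(x$val_loss)) {
    lines(seq_along(x$val_loss), x$val_loss, lty = 2)
    legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  abline(v = x$checkpoint_epoch, col = "grey60", lty = 3)
  invisible(x)
}
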