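#' Network architecture configuration
#'
#' Describes the 3D residual channel-attention backbone: a head block
#' (3^3 convolution raising `in_channels` to `head_channels`, channel-wise
#' 3D batch normalisation, ReLU, factor-2 max pooling), `n_rcab` residual
#' channel-attention blocks at constant width, and a tail (global average
#' pooling followed by a 1^3 convolution to `n_classes` logits and
#' softmax).  `in_channels = 19` builds the prior-informed fusion network
#' (three image patches + 16 constant prior planes); `in_channels = 3`
#' builds the image-only ablation.
#'
#' @param in_channels 19 (fusion) or 3 (image-only).
#' @param head_channels feature width after the head convolution.
#' @param n_rcab number of residual channel-attention blocks (>= 1).
#' @param attention_reduction divisor of `head_channels` giving the hidden
#'   width of the attention MLP.
#' @param head_stride stride of the head convolution (1 in the full
#'   architecture; 2 in the desk-scale configuration).
#' @param pool max-pooling factor in the head.
#' @param n_classes number of output classes.
#' @return Object of class `net_config`.
#' @export
net_config <- function(in_channels = 19L, head_channels = 64L, n_rcab = 4L,
                       attention_reduction = 8L, head_stride = 1L,
                       pool = 2L, n_classes = 2L) {
  if (head_channels %% attention_reduction != 0)
    stop("head_channels must be divisible by attention_reduction")
  if (n_rcab < 1) stop("n_rcab must be >= 1")
  if (!in_channels %in% c(3L, 19L) && in_channels < 1)
    stop("invalid in_channels")
  structure(list(in_channels = as.integer(in_channels),
                 head_channels = as.integer(head_channels),
                 n_rcab = as.integer(n_rcab),
                 attention_reduction = as.integer(attention_reduction),
                 head_stride = as.integer(head_stride),
                 pool = as.integer(pool),
                 n_classes = as.integer(n_classes)),
            class = "net_config")
}

.he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

#' Build an untrained network
#'
#' Convolution weights are He-normal, with two exceptions that stabilise
#' training in the small-data regime: the second convolution of each RCAB
#' and the attention MLP output layer start at zero (every residual block
#' is initially an identity map), and the head kernels acting on the
#' constant prior planes start at zero (the fusion network is initially
#' the image-only submodel and recruits the priors through their
#' gradients).  Batch-normalisation keeps running statistics that
#' are frozen at inference.
#'
#' @param cfg a [net_config()].
#' @param seed seed for the weight draw.
#' @return Object of class `pcmm_network`.
#' @export
build_network <- function(cfg, seed = 1L) {
  set.seed(seed)
  C <- cfg$head_channels
  ci <- min(cfg$in_channels, 3L)         # image channels convolved densely
  np <- cfg$in_channels - ci             # constant prior planes
  hid <- C %/% cfg$attention_reduction
  params <- list(
    head_w_img = .he_init(C, 27L * ci, 27L * cfg$in_channels),
    head_w_pri = matrix(0, C, 27L * np),   # priors start silent: the
                 # fusion model begins as the image submodel and recruits
                 # prior planes only where gradients support them
    head_b = numeric(C),
    head_gamma = rep(1, C), head_beta = numeric(C),
    tail_w = .he_init(cfg$n_classes, C, C), tail_b = numeric(cfg$n_classes)
  )
  for (r in seq_len(cfg$n_rcab)) {
    params[[paste0("rcab", r, "_w1")]] <- .he_init(C, 27L * C, 27L * C)
    params[[paste0("rcab", r, "_b1")]] <- numeric(C)
    params[[paste0("rcab", r, "_w2")]] <- matrix(0, C, 27L * C)
    params[[paste0("rcab", r, "_b2")]] <- numeric(C)
    params[[paste0("rcab", r, "_ca_w1")]] <- .he_init(hid, C, C)
    params[[paste0("rcab", r, "_ca_b1")]] <- numeric(hid)
    params[[paste0("rcab", r, "_ca_w2")]] <- matrix(0, C, hid)
    params[[paste0("rcab", r, "_ca_b2")]] <- numeric(C)
  }
  structure(list(cfg = cfg, params = params,
                 bn_mean = numeric(C), bn_var = rep(1, C),
                 bn_momentum = 0.1, bn_eps = 1e-5, seed = seed),
            class = "pcmm_network")
}

#' @export
print.pcmm_network <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("3D residual channel-attention network (%s)\n",
              if (cfg$in_channels > 3) "prior-informed fusion" else "image-only"))
  cat(sprintf("  head: conv3(%d -> %d, stride %d) + BN3d + ReLU + maxpool %d\n",
              cfg$in_channels, cfg$head_channels, cfg$head_stride, cfg$pool))
  cat(sprintf("  body: %d RCAB @ width %d (attention hidden %d)\n",
              cfg$n_rcab, cfg$head_channels,
              cfg$head_channels %/% cfg$attention_reduction))
  cat(sprintf("  tail: GAP + linear %d -> %d + softmax\n",
              cfg$head_channels, cfg$n_classes))
  cat(sprintf("  parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a `pcmm_network`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- functional pieces ------------------------------------------------

.split_input <- function(x) {
  # Accept (C, s, s, s[, n]) tensors; constant prior planes (channels 4+)
  # are collapsed to their scalar values.
  d <- dim(x)
  if (length(d) == 4) { dim(x) <- c(d, 1L); d <- dim(x) }
  C <- d[1]
  if (C <= 3) return(list(images = x, priors = NULL))
  img <- x[1:3, , , , , drop = FALSE]
  pri <- x[4:C, 1, 1, 1, , drop = FALSE]
  dim(pri) <- c(C - 3L, d[5])
  list(images = img, priors = pri)
}

#' Channel attention gate
#'
#' Squeeze-and-excitation style gating: each channel is globally average
#' pooled to a descriptor, passed through a two-layer MLP
#' (ReLU hidden, sigmoid output), and the input is rescaled per channel by
#' the resulting weight in (0, 1).  Spatial shape is unchanged.
#'
#' @param x (C, d, h, w, n) feature map array.
#' @param w1,b1 hidden layer (hid x C matrix, hid vector); `nrow(w1)` must
#'   divide C via the reduction used to build it.
#' @param w2,b2 output layer (C x hid matrix, C vector).
#' @return List with `y` (gated map), `weights` (C x n gate matrix) and
#'   internals used by backward.
#' @export
channel_attention <- function(x, w1, b1, w2, b2) {
  d <- dim(x)
  C <- d[1]; V <- prod(d[2:4]); n <- d[5]
  xm <- matrix(x, C, V * n)
  g <- vapply(seq_len(n), function(i)
    rowMeans(xm[, ((i - 1) * V + 1):(i * V), drop = FALSE]), numeric(C))
  g <- matrix(g, C, n)
  h <- w1 %*% g + b1              # hid x n
  hr <- pmax(h, 0)
  s <- plogis(w2 %*% hr + b2)     # C x n, strictly in (0,1)
  y <- xm
  for (i in seq_len(n))
    y[, ((i - 1) * V + 1):(i * V)] <- y[, ((i - 1) * V + 1):(i * V)] * s[, i]
  dim(y) <- d
  list(y = y, weights = s, g = g, h = h, hr = hr)
}

.channel_attention_bwd <- function(gy, x, ca, w1, w2) {
  d <- dim(x)
  C <- d[1]; V <- prod(d[2:4]); n <- d[5]
  gym <- matrix(gy, C, V * n); xm <- matrix(x, C, V * n)
  gx <- gym
  gs <- matrix(0, C, n)
  for (i in seq_len(n)) {
    cols <- ((i - 1) * V + 1):(i * V)
    gs[, i] <- rowSums(gym[, cols, drop = FALSE] * xm[, cols, drop = FALSE])
    gx[, cols] <- gym[, cols, drop = FALSE] * ca$weights[, i]
  }
  dz2 <- gs * ca$weights * (1 - ca$weights)   # C x n
  gw2 <- dz2 %*% t(ca$hr)
  gb2 <- rowSums(dz2)
  dhr <- t(w2) %*% dz2
  dh <- dhr * (ca$h > 0)
  gw1 <- dh %*% t(ca$g)
  gb1 <- rowSums(dh)
  dg <- t(w1) %*% dh                          # C x n
  for (i in seq_len(n)) {
    cols <- ((i - 1) * V + 1):(i * V)
    gx[, cols] <- gx[, cols, drop = FALSE] + dg[, i] / V
  }
  dim(gx) <- d
  list(gx = gx, gw1 = gw1, gb1 = gb1, gw2 = gw2, gb2 = gb2)
}

#' Forward pass of one residual channel-attention block
#'
#' `y = x + CA(conv2(relu(conv1(x))))`: two 3^3 convolutions with a ReLU
#' between, channel attention on the branch output, and an identity skip.
#'
#' @param x (C, d, h, w, n) feature map.
#' @param params list with `w1`, `b1`, `w2`, `b2`, `ca_w1`, `ca_b1`,
#'   `ca_w2`, `ca_b2` (layout as in [build_network()]).
#' @return Feature map of the same shape.
#' @export
rcab_forward <- function(x, params) {
  a1 <- cpp_conv3d_fwd(x, params$w1, params$b1, 1L, FALSE)$y
  r1 <- array(pmax(a1, 0), dim(a1))
  a2 <- cpp_conv3d_fwd(r1, params$w2, params$b2, 1L, FALSE)$y
  ca <- channel_attention(a2, params$ca_w1, params$ca_b1,
                          params$ca_w2, params$ca_b2)
  x + ca$y
}

.bn_forward <- function(x, gamma, beta, model, training) {
  d <- dim(x); C <- d[1]
  xm <- matrix(x, C)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans((xm - mu)^2)
  } else {
    mu <- model$bn_mean; va <- model$bn_var
  }
  inv <- 1 / sqrt(va + model$bn_eps)
  xhat <- (xm - mu) * inv
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, mu = mu, va = va)
}

.bn_backward <- function(gy, bn, gamma, d) {
  C <- d[1]; m <- prod(d[-1])
  gym <- matrix(gy, C)
  ggamma <- rowSums(gym * bn$xhat)
  gbeta <- rowSums(gym)
  gx <- (gamma * bn$inv) * (gym - gbeta / m - bn$xhat * (ggamma / m))
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# Full forward pass. images: (ci, s, s, s, n); priors: (np x n) or NULL.
.net_forward <- function(model, images, priors, training = FALSE,
                         keep_cache = FALSE) {
  p <- model$params; cfg <- model$cfg
  d <- dim(images)
  if (length(d) == 4) { dim(images) <- c(d, 1L); d <- dim(images) }
  if (is.null(priors) || ncol(p$head_w_pri) == 0) {
    if (cfg$in_channels > 3)
      stop("this network expects ", cfg$in_channels - 3, " prior planes")
    hres <- cpp_conv3d_fwd(images, p$head_w_img, p$head_b, cfg$head_stride,
                           keep_cache)
    conv <- hres$y
  } else {
    if (is.null(dim(priors))) priors <- matrix(priors, ncol = d[5])
    if (nrow(priors) != cfg$in_channels - 3L)
      stop("prior plane count mismatch")
    hres <- cpp_head_fwd(images, priors, p$head_w_img, p$head_w_pri,
                         p$head_b, cfg$head_stride, keep_cache)
    conv <- hres$y
  }
  bn <- .bn_forward(conv, p$head_gamma, p$head_beta, model, training)
  relu <- array(pmax(bn$y, 0), dim(bn$y))
  pool <- cpp_maxpool_fwd(relu, cfg$pool)
  x <- pool$y
  rcabs <- vector("list", cfg$n_rcab)
  for (r in seq_len(cfg$n_rcab)) {
    pr <- .rcab_params(p, r)
    c1 <- cpp_conv3d_fwd(x, pr$w1, pr$b1, 1L, keep_cache)
    a1 <- c1$y
    r1 <- array(pmax(a1, 0), dim(a1))
    c2 <- cpp_conv3d_fwd(r1, pr$w2, pr$b2, 1L, keep_cache)
    a2 <- c2$y
    ca <- channel_attention(a2, pr$ca_w1, pr$ca_b1, pr$ca_w2, pr$ca_b2)
    y <- x + ca$y
    if (keep_cache) rcabs[[r]] <- list(x = x, a1 = a1, r1 = r1, a2 = a2, ca = ca,
                                       c1cache = c1$cache, c2cache = c2$cache)
    x <- y
  }
  dx <- dim(x); C <- dx[1]; V <- prod(dx[2:4]); n <- dx[5]
  xm <- matrix(x, C, V * n)
  z <- vapply(seq_len(n), function(i)
    rowMeans(xm[, ((i - 1) * V + 1):(i * V), drop = FALSE]), numeric(C))
  z <- matrix(z, C, n)
  logits <- p$tail_w %*% z + p$tail_b       # n_classes x n
  lmax <- apply(logits, 2, max)
  el <- exp(sweep(logits, 2, lmax))
  probs <- sweep(el, 2, colSums(el), "/")
  out <- list(probs = probs, logits = logits)
  if (keep_cache)
    out$cache <- list(images = images, priors = priors, conv = conv, bn = bn,
                      relu_mask = bn$y > 0, pool = pool, rcabs = rcabs,
                      head_cache = hres$cache, body_out = x, z = z,
                      body_dim = dx)
  out
}

.rcab_params <- function(p, r) {
  list(w1 = p[[paste0("rcab", r, "_w1")]], b1 = p[[paste0("rcab", r, "_b1")]],
       w2 = p[[paste0("rcab", r, "_w2")]], b2 = p[[paste0("rcab", r, "_b2")]],
       ca_w1 = p[[paste0("rcab", r, "_ca_w1")]],
       ca_b1 = p[[paste0("rcab", r, "_ca_b1")]],
       ca_w2 = p[[paste0("rcab", r, "_ca_w2")]],
       ca_b2 = p[[paste0("rcab", r, "_ca_b2")]])
}

# Backward pass from dlogits (n_classes x n); returns grads named like params.
.net_backward <- function(model, cache, dlogits) {
  p <- model$params; cfg <- model$cfg
  g <- list()
  g$tail_w <- dlogits %*% t(cache$z)
  g$tail_b <- rowSums(dlogits)
  dz <- t(p$tail_w) %*% dlogits                  # C x n
  dx <- cache$body_dim; C <- dx[1]; V <- prod(dx[2:4]); n <- dx[5]
  gb <- matrix(0, C, V * n)
  for (i in seq_len(n))
    gb[, ((i - 1) * V + 1):(i * V)] <- dz[, i] / V
  dim(gb) <- dx
  for (r in rev(seq_len(cfg$n_rcab))) {
    cc <- cache$rcabs[[r]]
    pr <- .rcab_params(p, r)
    cab <- .channel_attention_bwd(gb, cc$a2, cc$ca, pr$ca_w1, pr$ca_w2)
    g[[paste0("rcab", r, "_ca_w1")]] <- cab$gw1
    g[[paste0("rcab", r, "_ca_b1")]] <- cab$gb1
    g[[paste0("rcab", r, "_ca_w2")]] <- cab$gw2
    g[[paste0("rcab", r, "_ca_b2")]] <- cab$gb2
    c2 <- cpp_conv3d_bwd(cc$r1, pr$w2, cab$gx, 1L, TRUE, cc$c2cache)
    g[[paste0("rcab", r, "_w2")]] <- c2$gw
    g[[paste0("rcab", r, "_b2")]] <- c2$gb
    dr1 <- c2$gx * (cc$a1 > 0)
    c1 <- cpp_conv3d_bwd(cc$x, pr$w1, dr1, 1L, TRUE, cc$c1cache)
    g[[paste0("rcab", r, "_w1")]] <- c1$gw
    g[[paste0("rcab", r, "_b1")]] <- c1$gb
    gb <- gb + c1$gx                           # skip connection
  }
  gpool <- cpp_maxpool_bwd(gb, cache$pool$idx, dim(cache$conv))
  grelu <- gpool * cache$relu_mask
  bnb <- .bn_backward(grelu, cache$bn, p$head_gamma, dim(cache$conv))
  g$head_gamma <- bnb$ggamma
  g$head_beta <- bnb$gbeta
  if (is.null(cache$priors) || ncol(p$head_w_pri) == 0) {
    cb <- cpp_conv3d_bwd(cache$images, p$head_w_img, bnb$gx,
                         cfg$head_stride, FALSE, cache$head_cache)
    g$head_w_img <- cb$gw
    g$head_w_pri <- matrix(0, nrow(p$head_w_pri), ncol(p$head_w_pri))
    g$head_b <- cb$gb
  } else {
    hb <- cpp_head_bwd(cache$images, cache$priors, bnb$gx,
                       cfg$head_stride, cfg$head_channels,
                       cache$head_cache)
    g$head_w_img <- hb$gw_img
    g$head_w_pri <- hb$gw_pri
    g$head_b <- hb$gb
  }
  g
}

#' Class probabilities for a batch of input tensors
#'
#' Runs the network in inference mode (batch-normalisation uses running
#' statistics), returning one softmax probability pair per case.
#'
#' @param model a `pcmm_network` (trained or not).
#' @param x either a stacked tensor array (C, s, s, s, n) / (C, s, s, s)
#'   in which channels beyond the third are constant prior planes, or a
#'   list with elements `images` (3, s, s, s, n) and `priors` (16 x n).
#' @return n x 2 matrix with columns `p_neg`, `p_pos`; rows sum to 1.
#' @export
predict_proba <- function(model, x) {
  if (is.list(x) && !is.null(x$images)) {
    images <- x$images; priors <- x$priors
    d <- dim(images)
    if (length(d) == 4) dim(images) <- c(d, 1L)
  } else {
    sp <- .split_input(x)
    images <- sp$images; priors <- sp$priors
  }
  if (model$cfg$in_channels !=
      dim(images)[1] + if (is.null(priors)) 0L else nrow(priors))
    stop("input channel count does not match the network")
  fw <- .net_forward(model, images, priors, training = FALSE)
  out <- t(fw$probs)
  colnames(out) <- c("p_neg", "p_pos")
  out
}
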