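# Small fixtures shared across test files; everything is generated in code.

# a cheap cohort spec: small volumes, few cases
tiny_cohort_spec <- function(n = 12, seed = 1, noise_sd = 0.3) {
  cohort_spec(n_cases = n, seed = seed, noise_sd = noise_sd,
              volume_shape = c(36L, 36L, 36L), lesion_radius_range = c(4, 6))
}

# a tiny network configuration usable with 8^3 inputs
tiny_net <- function(in_channels = 19L, seed = 1L) {
  net_config(in_channels = in_channels, head_channels = 4L, n_rcab = 1L,
             attention_reduction = 2L, head_stride = 1L, pool = 2L)
}

# random (images, priors, labels) toy data on an 8^3 grid
tiny_data <- function(n = 8, s = 8L, seed = 1, informative_prior = TRUE) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  images <- array(runif(3 * s^3 * n), c(3L, s, s, s, n))
  priors <- matrix(runif(16 * n), 16L, n)
  if (informative_prior) priors[8, ] <- labels
  list(images = images, priors = priors, labels = labels)
}

# dense reference implementation of the 3^3/pad-1 convolution
naive_conv3d <- function(x, w, b, stride = 1L) {
  d <- dim(x); C <- d[1]; D <- d[2]; H <- d[3]; W <- d[4]; N <- d[5]
  Cout <- nrow(w)
  Do <- (D - 1) %/% stride + 1
  Ho <- (H - 1) %/% stride + 1
  Wo <- (W - 1) %/% stride + 1
  y <- array(0, c(Cout, Do, Ho, Wo, N))
  for (n in seq_len(N)) for (io in 1:Do) for (jo in 1:Ho) for (ko in 1:Wo) {
    for (o in 1:Cout) {
      acc <- b[o]
      for (dk in 0:2) for (dj in 0:2) for (di in 0:2) {
        i <- stride * (io - 1) + di
        j <- stride * (jo - 1) + dj
        k <- stride * (ko - 1) + dk
        if (i >= 1 && i <= D && j >= 1 && j <= H && k >= 1 && k <= W) {
          off <- di + 3 * (dj + 3 * dk)
          for (cc in 1:C) acc <- acc + w[o, cc + C * off] * x[cc, i, j, k, n]
        }
      }
      y[o, io, jo, ko, n] <- acc
    }
  }
  y
}

# exhaustive pairwise AUC (ties counted one half)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
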