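#' Normalise a modality volume to [0, 1]
#'
#' Voxels below zero are set to zero; the volume is then divided by the
#' maximum of the clipped values.  An all-zero (or all-negative) volume is
#' returned as zeros unchanged.  Applied to the whole volume before any
#' cropping, so the patch scale is anchored to the global maximum.
#'
#' @param volume 3D numeric array; all values must be finite.
#' @return Array of the same shape with values in [0, 1].
#' @export
normalize_intensity <- function(volume) {
  if (any(!is.finite(volume))) stop("volume contains non-finite voxels")
  v <- volume
  v[v < 0] <- 0
  mx <- max(v)
  if (mx > 0) v <- v / mx
  v
}

#' Crop a cubic patch centred on the VOI
#'
#' Takes the half-open window `[c - size/2, c + size/2)` along each axis.
#' Voxels falling outside the volume are zero-filled, so the output shape
#' is always `size^3`.
#'
#' @param volume 3D array.
#' @param center integer voxel triple (1-based), must lie inside the volume.
#' @param size cube edge (default 32).
#' @return `size^3` array.
#' @export
crop_voi_patch <- function(volume, center, size = 32L) {
  dims <- dim(volume)
  if (length(dims) != 3) stop("volume must be 3D")
  if (any(center < 1) || any(center > dims)) stop("center outside volume")
  h <- size %/% 2L
  patch <- array(0, c(size, size, size))
  lo <- center - h          # first source index per axis
  src <- lapply(1:3, function(a) {
    idx <- lo[a]:(lo[a] + size - 1L)
    ok <- idx >= 1L & idx <= dims[a]
    list(src = idx[ok], dst = which(ok))
  })
  patch[src[[1]]$dst, src[[2]]$dst, src[[3]]$dst] <-
    volume[src[[1]]$src, src[[2]]$src, src[[3]]$src]
  patch
}

#' Fit a training-set min-max scaler for the prior features
#'
#' Learns per-feature minimum and maximum on the training rows only.  New
#' data are mapped through `(x - min) / (max - min)` and clipped to
#' [0, 1]; a constant feature maps to 0.  This puts the prior planes on
#' the same [0, 1] scale as the image channels.
#'
#' @param train_table training-row feature table.
#' @return Object of class `prior_scaler`.
#' @export
prior_scaler <- function(train_table) {
  if (nrow(train_table) == 0) stop("empty training set")
  mins <- vapply(train_table, min, numeric(1))
  maxs <- vapply(train_table, max, numeric(1))
  structure(list(mins = mins, maxs = maxs, features = names(train_table)),
            class = "prior_scaler")
}

#' @rdname prior_scaler
#' @param object a `prior_scaler`.
#' @param newdata feature table to transform.
#' @param ... unused.
#' @export
predict.prior_scaler <- function(object, newdata, ...) {
  if (!all(object$features %in% names(newdata)))
    stop("newdata lacks features seen at fit time")
  out <- newdata[, object$features, drop = FALSE]
  for (f in object$features) {
    rng <- object$maxs[f] - object$mins[f]
    out[[f]] <- if (rng > 0) (out[[f]] - object$mins[f]) / rng else 0
    out[[f]] <- pmin(pmax(out[[f]], 0), 1)
  }
  out
}

#' Encode scaled prior features as constant image planes
#'
#' Each of the 16 features becomes one spatially constant `size^3` channel
#' whose every voxel equals the (scaled) feature value, in the fixed order
#' of [prior_feature_names()].
#'
#' @param features numeric vector (or single-row data.frame) of scaled
#'   features, all in [0, 1].
#' @param size cube edge.
#' @return Array of shape (n_features, size, size, size).
#' @export
encode_prior_planes <- function(features, size = 32L) {
  v <- as.numeric(features)
  if (any(v < 0 | v > 1))
    stop("feature values outside [0,1]; scale them with prior_scaler() first")
  nf <- length(v)
  array(rep(v, times = size^3), c(nf, size, size, size))
}

#' Stack image patches and prior planes into a network input tensor
#'
#' @param patches the three normalised modality patches: a
#'   (3, s, s, s) array or a list of three `s^3` arrays.
#' @param planes prior planes from [encode_prior_planes()], or `NULL` for
#'   the image-only (MM) ablation.
#' @return (n_channels, s, s, s) array: channels 1-3 are the image patches,
#'   channels 4..(3+k) the prior planes.
#' @export
assemble_input <- function(patches, planes = NULL) {
  if (is.list(patches)) {
    s <- dim(patches[[1]])
    arr <- array(0, c(length(patches), s))
    for (i in seq_along(patches)) {
      if (!identical(dim(patches[[i]]), s)) stop("patch shape mismatch")
      arr[i, , , ] <- patches[[i]]
    }
    patches <- arr
  }
  dp <- dim(patches)
  if (length(dp) != 4) stop("patches must be (n_mod, s, s, s)")
  if (is.null(planes)) return(patches)
  if (!identical(dim(planes)[2:4], dp[2:4])) stop("plane shape mismatch")
  out <- array(0, c(dp[1] + dim(planes)[1], dp[2], dp[3], dp[4]))
  out[seq_len(dp[1]), , , ] <- patches
  out[dp[1] + seq_len(dim(planes)[1]), , , ] <- planes
  out
}

#' Randomly flip a tensor along the three spatial axes
#'
#' Each spatial axis is independently reversed with probability 1/2; the
#' same flip is applied to every channel, so image patches and prior
#' planes stay aligned (constant planes are unchanged by construction).
#' Applying the same mask twice restores the original tensor.
#'
#' @param x (C, s, s, s) array.
#' @param seed optional seed for the flip draw.
#' @param mask optional logical length-3 vector forcing the flips.
#' @return Flipped array with attribute `flip_mask`.
#' @export
random_flip <- function(x, seed = NULL, mask = NULL) {
  if (is.null(mask)) {
    if (!is.null(seed)) set.seed(seed)
    mask <- runif(3) < 0.5
  }
  d <- dim(x)
  i1 <- if (mask[1]) rev(seq_len(d[2])) else seq_len(d[2])
  i2 <- if (mask[2]) rev(seq_len(d[3])) else seq_len(d[3])
  i3 <- if (mask[3]) rev(seq_len(d[4])) else seq_len(d[4])
  out <- x[, i1, i2, i3, drop = FALSE]
  dim(out) <- d
  attr(out, "flip_mask") <- mask
  out
}

#' Stratified train/validation split
#'
#' Randomly partitions cases into training and validation sets preserving
#' the label strata at the requested ratio (default 7:3).  The validation
#' count per stratum follows the allocation rule: `floor_validation`
#' (default) gives each stratum `floor((1 - f) n_s)` validation cases with
#' the remainder to training; `largest_remainder` fixes the total
#' validation size at `round((1 - f) n)` and distributes the leftover by
#' largest fractional remainder.
#'
#' @param labels 0/1 label vector (one per case).
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param seed RNG seed for the random membership.
#' @param allocation allocation rule.
#' @return List with integer index vectors `train` and `validation`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L,
                             allocation = c("floor_validation",
                                            "largest_remainder")) {
  allocation <- match.arg(allocation)
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (length(labels) == 0) stop("empty label stratum")
  strata <- sort(unique(labels))
  ns <- vapply(strata, function(s) sum(labels == s), integer(1))
  if (any(ns == 0)) stop("empty label stratum")
  raw <- (1 - train_fraction) * ns
  nval <- floor(raw)
  if (allocation == "largest_remainder") {
    total <- round((1 - train_fraction) * length(labels))
    left <- total - sum(nval)
    if (left > 0) {
      ord <- order(raw - nval, decreasing = TRUE)
      nval[ord[seq_len(left)]] <- nval[ord[seq_len(left)]] + 1L
    }
  }
  set.seed(seed)
  val <- integer(0)
  for (i in seq_along(strata)) {
    idx <- which(labels == strata[i])
    val <- c(val, sample(idx, nval[i]))
  }
  val <- sort(val)
  list(train = setdiff(seq_along(labels), val), validation = val)
}

#' Assemble a whole data set into network-ready tensors
#'
#' Scales the prior features with a training-set min-max scaler and packs
#' images and scaled priors for the network.  The scaler must be fit on
#' training rows only; pass it when transforming validation data.
#'
#' @param images (3, s, s, s, n) array of normalised patches.
#' @param features raw feature table (n rows).
#' @param scaler optional pre-fit [prior_scaler()]; fit on `features` if
#'   omitted.
#' @return List with `images`, `priors` (16 x n matrix in [0, 1]) and the
#'   `scaler`.
#' @export
prepare_network_inputs <- function(images, features, scaler = NULL) {
  if (is.null(scaler)) scaler <- prior_scaler(features)
  scaled <- predict(scaler, features)
  priors <- t(as.matrix(scaled[, prior_feature_names(), drop = FALSE]))
  list(images = images, priors = priors, scaler = scaler)
}
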