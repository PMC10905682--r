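#' Fit a prior-informed (or image-only) LVI network
#'
#' High-level modelling interface: scales the prior features on the
#' training data, builds the requested architecture, trains it and
#' returns a fitted-model object with the usual methods
#' (`print`, `summary`, `predict`, `plot`).
#'
#' @param images (3, s, s, s, n) array of normalised modality patches.
#' @param features n-row table of the 16 prior clinico-radiological
#'   features (ignored when `net$in_channels == 3`).
#' @param labels 0/1 LVI labels.
#' @param net a [net_config()]; `in_channels = 19` fuses the priors,
#'   `in_channels = 3` is the image-only ablation.
#' @param train a [train_config()].
#' @param validation optional list(images, features, labels) monitored
#'   during training.
#' @return Object of class `pcmm_fit`.
#' @export
pcmm_fit <- function(images, features = NULL, labels,
                     net = net_config(), train = train_config(),
                     validation = NULL) {
  use_priors <- net$in_channels > 3
  scaler <- NULL
  priors <- NULL
  if (use_priors) {
    if (is.null(features)) stop("features required when in_channels > 3")
    prep <- prepare_network_inputs(images, features)
    priors <- prep$priors
    scaler <- prep$scaler
  }
  vdata <- NULL
  if (!is.null(validation)) {
    vp <- NULL
    if (use_priors)
      vp <- t(as.matrix(predict(scaler, validation$features)[,
               prior_feature_names(), drop = FALSE]))
    vdata <- list(images = validation$images, priors = vp,
                  labels = validation$labels)
  }
  model <- build_network(net, seed = train$seed)
  res <- train_model(model, list(images = images, priors = priors,
                                 labels = labels), train, validation = vdata)
  structure(list(model = res$model, history = res$history, scaler = scaler,
                 net = net, train = train, n = length(labels),
                 prevalence = mean(labels), call = match.call()),
            class = "pcmm_fit")
}

#' @export
print.pcmm_fit <- function(x, ...) {
  cat(sprintf("%s fit on %d cases (prevalence %.3f)\n",
              if (x$net$in_channels > 3) "Prior-informed fusion network"
              else "Image-only network", x$n, x$prevalence))
  print(x$model)
  print(x$history)
  invisible(x)
}

#' @export
summary.pcmm_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  loss at checkpoint: %.4f\n",
              object$history$train_loss[object$history$checkpoint_epoch]))
  invisible(object)
}

#' @param object a `pcmm_fit`.
#' @param images new (3, s, s, s, n) patch array.
#' @param features new feature table (fusion networks only).
#' @param type `"prob"` for P(LVI = 1), `"matrix"` for both columns.
#' @param ... unused.
#' @rdname pcmm_fit
#' @export
predict.pcmm_fit <- function(object, images, features = NULL,
                             type = c("prob", "matrix"), ...) {
  type <- match.arg(type)
  priors <- NULL
  if (object$net$in_channels > 3) {
    if (is.null(features)) stop("features required for the fusion network")
    priors <- t(as.matrix(predict(object$scaler, features)[,
                 prior_feature_names(), drop = FALSE]))
  }
  pm <- predict_proba(object$model, list(images = images, priors = priors))
  if (type == "prob") pm[, "p_pos"] else pm
}

#' @export
plot.pcmm_fit <- function(x, ...) {
  plot(x$history, main = "training loss", ...)
  invisible(x)
}
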