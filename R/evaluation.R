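#' ROC curve and AUC
#'
#' AUC is computed by the Mann-Whitney U formulation with ties counted
#' one half (midranks); the curve is evaluated at every unique score
#' threshold with the convention "score >= threshold is called positive".
#' The trapezoidal area under the resulting curve equals the
#' Mann-Whitney value.
#'
#' @param scores numeric risk scores, finite.
#' @param labels 0/1 labels; both classes must be present.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
compute_roc_auc <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("labels must be 0/1 with both classes present")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) / m - (m + 1) / 2) / n
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(th, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(th, function(t) mean(neg < t), numeric(1))
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = m, n_neg = n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, ...) {
  fpr <- 1 - x$specificity; tpr <- x$sensitivity
  o <- order(fpr, tpr)
  if (add) lines(fpr[o], tpr[o], ...)
  else {
    plot(fpr[o], tpr[o], type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "1 - specificity", ylab = "sensitivity", ...)
    abline(0, 1, col = "grey70", lty = 2)
  }
  invisible(x)
}

#' Operating-point metrics at the Youden-optimal threshold
#'
#' Chooses the threshold maximising Youden's J = sensitivity +
#' specificity - 1 (ties resolved toward the lower threshold, i.e. the
#' more sensitive operating point) and reports accuracy, sensitivity,
#' specificity and the confusion matrix there.
#'
#' @param roc a `roc_result` for the same scores/labels.
#' @param scores,labels the scored cases.
#' @param threshold optional fixed threshold overriding the Youden choice
#'   (e.g. 0.5 for a probability output).
#' @return List: `threshold`, `accuracy`, `sensitivity`, `specificity`,
#'   `youden`, `confusion` (2x2 matrix, rows = truth, cols = call).
#' @export
metrics_at_youden <- function(roc, scores, labels, threshold = NULL) {
  if (is.null(threshold)) {
    j <- roc$sensitivity + roc$specificity - 1
    best <- max(j)
    threshold <- min(roc$thresholds[j >= best - 1e-12])
  }
  call <- as.integer(scores >= threshold)
  tp <- sum(call == 1 & labels == 1); fn <- sum(call == 0 & labels == 1)
  tn <- sum(call == 0 & labels == 0); fp <- sum(call == 1 & labels == 0)
  conf <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                 dimnames = list(truth = c("neg", "pos"),
                                 call = c("neg", "pos")))
  list(threshold = threshold,
       accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       youden = tp / (tp + fn) + tn / (tn + fp) - 1,
       confusion = conf)
}

# placement values (structural components) for one score vector
.placements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Variance of a single AUC (DeLong estimator)
#'
#' @param scores,labels the scored cases.
#' @return Estimated variance of the empirical AUC.
#' @export
delong_variance <- function(scores, labels) {
  pl <- .placements(scores, labels)
  var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
}

#' DeLong test for two paired AUCs
#'
#' Nonparametric comparison of correlated ROC areas via the covariance of
#' placement values (structural components); the difference is referred
#' to a two-sided normal distribution.  Identical score vectors give a
#' degenerate zero-variance comparison reported as p = 1.
#'
#' @param scores_a,scores_b scores of the two models on the same cases.
#' @param labels 0/1 labels.
#' @return Object of class `delong_comparison`: `auc_a`, `auc_b`, `diff`,
#'   `var_diff`, `z`, `p_value`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores must be paired on the same cases")
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  degenerate <- vd <= 0
  if (degenerate) {
    z <- if (abs(diff) < 1e-15) 0 else sign(diff) * Inf
    p <- if (abs(diff) < 1e-15) 1 else 0
  } else {
    z <- diff / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, diff = diff,
                 var_diff = max(vd, 0), z = z, p_value = p,
                 degenerate = degenerate),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: %.4f vs %.4f (diff %+.4f), z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$diff, x$z, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Diagnostic-efficiency report across models
#'
#' One row per model with AUC, accuracy, sensitivity and specificity at
#' the Youden threshold, plus the DeLong p-value of each model's AUC
#' against a designated reference model (NA on the reference row).
#'
#' @param scores named list of score vectors, paired on the same cases.
#' @param labels 0/1 labels.
#' @param reference name of the reference model (default: last element).
#' @return data.frame of class `model_report`; ROC curves attached as
#'   attribute `"rocs"` for plotting.
#' @export
compare_models_report <- function(scores, labels,
                                  reference = names(scores)[length(scores)]) {
  if (length(scores) < 2) stop("need at least two models")
  ns <- lengths(scores)
  if (length(unique(ns)) != 1 || ns[1] != length(labels))
    stop("scores must be paired across models and match the labels")
  if (!reference %in% names(scores)) stop("unknown reference model")
  rocs <- lapply(scores, compute_roc_auc, labels = labels)
  rows <- lapply(names(scores), function(nm) {
    mt <- metrics_at_youden(rocs[[nm]], scores[[nm]], labels)
    p <- if (nm == reference) NA_real_
         else delong_test(scores[[nm]], scores[[reference]], labels)$p_value
    data.frame(model = nm, auc = rocs[[nm]]$auc, accuracy = mt$accuracy,
               sensitivity = mt$sensitivity, specificity = mt$specificity,
               p_vs_reference = p)
  })
  out <- do.call(rbind, rows)
  attr(out, "rocs") <- rocs
  attr(out, "reference") <- reference
  class(out) <- c("model_report", "data.frame")
  out
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model comparison (DeLong reference: %s)\n",
              attr(x, "reference")))
  print.data.frame(cbind(x["model"], round(x[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.model_report <- function(x, ...) {
  rocs <- attr(x, "rocs")
  cols <- seq_along(rocs)
  plot(rocs[[1]], col = cols[1], main = "ROC comparison", ...)
  if (length(rocs) > 1)
    for (i in 2:length(rocs)) plot(rocs[[i]], add = TRUE, col = cols[i])
  legend("bottomright",
         sprintf("%s (AUC %.3f)", names(rocs),
                 vapply(rocs, function(r) r$auc, numeric(1))),
         col = cols, lty = 1, bty = "n")
  invisible(x)
}
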