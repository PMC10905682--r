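#' Univariate logistic regression of LVI on one covariate
#'
#' Maximum-likelihood logistic fit of the binary label on a single
#' covariate (multi-level descriptors enter as their ordinal codes, so one
#' odds ratio per variable).  Wald confidence interval and p-value; for a
#' binary covariate the OR equals the 2x2 cross-product ratio.  Complete
#' (or quasi-complete) separation is flagged rather than silently
#' estimated.
#'
#' @param x numeric covariate vector.
#' @param y 0/1 label vector; both classes must be present.
#' @param conf_level Wald CI level.
#' @return One-row data.frame of class `logistic_fit`: `coefficient`,
#'   `se`, `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`, `separation`.
#' @export
fit_univariate_logistic <- function(x, y, conf_level = 0.95) {
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop("labels must be 0/1 with both classes present")
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  beta <- coef(fit)[["x"]]
  se <- sqrt(diag(vcov(fit)))[["x"]]
  sep <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 100
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    coefficient = beta, se = se, odds_ratio = exp(beta),
    ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
    p_value = 2 * pnorm(-abs(beta / se)), separation = sep
  )
  class(out) <- c("logistic_fit", "data.frame")
  out
}

#' Univariate screen at a p-value threshold
#'
#' Fits one univariate logistic model per column and keeps the features
#' with Wald p below `alpha` (the clinical-model pre-selection step,
#' default alpha 0.1), preserving column order.
#'
#' @param table feature table (numeric columns).
#' @param labels 0/1 labels.
#' @param alpha significance threshold.
#' @return Character vector of retained feature names, with the per-feature
#'   fits attached as attribute `"fits"`.
#' @export
screen_univariate <- function(table, labels, alpha = 0.1) {
  fits <- lapply(table, fit_univariate_logistic, y = labels)
  p <- vapply(fits, function(f) f$p_value, numeric(1))
  # complete separation collapses the Wald statistic (Hauck-Donner);
  # a separating feature is maximally associated, so it is kept
  p[vapply(fits, function(f) f$separation, logical(1))] <- 0
  keep <- names(table)[p < alpha]
  attr(keep, "fits") <- do.call(rbind, fits)
  keep
}

#' Multivariate logistic regression
#'
#' Joint maximum-likelihood fit; adjusted odds ratios, Wald CIs and
#' p-values per covariate.  Perfect collinearity or separation aborts
#' with a diagnostic instead of returning unstable estimates.
#'
#' @param table covariate table (>= 1 numeric column).
#' @param labels 0/1 labels.
#' @param conf_level Wald CI level.
#' @return data.frame of class `logistic_fit`, one row per covariate,
#'   with the fitted `glm` attached as attribute `"glm"`.
#' @export
fit_multivariate_logistic <- function(table, labels, conf_level = 0.95) {
  if (ncol(table) < 1) stop("need at least one covariate")
  X <- as.matrix(table)
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("perfect collinearity among covariates")
  df <- data.frame(table, y = labels, check.names = FALSE)
  fit <- suppressWarnings(glm(y ~ ., family = binomial(), data = df))
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15))
    stop("separation or non-convergence in multivariate fit")
  beta <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    coefficient = beta, se = se, odds_ratio = exp(beta),
    ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
    p_value = 2 * pnorm(-abs(beta / se)), separation = FALSE,
    row.names = colnames(table)
  )
  class(out) <- c("logistic_fit", "data.frame")
  attr(out, "glm") <- fit
  out
}

#' Fit the clinico-radiological baseline model
#'
#' The published two-step procedure: univariate screen of all prior
#' features at `alpha`, then a joint multivariate logistic model on the
#' survivors.  The returned object scores new patients via
#' `predict(..., type = "prob")`.
#'
#' @param features table of prior clinico-radiological features.
#' @param labels 0/1 LVI labels.
#' @param alpha univariate screening threshold (default 0.1).
#' @return Object of class `clinical_model`.
#' @export
clinical_model <- function(features, labels, alpha = 0.1) {
  selected <- screen_univariate(features, labels, alpha)
  if (length(selected) == 0) stop("no feature passed the univariate screen")
  multi <- fit_multivariate_logistic(features[, selected, drop = FALSE],
                                     labels)
  structure(list(selected = selected, univariate = attr(selected, "fits"),
                 multivariate = multi, glm = attr(multi, "glm"),
                 alpha = alpha),
            class = "clinical_model")
}

#' @export
print.clinical_model <- function(x, ...) {
  cat(sprintf("clinico-radiological logistic model (univariate screen p < %g)\n",
              x$alpha))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  print(round(as.data.frame(x$multivariate)[
    c("odds_ratio", "ci_lower", "ci_upper", "p_value")], 4))
  invisible(x)
}

#' @rdname clinical_model
#' @param object a `clinical_model`.
#' @param newdata feature table to score.
#' @param type `"prob"` for P(LVI = 1).
#' @param ... unused.
#' @export
predict.clinical_model <- function(object, newdata, type = "prob", ...) {
  if (!all(object$selected %in% names(newdata)))
    stop("newdata lacks the model's features")
  as.numeric(predict(object$glm,
                     newdata = newdata[, object$selected, drop = FALSE],
                     type = "response"))
}

# ---- radiomics selection chain ---------------------------------------

#' Training-set z-score scaler
#'
#' Centres and scales each column to mean 0, sd 1 using training-row
#' statistics; zero-variance columns are dropped with a warning.
#' Validation data are transformed with the training parameters via
#' `predict()`.
#'
#' @param table training feature table.
#' @return Object of class `zscore_scaler` with the transformed training
#'   table in `$scaled`.
#' @export
zscore_normalize <- function(table) {
  if (nrow(table) == 0 || ncol(table) == 0) stop("empty table")
  mu <- vapply(table, mean, numeric(1))
  sdev <- vapply(table, sd, numeric(1))
  drop <- names(table)[sdev == 0 | !is.finite(sdev)]
  if (length(drop))
    warning("dropping constant feature(s): ", paste(drop, collapse = ", "))
  keep <- setdiff(names(table), drop)
  obj <- structure(list(mean = mu[keep], sd = sdev[keep], features = keep,
                        dropped = drop),
                   class = "zscore_scaler")
  obj$scaled <- predict(obj, table)
  obj
}

#' @rdname zscore_normalize
#' @param object a `zscore_scaler`.
#' @param newdata table to transform.
#' @param ... unused.
#' @export
predict.zscore_scaler <- function(object, newdata, ...) {
  out <- newdata[, object$features, drop = FALSE]
  for (f in object$features)
    out[[f]] <- (out[[f]] - object$mean[f]) / object$sd[f]
  out
}

#' Univariate filter for radiomics features
#'
#' Keeps features whose univariate logistic Wald p-value is below `alpha`
#' (default 0.01, the radiomics-chain threshold).  Features flagged for
#' complete separation are kept: their Wald p-value is degenerate
#' (Hauck-Donner collapse) while the association is maximal.
#'
#' @param table normalised feature table.
#' @param labels 0/1 labels.
#' @param alpha threshold.
#' @return Character vector of retained features with p-values attached as
#'   attribute `"p"`.
#' @export
univariate_filter <- function(table, labels, alpha = 0.01) {
  fits <- lapply(table, fit_univariate_logistic, y = labels)
  p <- vapply(fits, function(f) f$p_value, numeric(1))
  p[vapply(fits, function(f) f$separation, logical(1))] <- 0  # Hauck-Donner
  keep <- names(table)[p < alpha]
  attr(keep, "p") <- p
  keep
}

# normality screen deciding Pearson vs Spearman for one pair
.cor_kind <- function(x, y) {
  shap <- function(v) {
    if (length(unique(v)) < 4) return(FALSE)
    v <- if (length(v) > 2000) sample(v, 2000) else v
    shapiro.test(v)$p.value > 0.05
  }
  if (shap(x) && shap(y)) "pearson" else "spearman"
}

#' Greedy correlation pruning
#'
#' Scans features in ascending univariate-p order (the more
#' label-associated member of a redundant pair survives) and removes any
#' feature whose absolute correlation with an already-kept feature is
#' `>= threshold`.  Pearson is used when both columns pass a normality
#' screen, Spearman otherwise; the choice is recorded per removal.
#'
#' @param table feature table.
#' @param threshold absolute correlation cut-off (default 0.90).
#' @param p optional named p-values defining the scan order (ascending);
#'   column order is used when absent.
#' @return Character vector of surviving features; removals (with the
#'   offending correlation and its kind) attached as attribute
#'   `"removed"`.
#' @export
correlation_prune <- function(table, threshold = 0.90, p = NULL) {
  feats <- names(table)
  ord <- if (is.null(p)) seq_along(feats) else order(p[feats])
  kept <- character(0)
  removed <- data.frame(feature = character(0), against = character(0),
                        r = numeric(0), kind = character(0))
  for (f in feats[ord]) {
    drop <- FALSE
    for (k in kept) {
      kind <- .cor_kind(table[[f]], table[[k]])
      r <- cor(table[[f]], table[[k]], method = kind)
      if (is.finite(r) && abs(r) >= threshold) {
        removed <- rbind(removed, data.frame(feature = f, against = k,
                                             r = r, kind = kind))
        drop <- TRUE
        break
      }
    }
    if (!drop) kept <- c(kept, f)
  }
  kept <- feats[feats %in% kept]   # restore column order
  attr(kept, "removed") <- removed
  kept
}

#' LASSO feature selection with cross-validated lambda
#'
#' L1-penalised logistic regression over a log-spaced lambda grid; lambda
#' is chosen at the minimum of the mean 5-fold cross-validated binomial
#' deviance (fold assignment stratified by label and seeded).  Features
#' with non-zero coefficients at the selected lambda are returned.
#'
#' @param table normalised feature table (>= 2 columns).
#' @param labels 0/1 labels, both classes present.
#' @param nfolds cross-validation folds.
#' @param seed fold-assignment seed.
#' @return List with `selected`, `coefficients` (named, non-zero),
#'   `lambda`, and the underlying `cv.glmnet` fit.
#' @export
lasso_cv_select <- function(table, labels, nfolds = 5, seed = 1L) {
  if (length(unique(labels)) < 2) stop("both classes required")
  X <- as.matrix(table)
  set.seed(seed)
  foldid <- integer(length(labels))
  for (cl in c(0, 1)) {
    idx <- which(labels == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  if (min(table(foldid, labels)) == 0)
    stop("degenerate single-class fold; use more data or fewer folds")
  cvfit <- glmnet::cv.glmnet(X, labels, family = "binomial", alpha = 1,
                             foldid = foldid, type.measure = "deviance")
  co <- as.matrix(coef(cvfit, s = "lambda.min"))[-1, 1]
  sel <- names(co)[co != 0]
  list(selected = sel, coefficients = co[co != 0],
       lambda = cvfit$lambda.min, cv_fit = cvfit)
}

#' Fit the radiomics baseline model
#'
#' The published three-step chain on a precomputed radiomics feature
#' table: z-score normalisation (training statistics), univariate filter
#' at p < 0.01, greedy correlation pruning at |r| >= 0.90, LASSO with
#' 5-fold cross-validated lambda.  Scores are the penalised-logistic
#' predicted probabilities at the selected lambda.
#'
#' @param table raw training radiomics table.
#' @param labels 0/1 labels.
#' @param alpha univariate threshold (default 0.01).
#' @param cor_threshold correlation cut-off (default 0.90).
#' @param nfolds,seed LASSO cross-validation controls.
#' @return Object of class `radiomics_model`; `$trace` records the
#'   surviving feature set after each stage (nested subsets).
#' @export
radiomics_model <- function(table, labels, alpha = 0.01,
                            cor_threshold = 0.90, nfolds = 5, seed = 1L) {
  scaler <- zscore_normalize(table)
  scaled <- scaler$scaled
  filtered <- univariate_filter(scaled, labels, alpha)
  if (length(filtered) == 0) stop("no feature passed the univariate filter")
  pruned <- correlation_prune(scaled[, filtered, drop = FALSE],
                              cor_threshold, p = attr(filtered, "p")[filtered])
  las <- if (length(pruned) >= 2)
    lasso_cv_select(scaled[, pruned, drop = FALSE], labels, nfolds, seed)
  else list(selected = pruned, coefficients = NULL, lambda = NA, cv_fit = NULL)
  trace <- list(all = names(table), normalized = scaler$features,
                filtered = as.character(filtered),
                pruned = as.character(pruned),
                selected = as.character(las$selected))
  structure(list(scaler = scaler, lasso = las, trace = trace,
                 alpha = alpha, cor_threshold = cor_threshold),
            class = "radiomics_model")
}

#' @export
print.radiomics_model <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("radiomics selection chain: %d -> %d (p < %g) -> %d (|r| < %g) -> %d (LASSO)\n",
              length(tr$all), length(tr$filtered), x$alpha,
              length(tr$pruned), x$cor_threshold, length(tr$selected)))
  invisible(x)
}

#' @rdname radiomics_model
#' @param object a `radiomics_model`.
#' @param newdata raw feature table to score.
#' @param ... unused.
#' @export
predict.radiomics_model <- function(object, newdata, ...) {
  scaled <- predict(object$scaler, newdata)
  X <- as.matrix(scaled[, object$trace$pruned, drop = FALSE])
  as.numeric(predict(object$lasso$cv_fit, newx = X, s = "lambda.min",
                     type = "response"))
}

#' Score patients with a fitted clinical model
#'
#' Thin functional wrapper kept for symmetry with the other model
#' families: logistic probabilities in (0, 1).
#'
#' @param model a `clinical_model`.
#' @param table feature table.
#' @return Numeric vector of P(LVI = 1).
#' @export
score_clinical <- function(model, table) {
  predict(model, table)
}
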