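test_that("the univariate logistic OR equals the 2x2 cross-product ratio", {
  counts <- lvi_table1_counts()
  d <- expand_counts(counts, "peritumoral_edema")
  f <- fit_univariate_logistic(d$x, d$y)
  expect_equal(signif(f$odds_ratio, 2), 7.5)   # published value
  expect_equal(f$odds_ratio, (39 * 143) / (37 * 20), tolerance = 1e-6)
  # no association on a balanced table
  bal <- data.frame(x = rep(c(0, 1), each = 20), y = rep(c(0, 1, 0, 1), each = 10))
  expect_equal(fit_univariate_logistic(bal$x, bal$y)$odds_ratio, 1,
               tolerance = 1e-8)
  # random tables: MLE equals the closed form
  set.seed(1)
  for (i in 1:20) {
    cells <- rpois(4, 30) + 1   # a d / b c
    x <- rep(c(0, 0, 1, 1), cells)
    y <- rep(c(0, 1, 0, 1), cells)
    f <- fit_univariate_logistic(x, y)
    expect_equal(f$odds_ratio, (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-6)
  }
  # complete separation is flagged, not silently estimated
  sep <- fit_univariate_logistic(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))
  expect_true(sep$separation)
  expect_error(fit_univariate_logistic(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the univariate screen keeps features below the threshold", {
  set.seed(2)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  tab <- data.frame(signal = y + rnorm(n, 0, 0.6), noise1 = rnorm(n),
                    noise2 = rnorm(n))
  expect_identical(as.character(screen_univariate(tab, y, alpha = 1e-12)),
                   character(0))
  expect_identical(as.character(screen_univariate(tab, y, alpha = 1)),
                   names(tab))
  expect_true("signal" %in% screen_univariate(tab, y, alpha = 0.1))
})

test_that("the multivariate fit reduces, recovers and fails as it should", {
  set.seed(3)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  uni <- fit_univariate_logistic(x, y)
  multi <- fit_multivariate_logistic(data.frame(x = x), y)
  expect_equal(multi$coefficient, uni$coefficient, tolerance = 1e-8)
  expect_equal(multi$p_value, uni$p_value, tolerance = 1e-8)
  # simulation recovery at n = 5000 with known coefficients
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(-1 + 1.0 * x1 + 0.5 * x2))
  m2 <- fit_multivariate_logistic(data.frame(x1 = x1, x2 = x2), y2)
  expect_lt(abs(m2["x1", "coefficient"] - 1.0), 3 * m2["x1", "se"])
  expect_lt(abs(m2["x2", "coefficient"] - 0.5), 3 * m2["x2", "se"])
  expect_error(fit_multivariate_logistic(data.frame(a = x1, b = x1), y2),
               "collinearity")
})

test_that("z-score normalisation is a training-statistics fixed point", {
  tab <- data.frame(a = c(1, 2, 3), b = c(10, 20, 60), flat = c(5, 5, 5))
  expect_warning(sc <- zscore_normalize(tab), "constant")
  expect_equal(sc$scaled$a, c(-1, 0, 1))
  expect_equal(sd(sc$scaled$b), 1)
  expect_false("flat" %in% names(sc$scaled))
  # population-sd convention check: (1,2,3) scaled by its sample sd
  expect_equal((c(1, 2, 3) - 2) / sd(c(1, 2, 3)), sc$scaled$a)
  # re-normalising already-normalised training data is a no-op
  sc2 <- zscore_normalize(sc$scaled)
  expect_equal(as.matrix(sc2$scaled), as.matrix(sc$scaled), tolerance = 1e-12)
  expect_error(zscore_normalize(tab[0, , drop = FALSE]), "empty")
})

test_that("the radiomics univariate filter controls the type-I rate", {
  set.seed(4)
  n <- 120
  y <- rbinom(n, 1, 0.35)
  strong <- data.frame(f = y + rnorm(n, 0, 0.1))
  expect_identical(as.character(univariate_filter(strong, y, 0.01)), "f")
  expect_identical(as.character(univariate_filter(strong, y, 0)), character(0))
  noise <- as.data.frame(matrix(rnorm(n * 1000), n))
  kept <- univariate_filter(noise, y, 0.01)
  expect_lt(length(kept), 10 + 3 * sqrt(1000 * 0.01 * 0.99))
  expect_gte(length(kept), 1)    # ~10 expected under the null
})

test_that("correlation pruning leaves no redundant pair", {
  set.seed(5)
  n <- 150
  base <- matrix(rnorm(n * 40), n)
  tab <- as.data.frame(base)
  tab$dup <- tab$V1                      # exact duplicate
  tab$near <- tab$V2 + rnorm(n, 0, 0.05) # |r| > 0.99
  kept <- correlation_prune(tab, 0.90)
  expect_true(xor("V1" %in% kept, "dup" %in% kept))
  expect_false(all(c("V2", "near") %in% kept))
  # all-pairs brute force on the survivors
  km <- as.matrix(tab[, kept])
  cc <- abs(cor(km))
  diag(cc) <- 0
  expect_lt(max(cc), 0.90)
  # orthogonal features all kept
  orth <- as.data.frame(qr.Q(qr(matrix(rnorm(100), 20, 5))))
  expect_equal(length(correlation_prune(orth, 0.9)), 5)
  # the lower-p member of a redundant pair survives
  p <- c(V1 = 0.5, dup = 0.001)
  kept2 <- correlation_prune(tab[, c("V1", "dup")], 0.9, p = p)
  expect_identical(as.character(kept2), "dup")
})

test_that("cross-validated LASSO recovers a planted sparse signal", {
  set.seed(6)
  n <- 500; p <- 50
  hits <- logical(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
    eta <- 1.5 * X[, 1] + 1.5 * X[, 2] + 1.5 * X[, 3] - 0.5
    y <- rbinom(n, 1, plogis(eta))
    sel <- lasso_cv_select(as.data.frame(X), y, seed = s)
    hits[s] <- all(c("f1", "f2", "f3") %in% sel$selected)
    expect_true(all(sel$selected %in% colnames(X)))
  }
  expect_gte(mean(hits), 0.9)
})

test_that("the LASSO path is monotone in the penalty", {
  set.seed(7)
  X <- matrix(rnorm(200 * 20), 200)
  y <- rbinom(200, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1)
  nz <- fit$df                       # nonzeros along the decreasing-lambda path
  expect_true(all(diff(nz[order(fit$lambda, decreasing = TRUE)]) >= 0))
  # heavy penalty: empty selection
  co <- as.matrix(coef(fit, s = max(fit$lambda)))[-1, 1]
  expect_equal(sum(co != 0), 0)
})

test_that("the radiomics chain yields nested stages and valid scores", {
  set.seed(8)
  n <- 160; p <- 40
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("r", 1:p)))
  X[, 2] <- X[, 1] + rnorm(n, 0, 0.05)          # redundant pair
  y <- rbinom(n, 1, plogis(1.2 * X[, 1] + 0.8 * X[, 3] - 0.6))
  rm <- radiomics_model(as.data.frame(X), y)
  tr <- rm$trace
  expect_true(all(tr$selected %in% tr$pruned))
  expect_true(all(tr$pruned %in% tr$filtered))
  expect_true(all(tr$filtered %in% tr$normalized))
  expect_true(all(tr$normalized %in% tr$all))
  sc <- predict(rm, as.data.frame(X))
  expect_true(all(sc > 0 & sc < 1))
  expect_gt(compute_roc_auc(sc, y)$auc, 0.6)
})

test_that("the clinical baseline reproduces the published selection pathway", {
  spec <- cohort_spec(n_cases = 400, seed = 9)
  feats <- sample_clinical_features(400, spec)
  b0 <- calibrate_intercept(spec, feats)
  y <- sample_labels(feats, b0, spec$effects, seed = 10)
  cm <- clinical_model(feats, y)
  expect_true("peritumoral_edema" %in% cm$selected)
  p <- predict(cm, feats)
  expect_true(all(p > 0 & p < 1))
  expect_equal(score_clinical(cm, feats), p)
  # probabilities follow the logistic formula of the fitted coefficients
  co <- coef(cm$glm)
  eta <- co[1]
  for (nm in cm$selected) eta <- eta + co[[nm]] * feats[[nm]]
  expect_equal(p, unname(plogis(eta)), tolerance = 1e-10)
  # monotone in a positive-coefficient covariate
  if (co[["peritumoral_edema"]] > 0) {
    f2 <- feats; f2$peritumoral_edema <- 1
    f1 <- feats; f1$peritumoral_edema <- 0
    expect_true(all(predict(cm, f2) > predict(cm, f1)))
  }
})
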