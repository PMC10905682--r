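test_that("clinical feature sampling follows the configured marginals", {
  spec <- cohort_spec(seed = 11)
  feats <- sample_clinical_features(239, spec)
  expect_equal(nrow(feats), 239)
  expect_named(feats, prior_feature_names())
  # edema marginal 0.318: realized prevalence within 3 binomial SEs
  se <- sqrt(0.318 * 0.682 / 239)
  expect_lt(abs(mean(feats$peritumoral_edema) - 0.318), 3 * se)
  # schema on a single draw
  one <- sample_clinical_features(1, spec)
  expect_equal(nrow(one), 1)
  expect_true(all(one$tic_curve %in% 1:3))
  expect_true(all(one$fgt_density %in% 1:4))
  expect_true(one$age > 0)
  expect_true(one$aln_short_axis >= 0)
  # determinism
  expect_identical(feats, sample_clinical_features(239, spec))
  # invalid marginal rejected
  bad <- table1_marginals()
  bad$peritumoral_edema$prob <- c(0.7, 0.7)
  expect_error(cohort_spec(marginals = bad), "invalid marginal")
})

test_that("intercept calibration hits the target prevalence", {
  spec0 <- cohort_spec(n_cases = 500, effects = c(peritumoral_edema = 0), seed = 2)
  feats <- sample_clinical_features(500, spec0)
  expect_equal(calibrate_intercept(
    cohort_spec(n_cases = 500, prevalence = 0.5,
                effects = c(peritumoral_edema = 0), seed = 2), feats),
    0, tolerance = 1e-6)
  expect_equal(calibrate_intercept(
    cohort_spec(n_cases = 500, prevalence = 0.247,
                effects = c(peritumoral_edema = 0), seed = 2), feats),
    qlogis(0.247), tolerance = 1e-6)
  # with a strong planted effect: verify by direct averaging over the table
  spec <- cohort_spec(n_cases = 500, seed = 2)
  b0 <- calibrate_intercept(spec, feats)
  eta <- b0 + log(7.5) * feats$peritumoral_edema +
    log(4.3) * feats$dwi_rim_sign + log(2.1) * feats$adjacent_vessel_sign
  expect_equal(mean(plogis(eta)), 0.247, tolerance = 1e-6)
  expect_error(cohort_spec(n_cases = 500, prevalence = 1), "prevalence")
})

test_that("label sampling is a seeded Bernoulli draw from the logistic model", {
  spec <- cohort_spec(n_cases = 400, seed = 3)
  feats <- sample_clinical_features(400, spec)
  # intercept -> -Inf limit: all negative
  l0 <- sample_labels(feats, -50, c(peritumoral_edema = 0), seed = 4)
  expect_true(all(l0 == 0))
  expect_identical(sample_labels(feats, -1, spec$effects, seed = 5),
                   sample_labels(feats, -1, spec$effects, seed = 5))
})

test_that("planted odds ratios are recovered by univariate logistic regression", {
  # a single planted binary effect: the marginal (univariate) OR then equals
  # the planted conditional OR, so the Wald CI should cover 7.5 in most
  # repeated draws.  (With several planted effects the marginal OR is
  # attenuated by non-collapsibility and 7.5 is not the right target.)
  spec <- cohort_spec(n_cases = 2000, seed = 1,
                      effects = c(peritumoral_edema = log(7.5)))
  feats <- sample_clinical_features(2000, spec)
  b0 <- calibrate_intercept(spec, feats)
  covered <- recovered <- logical(60)
  for (i in seq_along(covered)) {
    y <- sample_labels(feats, b0, spec$effects, seed = 100 + i)
    f <- fit_univariate_logistic(feats$peritumoral_edema, y)
    covered[i] <- f$ci_lower <= 7.5 && 7.5 <= f$ci_upper
    recovered[i] <- abs(f$coefficient - log(7.5)) <= 3 * f$se
  }
  expect_gte(mean(covered), 0.9)
  expect_gte(mean(recovered), 0.95)
})

test_that("cohort prevalence is calibrated within binomial tolerance", {
  spec <- cohort_spec(n_cases = 2000, seed = 7)
  feats <- sample_clinical_features(2000, spec)
  b0 <- calibrate_intercept(spec, feats)
  y <- sample_labels(feats, b0, spec$effects, seed = 8)
  tol <- 3 * sqrt(0.247 * 0.753 / 2000)
  expect_lt(abs(mean(y) - 0.247), tol)
})

test_that("case rendering produces label-linked image signs", {
  spec <- tiny_cohort_spec(noise_sd = 0)
  feats <- sample_clinical_features(1, spec)
  feats$dwi_rim_sign <- 0; feats$peritumoral_edema <- 0
  cs <- render_case(feats, 0L, spec, case_seed = 21)
  expect_length(cs$volumes, 3)
  expect_true(all(vapply(cs$volumes, function(v) all(v >= 0), logical(1))))
  # noiseless, no rim/halo: the brightest voxel sits at the lesion center
  mx <- which(cs$volumes[[1]] == max(cs$volumes[[1]]), arr.ind = TRUE)[1, ]
  expect_true(all(abs(mx - cs$voi_center) <= 1))

  # rim on vs off: mean intensity on the lesion shell strictly greater
  feats_rim <- feats; feats_rim$dwi_rim_sign <- 1
  cs_rim <- render_case(feats_rim, 1L, spec, case_seed = 21)
  d <- spec$volume_shape
  ctr <- cs$voi_center
  grid <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  dist <- sqrt((grid$i - ctr[1])^2 + (grid$j - ctr[2])^2 + (grid$k - ctr[3])^2)
  shell <- dist > 4 & dist < 9   # generous band around the lesion surface
  expect_gt(mean(cs_rim$volumes[[3]][shell]), mean(cs$volumes[[3]][shell]))

  # determinism
  cs2 <- render_case(feats, 0L, spec, case_seed = 21)
  expect_identical(cs$volumes, cs2$volumes)

  # lesion larger than volume is refused
  expect_error(cohort_spec(volume_shape = c(32, 32, 32),
                           lesion_radius_range = c(14, 15)),
               "lesion larger")
})

test_that("cohort generation round-trips through NIfTI and CSV", {
  dir <- withr::local_tempdir()
  spec <- tiny_cohort_spec(n = 6, seed = 5)
  man <- generate_cohort(spec, dir)
  expect_equal(length(list.files(dir, pattern = "\\.nii\\.gz$")), 18)
  tab <- read.csv(file.path(dir, "features.csv"))
  expect_equal(nrow(tab), 6)
  expect_true(all(c("case_id", prior_feature_names(), "lvi") %in% names(tab)))
  expect_equal(man$n_cases, 6)

  back <- read_cohort(dir)
  expect_equal(length(back$cases), 6)
  # volumes survive the round trip exactly (written values reproduced)
  cs <- render_case(back$features[2, , drop = FALSE], back$labels[2], spec,
                    case_seed = spec$seed + 1000L + 2L)
  expect_equal(back$cases[[2]]$volumes[[1]], cs$volumes[[1]],
               tolerance = 1e-6)

  # regeneration is byte-identical at the table level
  dir2 <- withr::local_tempdir()
  generate_cohort(spec, dir2)
  expect_identical(unname(tools::md5sum(file.path(dir, "features.csv"))),
                   unname(tools::md5sum(file.path(dir2, "features.csv"))))
})
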