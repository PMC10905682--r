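test_that("intensity normalisation clips negatives and scales to [0, 1]", {
  set.seed(1)
  v <- array(runif(6^3, -5, 10), c(6, 6, 6))
  nv <- normalize_intensity(v)
  expect_equal(min(nv), 0)
  expect_equal(max(nv), 1)
  expect_equal(normalize_intensity(array(0, c(3, 3, 3))), array(0, c(3, 3, 3)))
  expect_equal(normalize_intensity(nv), nv)   # idempotent
  v[1] <- NaN
  expect_error(normalize_intensity(v), "non-finite")
})

test_that("VOI patch cropping uses a half-open window with zero padding", {
  set.seed(2)
  vol <- array(rnorm(64^3), c(64, 64, 64))
  p <- crop_voi_patch(vol, c(33, 33, 33), 32)
  expect_equal(p, vol[17:48, 17:48, 17:48])
  # corner crop: exactly one octant from the volume, the rest zeros
  pc <- crop_voi_patch(vol, c(1, 1, 1), 32)
  expect_equal(pc[17:32, 17:32, 17:32], vol[1:16, 1:16, 1:16])
  expect_true(all(pc[1:16, , ] == 0))
  expect_equal(sum(pc != 0), sum(vol[1:16, 1:16, 1:16] != 0))
  # brute-force index oracle at a random center
  ctr <- c(9, 40, 22)
  p2 <- crop_voi_patch(vol, ctr, 32)
  for (t in 1:50) {
    ijk <- sample(32, 3, replace = TRUE)
    src <- ctr - 16 + ijk - 1 + c(0, 0, 0)
    expected <- if (all(src >= 1 & src <= 64)) vol[src[1], src[2], src[3]] else 0
    expect_identical(p2[ijk[1], ijk[2], ijk[3]], expected)
  }
  expect_error(crop_voi_patch(vol, c(0, 5, 5)), "outside")
})

test_that("normalisation before cropping differs from cropping first and is the fixed order", {
  vol <- array(0, c(48, 48, 48))
  vol[40, 40, 40] <- 10          # global max far from the patch
  vol[10, 10, 10] <- 2
  a <- crop_voi_patch(normalize_intensity(vol), c(10, 10, 10), 8)
  b <- normalize_intensity(crop_voi_patch(vol, c(10, 10, 10), 8))
  expect_equal(max(a), 0.2)      # anchored to the whole-volume max
  expect_equal(max(b), 1)        # re-anchored to the patch max
  expect_false(isTRUE(all.equal(a, b)))
  # the pipeline normalises the whole volume first
  ds <- simulate_patch_dataset(tiny_cohort_spec(n = 2), patch_size = 16)
  expect_lte(max(ds$images), 1)
})

test_that("prior feature scaling is training min-max with clipped transform", {
  train <- data.frame(age = c(25, 55, 85), flag = c(0, 1, 0), const = c(2, 2, 2))
  sc <- prior_scaler(train)
  scaled <- predict(sc, train)
  expect_equal(scaled$age, c(0, 0.5, 1))
  expect_equal(scaled$flag, c(0, 1, 0))          # binary unchanged
  expect_equal(scaled$const, c(0, 0, 0))         # constant maps to 0
  val <- predict(sc, data.frame(age = 90, flag = 1, const = 5))
  expect_equal(val$age, 1)                       # clipped, matches direct rule
  expect_equal(val$age, min(max((90 - 25) / 60, 0), 1))
  expect_error(prior_scaler(train[0, ]), "empty")
})

test_that("prior planes are constant with the feature value", {
  v <- runif(16)
  planes <- encode_prior_planes(v, size = 8)
  expect_equal(dim(planes), c(16L, 8L, 8L, 8L))
  for (f in 1:16) {
    expect_equal(var(c(planes[f, , , ])), 0)
    expect_equal(mean(planes[f, , , ]), v[f])
  }
  expect_true(all(planes[3, , , ] == v[3]))
  expect_error(encode_prior_planes(c(v[-1], 1.5)), "outside")
})

test_that("input assembly stacks channels recoverably", {
  set.seed(3)
  patches <- array(runif(3 * 8^3), c(3, 8, 8, 8))
  planes <- encode_prior_planes(runif(16), 8)
  x <- assemble_input(patches, planes)
  expect_equal(dim(x), c(19L, 8L, 8L, 8L))
  expect_equal(x[1:3, , , ], patches)
  expect_equal(x[4:19, , , ], planes)
  # ablation mode: no planes
  x3 <- assemble_input(patches)
  expect_equal(dim(x3), c(3L, 8L, 8L, 8L))
  # round trip: slice and restack
  expect_equal(assemble_input(x[1:3, , , , drop = FALSE], x[4:19, , , , drop = FALSE]), x)
  expect_error(assemble_input(patches, planes[, 1:4, , , drop = FALSE]), "mismatch")
})

test_that("random flipping is a seeded involution preserving voxels", {
  set.seed(4)
  x <- array(runif(19 * 6^3), c(19, 6, 6, 6))
  f1 <- random_flip(x, mask = c(TRUE, TRUE, TRUE))
  f2 <- random_flip(f1, mask = c(TRUE, TRUE, TRUE))
  expect_equal(array(f2, dim(x)), x)
  # per-channel voxel multisets preserved
  fs <- random_flip(x, seed = 9)
  for (c in c(1, 7, 19))
    expect_equal(sort(c(fs[c, , , ])), sort(c(x[c, , , ])))
  # reproducible mask
  expect_equal(attr(random_flip(x, seed = 9), "flip_mask"),
               attr(random_flip(x, seed = 9), "flip_mask"))
  # constant planes unchanged
  planes <- encode_prior_planes(runif(16), 6)
  x2 <- assemble_input(array(runif(3 * 6^3), c(3, 6, 6, 6)), planes)
  ff <- random_flip(x2, mask = c(TRUE, FALSE, TRUE))
  expect_equal(ff[4:19, , , ], planes)
})

test_that("the stratified split partitions cases at the 7:3 ratio", {
  labels <- c(rep(0, 256), rep(1, 85))
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_setequal(c(sp$train, sp$validation), seq_along(labels))
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_equal(sum(labels[sp$validation] == 0), 76)
  expect_equal(sum(labels[sp$validation] == 1), 25)   # floor rule
  sp2 <- stratified_split(labels, 0.7, seed = 1, allocation = "largest_remainder")
  expect_equal(length(sp2$validation), 102)
  expect_true(sum(labels[sp2$validation] == 1) %in% c(25, 26))

  # 10 cases, balanced labels: exact 7/3 under the largest-remainder rule,
  # 8/2 under the conservative floor rule
  small <- stratified_split(rep(c(0, 1), each = 5), 0.7, seed = 2,
                            allocation = "largest_remainder")
  expect_length(small$train, 7)
  expect_length(small$validation, 3)
  smallf <- stratified_split(rep(c(0, 1), each = 5), 0.7, seed = 2)
  expect_length(smallf$validation, 2)

  expect_identical(stratified_split(labels, 0.7, seed = 3),
                   stratified_split(labels, 0.7, seed = 3))
  expect_error(stratified_split(integer(0)), "stratum|empty")
  # per-stratum fraction within one case of the target
  for (s in c(0, 1)) {
    nval <- sum(labels[sp$validation] == s)
    expect_lt(abs(nval - 0.3 * sum(labels == s)), 1)
  }
})
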