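#' Canonical order of the 16 prior clinico-radiological features
#'
#' The fixed field order used everywhere a feature vector is turned into
#' network input planes (channels 4..19 of the fused tensor).
#'
#' @return Character vector of length 16.
#' @export
prior_feature_names <- function() {
  c("age", "menopausal_status", "location", "tic_curve", "fgt_density",
    "bpe", "intratumoral_high_signal", "peritumoral_edema",
    "subcutaneous_edema", "intratumoral_necrosis", "internal_enhancement",
    "adjacent_vessel_sign", "increased_ipsilateral_vascularity",
    "mraln_status", "aln_short_axis", "dwi_rim_sign")
}

#' Default planted label effects
#'
#' Log odds-ratios used by the generator's label model.  Defaults mirror
#' the dominant univariate associations of the modelled study: peritumoral
#' edema OR 7.5, DWI rim sign OR 4.3, adjacent vessel sign OR 2.1; all
#' other features carry no direct effect.
#'
#' @return Named numeric vector of log odds-ratios.
#' @export
default_planted_effects <- function() {
  c(peritumoral_edema = log(7.5),
    dwi_rim_sign = log(4.3),
    adjacent_vessel_sign = log(2.1))
}

#' Specification of a synthetic LVI cohort
#'
#' Bundles every knob of the generator: cohort size, target LVI prevalence,
#' planted feature effects on the label, rendering geometry/contrast of the
#' three modality volumes, noise level and the master seed.
#'
#' @param n_cases number of patients (>= 2).
#' @param prevalence target marginal P(LVI = 1), strictly in (0, 1).
#'   Default 0.247 matches the modelled training cohort (59/239).
#' @param effects named numeric vector of log odds-ratios on the label.
#' @param marginals feature marginals as produced by [table1_marginals()].
#' @param volume_shape integer triple, each >= 32.
#' @param lesion_radius_range range (voxels) for the ellipsoid semi-axes.
#' @param contrast length-3 numeric, additive lesion intensity per modality.
#' @param rim_amplitude added shell intensity on modality 3 when
#'   `dwi_rim_sign == 1`.
#' @param halo_amplitude added peri-lesional halo intensity on modality 2
#'   when `peritumoral_edema == 1`.
#' @param noise_sd standard deviation of additive Gaussian voxel noise, in
#'   the same arbitrary intensity units as `contrast`.
#' @param seed master seed; per-case rendering uses substreams offset by
#'   the case index so cohorts are extensible without reshuffling.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 239, prevalence = 0.247,
                        effects = default_planted_effects(),
                        marginals = table1_marginals(),
                        volume_shape = c(40L, 40L, 40L),
                        lesion_radius_range = c(5, 8),
                        contrast = c(1.0, 0.8, 1.2),
                        rim_amplitude = 0.3, halo_amplitude = 0.25,
                        noise_sd = 0.3, seed = 1L) {
  stopifnot(n_cases >= 2, prevalence > 0, prevalence < 1,
            all(volume_shape >= 32), length(volume_shape) == 3,
            all(is.finite(effects)), length(contrast) == 3,
            lesion_radius_range[1] > 0,
            diff(lesion_radius_range) >= 0)
  for (m in marginals) {
    if (m$type != "continuous" &&
        (any(m$prob < 0) || abs(sum(m$prob) - 1) > 1e-8))
      stop("invalid marginal: probabilities must be in [0,1] and sum to 1")
  }
  if (max(lesion_radius_range) * 2 + 8 > min(volume_shape))
    stop("lesion larger than volume")
  structure(list(
    n_cases = as.integer(n_cases), prevalence = prevalence,
    effects = effects, marginals = marginals,
    volume_shape = as.integer(volume_shape),
    lesion_radius_range = lesion_radius_range, contrast = contrast,
    rim_amplitude = rim_amplitude, halo_amplitude = halo_amplitude,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Draw clinico-radiological feature vectors
#'
#' Samples `n` independent patients from the marginals of a [cohort_spec()].
#' Features are drawn independently of each other (the modelled study
#' reports no inter-feature correlations).
#'
#' @param n number of patients (>= 1).
#' @param spec a [cohort_spec()].
#' @param seed optional seed; defaults to `spec$seed`.
#' @return data.frame with the 16 columns of [prior_feature_names()].
#' @export
sample_clinical_features <- function(n, spec, seed = spec$seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  out <- lapply(prior_feature_names(), function(f) {
    m <- spec$marginals[[f]]
    if (m$type == "continuous") m$sample(n)
    else sample(m$levels, n, replace = TRUE, prob = m$prob)
  })
  names(out) <- prior_feature_names()
  as.data.frame(out)
}

# linear predictor excluding the intercept
.planted_eta <- function(features, effects) {
  eta <- numeric(nrow(features))
  for (f in names(effects)) {
    if (!f %in% names(features)) stop("effect on unknown feature: ", f)
    eta <- eta + effects[[f]] * features[[f]]
  }
  eta
}

#' Calibrate the label-model intercept to a target prevalence
#'
#' Finds, by monotone root search, the intercept b0 such that the mean of
#' plogis(b0 + sum_f effect_f x_f) over the supplied feature table equals
#' the target prevalence to within 1e-6.
#'
#' @param spec a [cohort_spec()]; supplies effects and the target.
#' @param features feature table the mean is taken over.
#' @return The intercept (log-odds scale).
#' @export
calibrate_intercept <- function(spec, features) {
  target <- spec$prevalence
  if (target <= 0 || target >= 1) stop("unattainable prevalence target")
  eta <- .planted_eta(features, spec$effects)
  f <- function(b0) mean(plogis(b0 + eta)) - target
  uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
}

#' Sample binary LVI labels from the planted logistic model
#'
#' @param features feature table.
#' @param intercept calibrated intercept from [calibrate_intercept()].
#' @param effects named log odds-ratio vector.
#' @param seed RNG seed.
#' @return Integer 0/1 vector, one label per row of `features`.
#' @export
sample_labels <- function(features, intercept, effects, seed) {
  p <- plogis(intercept + .planted_eta(features, effects))
  set.seed(seed)
  rbinom(nrow(features), 1L, p)
}

#' Render one synthetic three-modality case
#'
#' Draws an ellipsoidal lesion at the VOI center with modality-specific
#' additive contrast, plus two label-linked image signs: a bright shell on
#' modality 3 when `dwi_rim_sign == 1` (DWI rim analogue) and a
#' peri-lesional halo on modality 2 when `peritumoral_edema == 1`
#' (peritumoral edema analogue).  Gaussian noise is added and negative
#' intensities are clipped to zero.
#'
#' @param features single-row data.frame of the 16 prior features.
#' @param label 0/1 LVI label (stored on the case; rendering itself is
#'   driven by the image-linked binary features, not the label).
#' @param spec a [cohort_spec()].
#' @param case_seed seed for this case's rendering substream.
#' @param case_id identifier string.
#' @return A `case` object: list with `case_id`, `volumes` (list of three
#'   equal-shape 3D arrays), `voi_center`, `features`, `lvi_label`.
#' @export
render_case <- function(features, label, spec, case_seed,
                        case_id = "case_0001") {
  stopifnot(nrow(features) == 1)
  set.seed(case_seed)
  dims <- spec$volume_shape
  rr <- spec$lesion_radius_range
  radii <- runif(3, rr[1], rr[2])
  if (any(2 * radii > dims)) stop("lesion larger than volume")
  center <- round(dims / 2 + runif(3, -2, 2))
  center <- pmin(pmax(center, ceiling(max(radii)) + 1),
                 dims - ceiling(max(radii)))

  # normalised ellipsoidal distance field (1 on the lesion surface)
  ax <- (seq_len(dims[1]) - center[1])
  ay <- (seq_len(dims[2]) - center[2])
  az <- (seq_len(dims[3]) - center[3])
  d2 <- outer(outer((ax / radii[1])^2, (ay / radii[2])^2, "+"),
              (az / radii[3])^2, "+")
  d <- sqrt(d2)
  interior <- d <= 1
  # soft edge so the lesion is not a binary stamp
  core <- pmax(1 - d^2, 0)   # array first: pmax keeps the dim of arg 1
  shell <- d > 1 & d <= 1.3
  halo <- d > 1.15 & d <= 1.75

  rim_on <- features$dwi_rim_sign[1] == 1
  halo_on <- features$peritumoral_edema[1] == 1

  volumes <- vector("list", 3)
  for (m in 1:3) {
    v <- spec$contrast[m] * core
    if (m == 3 && rim_on) v[shell] <- v[shell] + spec$rim_amplitude
    if (m == 2 && halo_on) v[halo] <- v[halo] + spec$halo_amplitude
    if (spec$noise_sd > 0)
      v <- v + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
    v[v < 0] <- 0
    volumes[[m]] <- v
  }
  structure(list(case_id = case_id, volumes = volumes,
                 voi_center = as.integer(center),
                 features = features, lvi_label = as.integer(label),
                 interior = NULL),
            class = "case")
}

#' Generate a cohort on disk
#'
#' Writes, per case, three NIfTI modality volumes named
#' `{case_id}_{mod}.nii.gz`, one `features.csv` with the 18-column layout
#' (case_id, 16 features, lvi) plus the VOI center, and a JSON manifest
#' echoing the spec and seed.  Regeneration with an identical spec is
#' byte-identical.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
generate_cohort <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  feats <- sample_clinical_features(spec$n_cases, spec)
  b0 <- calibrate_intercept(spec, feats)
  labels <- sample_labels(feats, b0, spec$effects, seed = spec$seed + 1L)
  ids <- sprintf("case_%04d", seq_len(spec$n_cases))
  centers <- matrix(NA_integer_, spec$n_cases, 3)
  mods <- c("mod1", "mod2", "mod3")
  for (i in seq_len(spec$n_cases)) {
    cs <- render_case(feats[i, , drop = FALSE], labels[i], spec,
                      case_seed = spec$seed + 1000L + i, case_id = ids[i])
    centers[i, ] <- cs$voi_center
    for (m in 1:3) {
      path <- file.path(out_dir, paste0(ids[i], "_", mods[m], ".nii.gz"))
      RNifti::writeNifti(cs$volumes[[m]], path)
    }
  }
  tab <- cbind(data.frame(case_id = ids), feats,
               data.frame(lvi = labels,
                          voi_x = centers[, 1], voi_y = centers[, 2],
                          voi_z = centers[, 3]))
  write.csv(tab, file.path(out_dir, "features.csv"), row.names = FALSE)
  manifest <- list(
    n_cases = spec$n_cases, prevalence_target = spec$prevalence,
    intercept = b0, effects = as.list(spec$effects),
    volume_shape = spec$volume_shape, noise_sd = spec$noise_sd,
    seed = spec$seed, modalities = mods
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort directory back into case objects
#'
#' @param dir directory written by [generate_cohort()].
#' @return List with `cases` (list of `case` objects), `features`, `labels`
#'   and the parsed `manifest`.
#' @export
read_cohort <- function(dir) {
  tab <- read.csv(file.path(dir, "features.csv"), stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mods <- manifest$modalities
  cases <- lapply(seq_len(nrow(tab)), function(i) {
    vols <- lapply(mods, function(m) {
      v <- RNifti::readNifti(file.path(dir, paste0(tab$case_id[i], "_", m, ".nii.gz")))
      array(as.numeric(v), dim = dim(v))
    })
    structure(list(case_id = tab$case_id[i], volumes = vols,
                   voi_center = as.integer(tab[i, c("voi_x", "voi_y", "voi_z")]),
                   features = tab[i, prior_feature_names(), drop = FALSE],
                   lvi_label = as.integer(tab$lvi[i])),
              class = "case")
  })
  list(cases = cases, features = tab[, prior_feature_names(), drop = FALSE],
       labels = as.integer(tab$lvi), manifest = manifest)
}

#' Simulate an in-memory patch data set
#'
#' End-to-end convenience path for experiments: samples features and
#' labels, renders each case, normalises each modality volume to [0, 1]
#' and crops the 32-voxel cube at the VOI center.  Volumes are discarded
#' after cropping so the memory footprint stays at patch scale.
#'
#' @param spec a [cohort_spec()].
#' @param patch_size cube edge in voxels.
#' @return List with `images` (3, s, s, s, n array), `features`
#'   (data.frame), `labels` (0/1), `intercept`.
#' @export
simulate_patch_dataset <- function(spec, patch_size = 32L) {
  feats <- sample_clinical_features(spec$n_cases, spec)
  b0 <- calibrate_intercept(spec, feats)
  labels <- sample_labels(feats, b0, spec$effects, seed = spec$seed + 1L)
  n <- spec$n_cases
  images <- array(0, c(3L, patch_size, patch_size, patch_size, n))
  for (i in seq_len(n)) {
    cs <- render_case(feats[i, , drop = FALSE], labels[i], spec,
                      case_seed = spec$seed + 1000L + i,
                      case_id = sprintf("case_%04d", i))
    for (m in 1:3) {
      v <- normalize_intensity(cs$volumes[[m]])
      images[m, , , , i] <- crop_voi_patch(v, cs$voi_center, patch_size)
    }
  }
  list(images = images, features = feats, labels = labels, intercept = b0)
}
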