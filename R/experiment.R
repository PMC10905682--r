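#' Desk-scale network configuration
#'
#' A reduced instance of the architecture sized for CPU-only experiments
#' on synthetic cohorts: 6 head channels, stride-2 head convolution,
#' factor-4 pooling, 2 residual channel-attention blocks, attention
#' reduction 3.  The
#' topology (head conv + BN + ReLU + pool, RCAB body, GAP + linear tail)
#' is unchanged from the full model.
#'
#' @param arch `"pcmm"` (19-channel fusion) or `"mm"` (3-channel
#'   image-only ablation).
#' @return A [net_config()].
#' @export
desk_net_config <- function(arch = c("pcmm", "mm")) {
  arch <- match.arg(arch)
  net_config(in_channels = if (arch == "pcmm") 19L else 3L,
             head_channels = 6L, n_rcab = 2L, attention_reduction = 3L,
             head_stride = 2L, pool = 4L)
}

#' Desk-scale training configuration
#'
#' Batch 16 and 30 epochs with Adam at 3e-4; loss
#' weighting, augmentation and min-train-loss checkpointing as in
#' [train_config()].
#'
#' @param seed training seed.
#' @param epochs,batch_size,learning_rate overridable schedule knobs.
#' @return A [train_config()].
#' @export
desk_train_config <- function(seed = 1L, epochs = 30L, batch_size = 16L,
                              learning_rate = 3e-4) {
  train_config(learning_rate = learning_rate, batch_size = batch_size,
               epochs = epochs, seed = seed)
}

#' One fusion-benefit run: prior-informed vs image-only network
#'
#' Generates a synthetic cohort with the default planted clinical effects,
#' splits it 7:3 stratified, trains the desk-scale fusion network and its
#' image-only ablation with identical schedules, fits the
#' clinico-radiological logistic baseline, and scores everything on the
#' validation split.
#'
#' @param seed master seed; drives cohort generation, the split and
#'   training.
#' @param n_cases cohort size.
#' @param epochs,batch_size,learning_rate training schedule.
#' @return List with validation AUCs (`auc_pcmm`, `auc_mm`,
#'   `auc_clinical`), the validation `scores` and `labels`, and the
#'   fitted objects.
#' @export
run_fusion_experiment <- function(seed = 1L, n_cases = 300L, epochs = 30L,
                                  batch_size = 16L, learning_rate = 3e-4) {
  spec <- cohort_spec(n_cases = n_cases, seed = seed)
  ds <- simulate_patch_dataset(spec)
  sp <- stratified_split(ds$labels, 0.7, seed = seed + 1L)
  tr <- sp$train; va <- sp$validation
  tcfg <- desk_train_config(seed = seed + 2L, epochs = epochs,
                            batch_size = batch_size,
                            learning_rate = learning_rate)
  fit_p <- pcmm_fit(ds$images[, , , , tr, drop = FALSE],
                    ds$features[tr, , drop = FALSE], ds$labels[tr],
                    net = desk_net_config("pcmm"), train = tcfg)
  fit_m <- pcmm_fit(ds$images[, , , , tr, drop = FALSE], labels = ds$labels[tr],
                    net = desk_net_config("mm"), train = tcfg)
  clin <- clinical_model(ds$features[tr, , drop = FALSE], ds$labels[tr])
  scores <- list(
    clinical = predict(clin, ds$features[va, , drop = FALSE]),
    mm = predict(fit_m, ds$images[, , , , va, drop = FALSE]),
    pcmm = predict(fit_p, ds$images[, , , , va, drop = FALSE],
                   ds$features[va, , drop = FALSE])
  )
  labels <- ds$labels[va]
  list(auc_pcmm = compute_roc_auc(scores$pcmm, labels)$auc,
       auc_mm = compute_roc_auc(scores$mm, labels)$auc,
       auc_clinical = compute_roc_auc(scores$clinical, labels)$auc,
       scores = scores, labels = labels,
       fits = list(pcmm = fit_p, mm = fit_m, clinical = clin))
}

#' Fusion benefit over several seeds
#'
#' Repeats [run_fusion_experiment()] over independent seeds and reports
#' per-seed and mean validation AUCs of the fusion network, its
#' image-only ablation and the clinical baseline.
#'
#' @param seeds integer vector of seeds.
#' @param ... passed to [run_fusion_experiment()].
#' @return data.frame with one row per seed plus attribute `"means"`.
#' @export
fusion_benefit <- function(seeds = 1:5, ...) {
  rows <- lapply(seeds, function(s) {
    r <- run_fusion_experiment(seed = s, ...)
    data.frame(seed = s, auc_pcmm = r$auc_pcmm, auc_mm = r$auc_mm,
               auc_clinical = r$auc_clinical)
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- colMeans(out[, -1])
  out
}
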