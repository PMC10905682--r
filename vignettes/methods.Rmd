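---
title: "Prior-informed multi-modal 3D networks for LVI prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-informed multi-modal 3D networks for LVI prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

Lymphovascular invasion (LVI) is a binary histopathological finding that
is only available after surgery, yet it influences the choice between
breast-conserving surgery and mastectomy. The inputs available before
surgery are (i) three co-registered MR volumes of the lesion
(T1-weighted, T2-weighted, contrast-enhanced T1), and (ii) the
radiologist's structured reading of the study — sixteen
clinico-radiological covariates ranging from binary signs (peritumoral
edema, DWI rim sign, adjacent vessel sign, MRI-reported axillary node
involvement, ...) over ordinal BI-RADS-style descriptors (TIC curve
type 1–3, fibroglandular tissue density 1–4, background parenchymal
enhancement 1–4, internal enhancement pattern 1–3) to continuous
measurements (age in years, axillary-node short-axis diameter in cm).

`pcmmnet` implements four models for this problem and the machinery to
compare them:

1. **Clinico-radiological logistic model.** Univariate logistic
   regression of LVI on each covariate; covariates with Wald p < 0.1
   enter a joint multivariate logistic model whose predicted
   probabilities are the risk score.
2. **Radiomics chain.** Given a precomputed quantitative feature table,
   the score is built by z-score normalisation (training statistics),
   a univariate filter at p < 0.01, greedy correlation pruning at
   |r| ≥ 0.90, and an L1-penalised logistic model with λ at the
   minimum of the 5-fold cross-validated deviance. Feature extraction
   itself (shape, intensity, texture formulas) is out of scope.
3. **MM-Net.** A compact 3D residual channel-attention CNN on the three
   32³ image patches alone.
4. **PCMM-Net.** The same backbone on a 19-channel input: the three
   patches plus sixteen *constant-filled planes*, one per prior
   covariate. The fusion happens at the input, not at the classifier
   head, so convolution, batch normalisation and channel attention all
   see the priors as ordinary channels.

## Architecture

The backbone is: head block — 3³ convolution (`in_channels` → 64,
stride 1), channel-wise 3D batch normalisation, ReLU, factor-2 max
pooling; body — four residual channel-attention blocks at constant
width, each computing `y = x + CA(conv(ReLU(conv(x))))` with 3³ kernels
where `CA` is a squeeze-and-excitation gate (global average pooling to
a channel descriptor, a two-layer MLP with reduction 8 and ReLU hidden
activation, sigmoid output in (0,1), per-channel rescaling); tail —
global average pooling followed by a linear map to two logits and
softmax. A 1³ convolution before pooling and a linear layer after
pooling are the same operator; the implementation uses the latter.

Everything is trained from scratch: no pretraining, no transfer. The
published schedule is the default: Adam (β = 0.9/0.999, no weight
decay), learning rate 1e-4, batch size 48, 100 epochs, random flips
along the three spatial axes each epoch, cross-entropy with class
coefficients 0.25 (LVI-negative) and 0.75 (LVI-positive), and the
final model taken at the epoch of least *training* loss (ties to the
earlier epoch). Validation-loss checkpointing is available
(`checkpoint_rule = "min_val_loss"`) because train-loss selection
invites overfitting, but it is never substituted silently.

Because no deep-learning runtime is available to R in this setting —
and because the network *is* the contribution — the forward and
backward passes are written in this package: im2col + single-precision
BLAS gemm kernels for the 3D convolutions (Rcpp/RcppArmadillo), an
analytic backward pass through batch normalisation, max pooling,
channel attention and the residual topology, and Adam in R. Two
implementation details are worth knowing:

* **Fused constant-plane head.** Convolving a spatially constant plane
  reduces to the plane value times a partial sum of kernel taps that
  depends only on the voxel's border class (interior, face, edge,
  corner). The head convolution therefore splits into a dense 3-channel
  image convolution plus a cheap per-class correction for the 16 prior
  channels. A test asserts bit-level (to single precision) equality
  with the dense 19-channel convolution.
* **Precision.** Kernels compute in single precision; parameters,
  gradients and the optimizer state stay in double precision. Gradient
  correctness is checked against central finite differences.

### Initialisation

Convolutions are He-normal. Two places start at zero, both to make the
initial network a simpler submodel whose complexity is recruited by
gradients rather than imposed by random weights: the second convolution
of each RCAB together with the attention output layer (so every
residual block starts as the identity), and the head kernels acting on
the prior planes (so the fusion network starts as its own image-only
ablation). The second choice matters in the small-sample regime: with
random prior kernels every case receives a random per-channel constant
shift at initialisation, which the optimizer must first unlearn, and
which we observed to slow the recruitment of the prior information
relative to memorisation of the image content.

## Preprocessing contract

* Intensities: negatives clipped to zero, then division by the
  whole-volume maximum — normalisation happens *before* cropping, so
  patch intensities stay anchored to the volume scale. A test documents
  that the two orders differ and fixes this one.
* Patches: 32³ voxels cropped at the VOI center with a half-open
  window; out-of-volume voxels are zero-filled (zero = background after
  normalisation). "32 mm" and "32 voxels" are identified under a 1 mm
  isotropic resampling convention.
* Prior features: training-set min–max scaling to [0,1], clipped on
  validation data, constants mapping to 0. This puts the prior planes
  on the image intensity scale so that attention sees commensurate
  channels. Multi-level descriptors enter as single ordinal channels —
  the fixed 16-plane layout leaves no room for one-hot coding.
* Split: stratified 7:3 with a seeded draw. The per-stratum validation
  count is `floor(0.3 n_s)` by default (remainder to training); a
  largest-remainder rule is available. Published realized counts are
  treated as one random realization, not a constraint.
* Augmentation: each axis flipped independently with probability 1/2,
  identically across channels; constant planes are invariant, so
  augmentation regularises only the image branch.

## Statistical conventions

* Logistic models use Wald confidence intervals and p-values —
  symmetric on the log-odds scale, matching the reporting style of the
  published tables. For a binary covariate the univariate OR is
  algebraically the 2×2 cross-product ratio; tests assert this to
  1e-6 relative accuracy.
* Complete separation is flagged (`separation = TRUE`, or an error in
  the multivariate fit), never silently estimated.
* No multiple-testing correction anywhere in the selection chains; the
  modelled procedure applies none.
* Correlation kind in pruning: Pearson when both columns pass a
  Shapiro–Wilk screen at p > 0.05, Spearman otherwise; the choice is
  recorded per removal. Pruning scans features in ascending univariate
  p so the more label-associated member of a redundant pair survives.
* ROC/AUC: Mann–Whitney with midrank ties; the trapezoidal area under
  the curve equals it to 1e-12 by construction (tested). Operating
  points use Youden's J with ties resolved toward the lower (more
  sensitive) threshold; the source never states how its operating
  thresholds were chosen, so this convention is ours and is documented.
* DeLong: placement-value covariance estimate, two-sided normal
  reference. Identical score vectors give a degenerate zero-variance
  comparison reported as p = 1 with a flag. Tests compare the variance
  against a 2000-replicate bootstrap (ratio within [0.7, 1.4] on n = 60)
  and the type-I rate against its nominal 5% (within [4.1%, 6.0%] over
  2000 null replicates), and cross-check p-values against an
  independent library implementation.

## The synthetic cohort generator

No public data set carries this combination of LVI labels, three
co-registered modalities and the sixteen priors, so the package ships a
generator whose planted structure makes every downstream stage
verifiable:

* **Features** are drawn independently per patient from the published
  training-cohort marginals (n = 239): level proportions for the
  fourteen categorical covariates; age ~ Normal(52, 9) truncated to
  [25, 85] years; node short-axis ~ Gamma(shape 2) with median matched
  to 0.5 cm. The source reports only marginals, so no inter-feature
  correlation is modelled (a correlation hook would be a
  straightforward extension).
* **Labels** follow a logistic model with planted log odds-ratios —
  log 7.5 on peritumoral edema, log 4.3 on the DWI rim sign, log 2.1
  on the adjacent vessel sign, zero elsewhere — with the intercept
  calibrated by monotone root search so the mean predicted probability
  over the sampled table equals the 24.7% target prevalence to 1e-6.
* **Volumes** (default 40³ voxels) contain one soft-edged ellipsoidal
  lesion (semi-axes 5–8 voxels) with modality-specific additive
  contrast (1.0 / 0.8 / 1.2 intensity units), plus two image-borne
  signs rendered iff the corresponding *feature* (not the label) is
  set: a bright shell on modality 3 emulating the DWI rim sign
  (amplitude 0.3) and a peri-lesional halo on modality 2 emulating
  peritumoral edema (amplitude 0.25). Gaussian noise (sd 0.3) is added
  and negatives are clipped. One master seed fans out to per-case
  substreams (offset by case index) so cohorts are extensible without
  reshuffling, and identical specs give byte-identical outputs.

Under this design the information accessible through the images is a
strict subset of the information in the priors: the images can reveal
edema and rim status (structural Bayes AUC ≈ 0.77 given the planted
effects and marginals), while the priors additionally carry the
adjacent-vessel effect (clinical Bayes bound ≈ 0.79). The sign
amplitudes are chosen so the per-voxel contrast-to-noise ratio is about
one: an ideal observer that knows the lesion geometry still detects the
signs reliably (the image-borne Bayes AUC stays ≈ 0.75), but a small
CNN estimating everything from 210 training cases operates far from
that bound. This is the regime the fusion architecture is designed
for — the prior channels deliver losslessly what the image branch can
only estimate noisily — and it is what the fusion-benefit experiment
measures.

What the generator does **not** emulate: breast anatomy, scanner
physics, partial-volume and bias fields, inter-feature correlation,
reader disagreement. Passing tests therefore demonstrate correctness of
the machinery and the qualitative fusion behaviour, not clinical
performance; the published real-data AUCs (private 341-patient cohort)
are out of reach by construction.

## Desk-scale experiment configuration

The published configuration (64 channels, four RCABs, full-resolution
head, lr 1e-4, batch 48, 100 epochs) is impractical for a CPU-only
test suite, so comparative experiments use a reduced instance of the
same topology, exposed as `desk_net_config()` / `desk_train_config()`:
6 head channels, stride-2 head convolution, factor-4 pooling (body at
4³), two RCABs with attention reduction 3, Adam at 3e-4, batch 16, 30
epochs. The learning rate and capacity were chosen from training-loss
convergence diagnostics: with 420 optimizer steps, larger steps
(≥ 1e-3) drive the network deep into memorisation — per-epoch
validation AUC peaks within the first epochs and then decays while the
training loss keeps falling, which interacts badly with the
min-train-loss checkpoint rule — whereas 3e-4 reaches the convergence
elbow near epoch 30. The experiment sizes are: cohorts of n = 300
(210 training / 90 validation), five seeds, identical schedules for
the fusion network and its image-only ablation.

## Numerical choices and degenerate inputs

* Cross-entropy probabilities are clamped at 1e-12 before the log.
* Batch-normalisation uses ε = 1e-5 and running statistics with
  momentum 0.1, frozen at inference.
* The intercept calibration brackets the root in [−40, 40] log-odds
  and refuses unattainable targets (0 or 1).
* All-zero volumes normalise to all-zero; constant features scale to 0;
  zero-variance radiomics columns are dropped with a warning.
* Checkpoint ties break toward the earlier epoch; Youden ties toward
  the lower threshold; the correlation-prune scan is deterministic
  given the p-value ordering.
* Non-finite training loss aborts with diagnostics (epoch, learning
  rate, batch statistics) rather than continuing.

## Known limitations

* The multivariate odds ratios printed in the source (1.401 and 1.193
  for edema and rim) are inconsistent with any standard covariate
  coding given the univariate ORs (7.5 and 4.3) from the same counts;
  the package reports standard adjusted ORs and makes no attempt to
  match those two printed values.
* Which three acquisitions constitute the "three modalities" is
  ambiguous in the source (three-phase post-contrast DCE vs
  T1/T2/cT1); the pipeline is modality-agnostic over any three
  co-registered volumes.
* Batch-normalisation statistics at batch size 16 are noisy; the
  running averages used at inference partially smooth this but small
  batches remain a variance source in the desk-scale runs.
* The generator's independence of features and the stylised lesion
  geometry make the synthetic task easier to calibrate than real data;
  transfer of the measured fusion benefit to a clinical cohort is an
  empirical question this package cannot answer.
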