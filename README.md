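# pcmmnet

Preoperative knowledge of lymphovascular invasion (LVI) changes surgical
planning in early breast cancer, but LVI is confirmed only on the
resected specimen. `pcmmnet` implements a deep-learning framework that
predicts LVI before surgery from multi-parametric breast MRI *and* the
radiologist's prior reading of the study: sixteen clinico-radiological
covariates (peritumoral edema, DWI rim sign, adjacent vessel sign,
BI-RADS-style descriptors, age, nodal measurements, ...) are injected
into a 3D convolutional network as **constant-filled image channels**,
fused with three co-registered 32×32×32 lesion patches into a 19-channel
input. The package is aimed at methods researchers in medical image
analysis who want a fully inspectable, CPU-only reference implementation
of this fusion strategy together with the baselines it is usually
compared against.

## What is implemented

* **PCMM-Net** — the prior-informed fusion network: a head block
  (3³ convolution raising 19 → 64 channels, 3D batch normalisation,
  ReLU, max pooling), four 3D residual channel-attention blocks (RCAB:
  conv → ReLU → conv → squeeze-and-excitation channel gate → skip), and
  a tail (global average pooling, linear layer, softmax LVI risk). The
  forward and backward passes, Adam, and the class-weighted
  cross-entropy loss (coefficients 0.25 / 0.75 against the ~1:3 class
  imbalance) are implemented from first principles with
  Rcpp/RcppArmadillo kernels; no external deep-learning runtime is used.
* **MM-Net** — the matched image-only ablation (3 input channels).
* **Clinico-radiological baseline** — univariate logistic screening at
  p < 0.1 followed by a multivariate logistic model
  (`clinical_model()`).
* **Radiomics selection chain** — z-score normalisation, univariate
  filter at p < 0.01, greedy correlation pruning at |r| ≥ 0.90, LASSO
  with 5-fold cross-validated λ (`radiomics_model()`; feature
  *extraction* is out of scope — the chain consumes a precomputed
  table).
* **Evaluation stack** — ROC/AUC by the Mann–Whitney formulation,
  Youden-threshold operating points, and the DeLong test for paired
  correlated AUCs (`compute_roc_auc()`, `metrics_at_youden()`,
  `delong_test()`, `compare_models_report()`).
* **Synthetic cohort generator** — three-modality volumes with an
  ellipsoidal lesion, a DWI-rim-like bright shell and a peritumoral
  halo rendered when the corresponding binary covariates are set, and
  labels drawn from a logistic model with planted effects (odds ratios
  7.5 for edema, 4.3 for the rim sign, 2.1 for the adjacent vessel
  sign) calibrated to 24.7% prevalence. Everything downstream can
  therefore be verified against known ground truth.

The published per-level clinical count table ships as
`inst/extdata/table1_counts.csv` and is the input for the
odds-ratio and variable-selection reproductions.

## Worked example

Refit the univariate logistic model for peritumoral edema from the
published 2×2 counts (143/37 absent/present among LVI-negative, 20/39
among LVI-positive):

```r
library(pcmmnet)
counts <- lvi_table1_counts()
d <- expand_counts(counts, "peritumoral_edema")
fit_univariate_logistic(d$x, d$y)
#>   coefficient    se odds_ratio ci_lower ci_upper  p_value separation
#> 1        2.02 0.331       7.54     3.94     14.4 1.07e-09   FALSE
```

The odds ratio 7.54 (95% CI 3.94–14.4) reproduces the published
7.5 (3.9–14) for this covariate; the cross-product ratio
(39·143)/(37·20) gives the same value, as it must for a single binary
covariate.

Run one desk-scale fusion experiment on a synthetic cohort of 300
(stratified 7:3 split, batch 16, 30 epochs — a few minutes on one CPU):

```r
res <- run_fusion_experiment(seed = 1)
compare_models_report(res$scores, res$labels, reference = "pcmm")
#> model comparison (DeLong reference: pcmm)
#>     model    auc accuracy sensitivity specificity p_vs_reference
#>  clinical 0.7885   0.7978      0.6957      0.8333         0.8430
#>        mm 0.5079   0.5730      0.6087      0.5606         0.0016
#>      pcmm 0.7839   0.7865      0.7391      0.8030             NA
```

On this cohort the fusion network (`pcmm`, validation AUC 0.78)
clearly beats its image-only ablation (`mm`, 0.51; DeLong p = 0.0016)
and matches the clinical logistic baseline, which is the expected
behaviour when the planted image signs are noise-limited while the same
information is available losslessly through the prior channels. Means
over seeds vary; `fusion_benefit(seeds = 1:5)` reports the per-seed and
mean AUCs.

A thin command-line front end is installed at `inst/cli/pcmm`
(`simulate`, `train`, `evaluate` subcommands) for driving the same
pipeline from a shell.

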