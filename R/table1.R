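#' Published clinico-radiological count table
#'
#' Per-level counts of the 14 categorical clinico-radiological covariates in
#' an LVI training cohort of 239 breast-cancer patients (180 LVI-negative,
#' 59 LVI-positive), as reported in the study this package models.  Binary
#' variables are coded 0/1 and multi-level descriptors (TIC curve type, FGT
#' density, BPE, internal enhancement pattern) ordinally 1..k.  The two
#' continuous covariates (age, ALN short-axis diameter) are summarised in
#' the source only by quantiles and are therefore not part of this table.
#'
#' @return A data.frame with columns `variable`, `level`, `code`,
#'   `lvi_neg`, `lvi_pos`.
#' @export
lvi_table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.csv", package = "pcmmnet")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Expand a count table into per-patient rows
#'
#' Reconstructs an analysable per-patient data set (one covariate at a time)
#' from grouped counts: each (level, class) cell becomes `count` identical
#' rows.  Used to refit univariate logistic models against published
#' aggregate tables.
#'
#' @param counts data.frame as returned by [lvi_table1_counts()].
#' @param variable name of one variable in `counts`.
#' @return data.frame with columns `x` (numeric code) and `y` (0/1 label).
#' @export
expand_counts <- function(counts, variable) {
  sub <- counts[counts$variable == variable, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown variable: ", variable)
  x <- rep(sub$code, times = sub$lvi_neg + sub$lvi_pos)
  y <- unlist(lapply(seq_len(nrow(sub)), function(i) {
    c(rep(0L, sub$lvi_neg[i]), rep(1L, sub$lvi_pos[i]))
  }))
  data.frame(x = as.numeric(x), y = as.integer(y))
}

#' Marginal distributions of the 16 prior clinico-radiological features
#'
#' Default sampling marginals for the synthetic cohort generator, taken from
#' the published training-cohort totals (n = 239).  Categorical variables
#' use the observed level proportions; age is truncated-normal(52, 9) on
#' [25, 85] and the ALN short-axis diameter is Gamma with median matched to
#' the published 0.5 cm.
#'
#' @return Named list, one element per feature: for categorical features a
#'   list with `type` ("binary"/"ordinal"), `levels` and `prob`; for
#'   continuous features a list with `type = "continuous"` and a `sample`
#'   function.
#' @export
table1_marginals <- function() {
  counts <- lvi_table1_counts()
  marg <- list()
  for (v in unique(counts$variable)) {
    sub <- counts[counts$variable == v, ]
    tot <- sub$lvi_neg + sub$lvi_pos
    marg[[v]] <- list(
      type = if (all(sub$code %in% c(0, 1))) "binary" else "ordinal",
      levels = sub$code,
      prob = tot / sum(tot)
    )
  }
  marg$age <- list(
    type = "continuous",
    sample = function(n) {
      x <- rnorm(n, mean = 52, sd = 9)
      pmin(pmax(x, 25), 85)
    }
  )
  # shape 2 gamma: median ~ shape - 1/3 scale units; scale set so median = 0.5 cm
  marg$aln_short_axis <- list(
    type = "continuous",
    sample = function(n) rgamma(n, shape = 2, scale = 0.5 / 1.678)
  )
  marg[prior_feature_names()]
}
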