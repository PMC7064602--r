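#' Fraction of predicted HLA binders among peptides
#'
#' Peptides whose external binding-predictor p-value is at or below the
#' threshold (default 0.05, inclusive) count as binders. The fraction of
#' binders is a plausibility check on an identification list: true HLA
#' ligands are overwhelmingly predicted binders.
#'
#' @param annotations data frame with a `binder_pvalue` column in `[0, 1]`.
#' @param threshold inclusive p-value cutoff.
#' @return fraction in `[0, 1]`; 0 with a warning for empty input.
#' @export
binder_fraction <- function(annotations, threshold = 0.05) {
  p <- annotations$binder_pvalue
  if (length(p) == 0) {
    warning("no peptides; binder fraction defined as 0")
    return(0)
  }
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop_validation("binder p-values must lie in [0, 1]")
  mean(p <= threshold)
}

#' Regress observed retention times on calculated hydrophobicity indices
#'
#' Ordinary least squares of mean retention time (minutes) on the
#' sequence-specific hydrophobicity index (%ACN) over unmodified
#' peptides. The residual standard error and the absolute residuals
#' quantify how well the external HI predictions agree with observation
#' — larger errors indicate lower-confidence identification sets.
#'
#' @param annotations data frame with `hi` and `rt_mean` columns.
#' @return list with `slope`, `intercept`, `residuals`,
#'   `abs_residuals`, `residual_se` (sqrt of RSS / (n - 2)), `n`.
#' @export
rt_hi_regression <- function(annotations) {
  ok <- is.finite(annotations$hi) & is.finite(annotations$rt_mean)
  hi <- annotations$hi[ok]
  rt <- annotations$rt_mean[ok]
  if (length(hi) < 3)
    stop_validation("need at least 3 peptides with both HI and RT")
  if (stats::var(hi) == 0)
    stop_validation("zero variance in HI; regression undefined")
  fit <- stats::lm(rt ~ hi)
  res <- unname(stats::residuals(fit))
  n <- length(res)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = res,
       abs_residuals = abs(res),
       residual_se = sqrt(sum(res^2) / (n - 2)),
       n = n)
}

#' One-sided F-test comparing residual variances
#'
#' Tests whether set A (hypothesized noisier, e.g. single-tool
#' identifications) has larger variance than set B (e.g. the combined
#' high-confidence set): `F = var(A)/var(B)` with `(nA - 1, nB - 1)`
#' degrees of freedom, p-value from the upper tail.
#'
#' @param residualsA,residualsB numeric vectors (length >= 2); A is the
#'   putatively noisier set.
#' @return list with `f_statistic`, `p_value`, `df` and
#'   `infinite_f` flag (`TRUE` when B has zero variance, reported as
#'   F = Inf, p = 0).
#' @export
variance_f_test <- function(residualsA, residualsB) {
  nA <- length(residualsA)
  nB <- length(residualsB)
  if (nA < 2 || nB < 2)
    stop_validation("each residual set needs at least 2 values")
  vA <- stats::var(residualsA)
  vB <- stats::var(residualsB)
  if (vB == 0) {
    warning("zero variance in denominator set; F is infinite")
    return(list(f_statistic = Inf, p_value = 0,
                df = c(nA - 1L, nB - 1L), infinite_f = TRUE))
  }
  f <- vA / vB
  list(f_statistic = f,
       p_value = stats::pf(f, nA - 1, nB - 1, lower.tail = FALSE),
       df = c(nA - 1L, nB - 1L), infinite_f = FALSE)
}

#' Read a per-peptide annotation table
#'
#' TSV with columns `peptide`, `binder_pvalue`, `hi`, `rt_mean`
#' (external predictor outputs: HLA-binding p-value, hydrophobicity
#' index in %ACN, mean observed retention time in minutes; when a peptide
#' is observed several times the mean RT is expected upstream).
#'
#' @param path TSV path.
#' @export
read_peptide_annotations <- function(path) {
  if (!file.exists(path)) stop_validation("annotation table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("peptide", "binder_pvalue", "hi", "rt_mean"))
    if (!col %in% names(df))
      stop_validation("annotation table is missing column '", col, "'")
  df
}

#' QC report over an identification list
#'
#' Computes the binder fraction and the RT~HI regression per peptide
#' class, and the one-sided F-test of a comparison set's residuals
#' against the reference set's.
#'
#' @param annotations data frame as in [read_peptide_annotations()],
#'   optionally with a `group` column.
#' @param comparison optional second annotation set hypothesized to be
#'   noisier than `annotations`.
#' @param binder_threshold passed to [binder_fraction()].
#' @return list with `binder_fraction`, `regression`, and (when
#'   `comparison` is given) `f_test`.
#' @export
qc_report <- function(annotations, comparison = NULL,
                      binder_threshold = 0.05) {
  out <- list(
    binder_fraction = binder_fraction(annotations, binder_threshold),
    regression = rt_hi_regression(annotations))
  if (!is.null(comparison)) {
    reg_cmp <- rt_hi_regression(comparison)
    out$comparison_regression <- reg_cmp
    out$f_test <- variance_f_test(reg_cmp$residuals,
                                  out$regression$residuals)
  }
  out
}
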