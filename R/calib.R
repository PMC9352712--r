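#' Fold change in sgRNA counts implied by a regression coefficient
#'
#' NB regressions act on the log scale, so a coefficient beta corresponds to
#' an `exp(beta)`-fold change in counts (e.g. -0.0396 -> 0.96-fold, a 4%
#' count decrease). Summaries round to 2 decimals; full precision is
#' retained in the return value.
#'
#' @param beta regression coefficient(s).
#' @return `exp(beta)`.
#' @export
countFoldChange <- function(beta) exp(beta)

#' Copy-number-equivalent ploidy units for a feature effect
#'
#' Expresses a feature's toxicity coefficient in units of local ploidy
#' increase, using the known toxic effect of copy-number-amplified loci as
#' the measuring stick. The copy-number regression contrast spans a
#' `cn_ratio`-fold ploidy difference (default 2.9, the ratio of the mean CN
#' score of the high and reference levels), so by rule-of-three the feature
#' corresponds to targeting a region with a
#' `cn_ratio * beta_feature / beta_cn`-fold local increase in ploidy.
#' Summaries round to 1 decimal.
#'
#' @param beta_feature feature coefficient(s).
#' @param beta_cn copy-number coefficient (non-zero).
#' @param cn_ratio ploidy fold difference spanned by the CN contrast.
#' @return fold-ploidy equivalent(s), full precision.
#' @export
ploidyEquivalent <- function(beta_feature, beta_cn, cn_ratio = 2.9) {
    if (!is.finite(beta_cn) || beta_cn == 0)
        stop("beta_cn must be non-zero to calibrate against copy number")
    if (cn_ratio <= 0) stop("cn_ratio must be > 0")
    cn_ratio * beta_feature / beta_cn
}

#' Ploidy ratio spanned by the binarized copy-number contrast
#'
#' @param mean_cn_reference mean CN score of the reference (low) level.
#' @param mean_cn_high mean CN score of the high level.
#' @return `mean_cn_high / mean_cn_reference` (e.g. 2.0 / 0.7 = 2.9).
#' @export
cnLevelRatio <- function(mean_cn_reference, mean_cn_high) {
    if (mean_cn_reference <= 0) stop("reference CN must be > 0")
    mean_cn_high / mean_cn_reference
}

#' Calibration table of feature effects in ploidy units
#'
#' @param betas named numeric vector of feature coefficients.
#' @param beta_cn copy-number coefficient.
#' @param cn_ratio see [ploidyEquivalent()].
#' @return data.frame with `feature`, `beta_feature`, `beta_cn`, `cn_ratio`,
#'   `count_fold_change` (2 dp) and `fold_ploidy` (1 dp); full-precision
#'   columns `count_fold_change_full`, `fold_ploidy_full` retained.
#' @export
ploidyCalibrationTable <- function(betas, beta_cn, cn_ratio = 2.9) {
    fp <- ploidyEquivalent(betas, beta_cn, cn_ratio)
    fc <- countFoldChange(betas)
    data.frame(feature = names(betas), beta_feature = unname(betas),
               beta_cn = beta_cn, cn_ratio = cn_ratio,
               count_fold_change = round(unname(fc), 2L),
               fold_ploidy = round(unname(fp), 1L),
               count_fold_change_full = unname(fc),
               fold_ploidy_full = unname(fp))
}

#' Example linear p53-toxicity score for sgRNA designs
#'
#' A configurable linear score ranking candidate cut sites by predicted
#' p53-dependent toxicity: the weighted sum of the locus covariates, with
#' default weights equal to the negated genotype-interaction coefficients
#' (so that higher score = more predicted toxicity). This is an example
#' score -- a documented reconstruction, not a trained classifier.
#'
#' @param feature_matrix numeric matrix or data.frame, sgRNAs x covariates
#'   (row names = sgRNA ids).
#' @param weights named numeric weights covering every covariate column;
#'   covariates with missing values are an error unless `na_zero = TRUE`.
#' @param na_zero treat missing covariate values as 0 instead of failing.
#' @return data.frame with `sgrna_id`, `score` and `percentile` (rank
#'   percentile of the score within the supplied library, in [0, 1]).
#' @export
scoreSgRNA <- function(feature_matrix, weights, na_zero = FALSE) {
    fm <- as.matrix(feature_matrix)
    miss <- setdiff(colnames(fm), names(weights))
    if (length(miss))
        stop("no weight for covariate(s): ", paste(miss, collapse = ", "))
    if (anyNA(fm)) {
        if (!na_zero)
            stop("missing covariate values; set na_zero = TRUE to impute 0")
        fm[is.na(fm)] <- 0
    }
    w <- weights[colnames(fm)]
    score <- drop(fm %*% w)
    data.frame(sgrna_id = rownames(fm), score = unname(score),
               percentile = (rank(score, ties.method = "average") - 0.5) /
                   length(score))
}

#' Default score weights from fitted interaction coefficients
#'
#' Averages each feature's interaction coefficient across fits (e.g. the
#' per-pseudo-replicate fits) and negates it, so features that increase
#' p53 toxicity get positive weight.
#'
#' @param fits list of [NBFit-class] objects; each `model_id` should name
#'   the feature (fits of the same feature across pseudo-replicates are
#'   averaged).
#' @return named numeric vector of weights.
#' @export
scoreWeightsFromFits <- function(fits) {
    est <- vapply(fits, function(f) termEstimate(f)$estimate, numeric(1L))
    ids <- vapply(fits, function(f) f@model_id, "")
    -tapply(est, ids, mean)[unique(ids)]
}
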