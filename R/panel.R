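#' Per-sgRNA TP53 effect sizes across a cell-line panel
#'
#' Compares each sgRNA's log2 fold counts between TP53 wild-type and
#' TP53-mutant cell lines. The effect size is Cohen's d with pooled SD
#' (wild type minus mutant), so negative values mean a worse effect on
#' fitness in TP53 wild-type lines; p-values are two-sided pooled-variance
#' t-tests, FDR-adjusted by Benjamini-Hochberg.
#'
#' @param lfc numeric matrix, sgRNAs x cell lines (log2 fold counts).
#' @param tp53_status character/factor per line, `"wt"` or `"mut"`.
#' @return data.frame with `sgrna_id`, `effect_size`, `p`, `fdr`, `n_wt`,
#'   `n_mut`; effect size is `NA` (flagged in `zero_sd`) when the pooled SD
#'   is zero.
#' @export
panelEffectSizes <- function(lfc, tp53_status) {
    lfc <- as.matrix(lfc)
    stopifnot(length(tp53_status) == ncol(lfc))
    wt <- tp53_status == "wt"; mut <- tp53_status == "mut"
    n1 <- sum(wt); n2 <- sum(mut)
    if (n1 < 2L || n2 < 2L)
        stop("need at least two wt and two mut cell lines")
    m1 <- rowMeans(lfc[, wt, drop = FALSE])
    m2 <- rowMeans(lfc[, mut, drop = FALSE])
    v1 <- apply(lfc[, wt, drop = FALSE], 1L, stats::var)
    v2 <- apply(lfc[, mut, drop = FALSE], 1L, stats::var)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    d <- (m1 - m2) / sp
    tstat <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
    zero <- !is.na(sp) & sp == 0
    d[zero] <- NA_real_; p[zero] <- NA_real_
    data.frame(sgrna_id = rownames(lfc), effect_size = unname(d),
               p = unname(p), fdr = stats::p.adjust(p, "BH"),
               n_wt = n1, n_mut = n2, zero_sd = unname(zero))
}

#' Call panel target and low-toxicity loci by effect size
#'
#' Target loci are sgRNAs with an effect size strictly below
#' `target_threshold` (worse fitness in TP53 wild type); the low-toxicity
#' control set has effect sizes strictly inside `control_band`. Thresholds
#' are unit-bound (standardized effect-size units); the two sets are
#' disjoint by construction.
#'
#' @param effects data.frame from [panelEffectSizes()].
#' @param target_threshold upper bound (exclusive) for targets
#'   (default -0.4).
#' @param control_band open interval for the low-toxicity set
#'   (default (-0.04, 0.04)).
#' @return list with `target` and `low_toxicity` sgRNA id vectors.
#' @export
callPanelLoci <- function(effects, target_threshold = -0.4,
                          control_band = c(-0.04, 0.04)) {
    d <- effects$effect_size
    ok <- !is.na(d)
    list(target = effects$sgrna_id[ok & d < target_threshold],
         low_toxicity = effects$sgrna_id[ok & d > control_band[1L] &
                                         d < control_band[2L]])
}

#' Prepare the cell-line-panel design for the HR models
#'
#' Builds the long model table for [fitTP53HR()] / [fitFeatureHR()]:
#' per-line offsets are the natural log of the summed counts over the known
#' non-essential genes, tissue enters as a categorical correcting variable
#' with breast as reference level, and lines missing a status or tissue are
#' dropped with a log entry (attribute `dropped`).
#'
#' @param counts numeric matrix, sgRNAs x cell lines (raw counts).
#' @param gene character vector per sgRNA (its gene).
#' @param tp53_status,hr_status per-line status, `"wt"`/`"mut"` (`NA`
#'   drops the line).
#' @param tissue per-line tissue label; a missing (NA) tissue is an error
#'   unless the line is already dropped for missing status.
#' @param nonessential gene symbols defining the offset reference set.
#' @param d2 per-sgRNA D2 essentiality covariate.
#' @param x optional per-sgRNA feature vector for the feature-by-HR model.
#' @param guides optional sgRNA ids restricting the model table to a locus
#'   set (e.g. panel target loci); offsets are always computed from the
#'   full count matrix.
#' @param reference_tissue reference level (default `"breast"`).
#' @return long data.frame with columns `sgrna_id`, `cell_line`, `count`,
#'   `tp53`, `hr`, `tissue`, `d2`, `off` (plus `x` when given); attribute
#'   `dropped` lists dropped lines with reasons, attribute `offsets` the
#'   per-line offsets.
#' @export
prepareHRDesign <- function(counts, gene, tp53_status, hr_status, tissue,
                            nonessential, d2, x = NULL, guides = NULL,
                            reference_tissue = "breast") {
    counts <- as.matrix(counts)
    stopifnot(length(gene) == nrow(counts),
              length(tp53_status) == ncol(counts),
              length(hr_status) == ncol(counts),
              length(tissue) == ncol(counts),
              length(d2) == nrow(counts))
    drop <- is.na(tp53_status) | is.na(hr_status)
    dropped <- data.frame(cell_line = colnames(counts)[drop],
                          reason = rep("missing TP53/HR status", sum(drop)))
    if (any(is.na(tissue[!drop])))
        stop("missing tissue for cell line ",
             colnames(counts)[!drop & is.na(tissue)][1L])
    keep <- which(!drop)
    ness <- toupper(gene) %in% toupper(nonessential)
    if (!any(ness)) stop("no sgRNA maps to the non-essential offset set")
    off <- log(colSums(counts[ness, keep, drop = FALSE]))
    tis <- factor(tissue[keep])
    if (reference_tissue %in% levels(tis))
        tis <- stats::relevel(tis, ref = reference_tissue)
    nl <- length(keep); ng <- nrow(counts)
    df <- data.frame(
        sgrna_id = rep(rownames(counts), times = nl),
        cell_line = rep(colnames(counts)[keep], each = ng),
        count = as.vector(counts[, keep, drop = FALSE]),
        tp53 = factor(rep(tp53_status[keep], each = ng),
                      levels = c("mut", "wt")),
        hr = factor(rep(hr_status[keep], each = ng),
                    levels = c("mut", "wt")),
        tissue = rep(tis, each = ng),
        d2 = rep(d2, times = nl),
        off = rep(off, each = ng))
    if (!is.null(x)) df$x <- rep(x, times = nl)
    if (!is.null(guides)) df <- df[df$sgrna_id %in% guides, , drop = FALSE]
    attr(df, "dropped") <- dropped
    attr(df, "offsets") <- stats::setNames(off, colnames(counts)[keep])
    df
}
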