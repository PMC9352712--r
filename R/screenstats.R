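#' Essentiality benchmark AUROC
#'
#' Area under the ROC curve for separating essential from non-essential
#' genes when genes are ranked by a score (here, mean normalized sgRNA
#' counts per gene: essential genes drop out, so lower counts should
#' indicate essentiality). Computed as the Mann-Whitney U statistic
#' normalized by n1 x n2, with ties counted 1/2 -- the probability that a
#' random essential gene ranks below (smaller score than) a random
#' non-essential gene.
#'
#' @param scores named numeric vector of per-gene scores (e.g. mean
#'   normalized counts).
#' @param essential,nonessential gene sets; intersected with the names of
#'   `scores`, both must remain non-empty.
#' @return AUROC in [0, 1].
#' @export
essentialityAUROC <- function(scores, essential, nonessential) {
    ess <- intersect(names(scores), essential)
    non <- intersect(names(scores), nonessential)
    if (!length(ess) || !length(non))
        stop("both gene classes must be non-empty after intersecting the ranking")
    x <- scores[ess]; y <- scores[non]
    r <- rank(c(x, y), ties.method = "average")
    n1 <- length(x); n2 <- length(y)
    # P(essential score < non-essential score), ties 1/2
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    1 - u / (n1 * n2)
}

#' Mean normalized count per gene
#'
#' @param se a normalized experiment.
#' @param samples sample ids to average over (default all).
#' @return named numeric vector over genes.
#' @export
geneMeanCounts <- function(se, samples = colnames(se)) {
    if (!isTRUE(metadata(se)$normalized))
        stop("normalize the counts first")
    norm <- SummarizedExperiment::assay(se, "normcounts")[, samples,
                                                          drop = FALSE]
    gene <- SummarizedExperiment::rowData(se)$gene
    keep <- !is.na(gene)
    m <- rowMeans(norm[keep, , drop = FALSE])
    tapply(m, gene[keep], mean)
}

#' Standardize gene scores within a condition
#'
#' `(x - mean) / SD` with the population (1/n) SD, so the standardized
#' scores have mean 0 and SD exactly 1; any averaging across later time
#' points and pseudo-replicates is done by the caller before standardizing.
#'
#' @param scores numeric vector (one condition).
#' @return z-scores with mean 0 and SD 1.
#' @export
zScore <- function(scores) {
    m <- mean(scores, na.rm = TRUE)
    s <- sqrt(mean((scores - m)^2, na.rm = TRUE))
    if (!is.finite(s) || s == 0)
        stop("cannot standardize a constant score vector (SD = 0)")
    (scores - mean(scores, na.rm = TRUE)) / s
}

#' EM clustering of control/treatment gene z-scores
#'
#' Gaussian-mixture EM on the 2-D (z_control, z_treatment) points with 1 to
#' `max_components` components, model selection by BIC. When the best model
#' has two components, the one with the lower mean treatment z-score is
#' labelled `selected` and the other `non_selected`; otherwise no selected
#' label is assigned. Deterministic given `seed` (seeded hierarchical/EM
#' initialization inside mclust).
#'
#' @param z_control,z_treatment per-gene z-scores.
#' @param max_components largest number of mixture components tried.
#' @param seed integer seed.
#' @importFrom mclust Mclust mclustBIC
#' @return list with `n_components`, `labels` (factor `selected` /
#'   `non_selected`, or `NULL` when best != 2), `classification` (component
#'   index per gene), `bic` (per tried G), `converged`.
#' @export
emTwoCluster <- function(z_control, z_treatment, max_components = 4L,
                         seed = 1L) {
    stopifnot(length(z_control) == length(z_treatment))
    if (length(z_control) < 20L) stop("need at least 20 genes to cluster")
    xy <- cbind(control = z_control, treatment = z_treatment)
    set.seed(as.integer(seed))
    mod <- Mclust(xy, G = seq_len(max_components), verbose = FALSE)
    if (is.null(mod)) stop("mixture model failed for every component count")
    labels <- NULL
    if (mod$G == 2L) {
        mu_t <- mod$parameters$mean["treatment", ]
        sel <- which.min(mu_t)
        labels <- factor(ifelse(mod$classification == sel, "selected",
                                "non_selected"),
                         levels = c("selected", "non_selected"))
    }
    list(n_components = mod$G, labels = labels,
         classification = mod$classification,
         bic = mod$BIC, converged = !is.na(mod$loglik))
}

#' Conditional-essentiality hit call
#'
#' A gene is a conditional hit when its control z-score is non-different
#' from 0, its treatment z-score is below 0, and the control-treatment
#' difference is also different from 0 -- all at `sd_threshold` standard
#' deviations: `|z_control| < t`, `z_treatment < -t`, and
#' `(z_treatment - z_control) / SD(diff) < -t`, where the difference is
#' standardized on its own SD (supply `diff_sd` to override, e.g. with a
#' pooled value).
#'
#' @param z_control,z_treatment per-gene z-scores.
#' @param sd_threshold significance threshold in SD units (default 2).
#' @param diff_sd SD used to standardize the difference; default
#'   `sd(z_treatment - z_control)`.
#' @return logical vector, `TRUE` = hit.
#' @export
conditionalHitCall <- function(z_control, z_treatment, sd_threshold = 2,
                               diff_sd = NULL) {
    d <- z_treatment - z_control
    if (is.null(diff_sd)) diff_sd <- stats::sd(d, na.rm = TRUE)
    if (!is.finite(diff_sd) || diff_sd <= 0)
        stop("difference SD must be positive")
    abs(z_control) < sd_threshold &
        z_treatment < -sd_threshold &
        d / diff_sd < -sd_threshold
}

#' Compare treatment-control fit residuals between genotypes
#'
#' Fits the ordinary least-squares line `z_treatment ~ z_control` separately
#' per genotype and reports each gene's residual; genes with a more negative
#' residual in one genotype show a higher degree of treatment-conditionality
#' there. The per-gene comparison is residual(ko) - residual(wt): negative
#' values mean stronger conditionality in the knockout.
#'
#' @param z_control,z_treatment named numeric vectors (gene per entry),
#'   concatenated over genotypes.
#' @param genotype factor/character aligned with the scores (`ko`/`wt`).
#' @return list with `residuals` (data.frame gene, genotype, residual,
#'   fitted), `fits` (per-genotype lm coefficients) and `comparison`
#'   (data.frame gene, residual_ko, residual_wt, diff_ko_minus_wt) for
#'   genes present in both genotypes.
#' @export
residualCompare <- function(z_control, z_treatment, genotype) {
    stopifnot(length(z_control) == length(z_treatment),
              length(genotype) == length(z_control))
    gene <- names(z_control)
    if (is.null(gene)) gene <- as.character(seq_along(z_control))
    out <- NULL; fits <- list()
    for (g in unique(as.character(genotype))) {
        i <- which(genotype == g)
        fit <- stats::lm(z_treatment[i] ~ z_control[i])
        fits[[g]] <- stats::coef(fit)
        out <- rbind(out, data.frame(gene = gene[i], genotype = g,
                                     residual = unname(stats::resid(fit)),
                                     fitted = unname(stats::fitted(fit))))
    }
    comparison <- NULL
    gs <- unique(as.character(genotype))
    if (all(c("ko", "wt") %in% gs)) {
        rk <- out[out$genotype == "ko", ]
        rw <- out[out$genotype == "wt", ]
        shared <- intersect(rk$gene, rw$gene)
        comparison <- data.frame(
            gene = shared,
            residual_ko = rk$residual[match(shared, rk$gene)],
            residual_wt = rw$residual[match(shared, rw$gene)])
        comparison$diff_ko_minus_wt <-
            comparison$residual_ko - comparison$residual_wt
    }
    list(residuals = out, fits = fits, comparison = comparison)
}

#' Hit-label permutation null for conditional hits
#'
#' Reshuffles the hit/non-hit gene labels independently within each
#' comparison column (preserving every column's hit count) and counts how
#' often at least `min_hits` genes are each a hit in at least `min_ko` of
#' the knockout comparisons while being a hit in at most `max_wt` of the
#' wild-type comparisons. With the study design of 12 comparisons (6
#' knockout, 6 wild type) and the >= 2 genes / >= 4 of 6 ko / 0 of 6 wt
#' rule, this approximates the probability that the observed pattern arises
#' by chance.
#'
#' @param hit_labels logical matrix, genes x comparisons.
#' @param is_ko logical vector per column, `TRUE` for knockout comparisons.
#' @param n_iter permutation iterations (default 1000).
#' @param min_hits minimum number of satisfying genes (default 2).
#' @param min_ko minimum ko comparisons a gene must be hit in (default 4).
#' @param max_wt maximum wt comparisons a gene may be hit in (default 0).
#' @param seed integer seed.
#' @return list with `n_iter`, `n_satisfying`, `frequency`, the rule
#'   parameters and `seed`. Column sums are asserted invariant in every
#'   iteration.
#' @export
permutationNull <- function(hit_labels, is_ko, n_iter = 1000L, min_hits = 2L,
                            min_ko = 4L, max_wt = 0L, seed = 1L) {
    hit_labels <- as.matrix(hit_labels)
    if (!is.logical(hit_labels)) stop("hit_labels must be logical")
    stopifnot(length(is_ko) == ncol(hit_labels))
    ng <- nrow(hit_labels)
    if (any(colSums(hit_labels) > ng))
        stop("column hit count exceeds the number of genes")
    set.seed(as.integer(seed))
    csums <- colSums(hit_labels)
    ko_cols <- which(is_ko); wt_cols <- which(!is_ko)
    n_sat <- 0L
    perm <- hit_labels
    for (it in seq_len(n_iter)) {
        for (j in seq_len(ncol(perm)))
            perm[, j] <- hit_labels[sample.int(ng), j]
        stopifnot(identical(colSums(perm), csums))  # labels only reshuffled
        nko <- rowSums(perm[, ko_cols, drop = FALSE])
        nwt <- if (length(wt_cols))
            rowSums(perm[, wt_cols, drop = FALSE]) else 0L
        if (sum(nko >= min_ko & nwt <= max_wt) >= min_hits)
            n_sat <- n_sat + 1L
    }
    list(n_iter = as.integer(n_iter), n_satisfying = n_sat,
         frequency = n_sat / n_iter,
         min_hits = as.integer(min_hits), min_ko = as.integer(min_ko),
         max_wt = as.integer(max_wt), seed = as.integer(seed))
}
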