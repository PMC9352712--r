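#' Bin a chromatin-mark abundance into absence / low / high
#'
#' Zero abundance is bin 0 (absence). Positive abundances are split at the
#' genome-size-weighted median of the positive territory into bin 1 and
#' bin 2, so that bins 1 and 2 cover equal total genome weight; values
#' exactly at the split go to the lower bin. Bin-1 sgRNAs are flagged in a
#' drop mask: single-feature regressions remove them to stress the contrast
#' between absence and clear abundance of a feature.
#'
#' When no genome-territory weights are available (synthetic data), equal
#' weights over the sgRNA universe preserve the 50/50 split semantics.
#'
#' @param abundance non-negative numeric vector (e.g. ChIP fold
#'   enrichment at each cut site).
#' @param weights optional positive genome-size weights, one per sgRNA.
#' @return list with `bin` (integer 0/1/2), `drop_mask` (logical, TRUE for
#'   bin 1) and `split` (the weighted median used; NA when no positives).
#' @export
binChromatin <- function(abundance, weights = NULL) {
    if (any(abundance < 0, na.rm = TRUE))
        stop("chromatin abundances must be non-negative")
    if (is.null(weights)) weights <- rep(1, length(abundance))
    stopifnot(length(weights) == length(abundance), all(weights > 0))
    bin <- integer(length(abundance))
    pos <- which(abundance > 0)
    split <- NA_real_
    if (length(pos)) {
        split <- .balancedSplit(abundance[pos], weights[pos])
        bin[pos] <- ifelse(abundance[pos] <= split, 1L, 2L)
    }
    bin[is.na(abundance)] <- NA_integer_
    list(bin = bin, drop_mask = !is.na(bin) & bin == 1L, split = split)
}

## split value minimizing the weight imbalance of {<= split} vs {> split};
## candidates are the two order statistics around half the total weight, so
## the imbalance never exceeds one element's weight
.balancedSplit <- function(x, w) {
    o <- order(x)
    xs <- x[o]
    cw <- cumsum(w[o])
    tot <- cw[length(cw)]
    k <- which(cw >= tot / 2)[1L]
    cand <- unique(c(if (k > 1L) xs[k - 1L], xs[k]))
    imb <- vapply(cand, function(s)
        abs(sum(w[x <= s]) - sum(w[x > s])), numeric(1L))
    cand[which.min(imb)]
}

#' Binarize copy-number bins
#'
#' Copy-number bins 1 (low) to 7 (high) are binarized into high (5-7)
#' versus low (1-4).
#'
#' @param cn_bin integer vector in 1..7.
#' @return logical vector, `TRUE` = high copy number.
#' @export
binarizeCN <- function(cn_bin) {
    if (any(!is.na(cn_bin) & (cn_bin < 1L | cn_bin > 7L)))
        stop("cn_bin must be in 1..7")
    cn_bin >= 5L
}

#' Binarize replication-timing bins
#'
#' Replication-timing bins run from 0 (no replication) to 6 (earliest);
#' they are binarized into early (6) versus late (1-5). Bin-0 sgRNAs are
#' dropped (`NA`), since gene regions are expected to replicate.
#'
#' @param rt_bin integer vector in 0..6.
#' @return logical vector, `TRUE` = early, `NA` = dropped (bin 0).
#' @export
binarizeRT <- function(rt_bin) {
    if (any(!is.na(rt_bin) & (rt_bin < 0L | rt_bin > 6L)))
        stop("rt_bin must be in 0..6")
    out <- rt_bin == 6L
    out[!is.na(rt_bin) & rt_bin == 0L] <- NA
    out
}

#' Split genes into short and long halves
#'
#' Genes longer than `max_length` (200 kb) are removed; the remainder is
#' split at the median length into two equally-sized bins (ties at the
#' median go to the lower, `short`, bin).
#'
#' @param lengths named numeric vector of gene lengths (bp).
#' @param max_length removal threshold (default 200,000 bp).
#' @return factor with levels `short`, `long` and `NA` for removed genes.
#' @export
geneLengthBins <- function(lengths, max_length = 2e5) {
    keep <- !is.na(lengths) & lengths <= max_length
    if (sum(keep) < 2L)
        stop("need at least two genes under ", max_length,
             " bp to split at the median")
    med <- stats::median(lengths[keep])
    out <- rep(NA_character_, length(lengths))
    out[keep] <- ifelse(lengths[keep] <= med, "short", "long")
    factor(out, levels = c("short", "long"))
}

#' Scale cut-to-5'-end distance to [0, 1]
#'
#' @param distance_bp distance of the DSB from the 5' gene end (bp).
#' @param gene_length_bp gene length (bp).
#' @return numeric vector in `[0, 1]`.
#' @export
scaleDist5p <- function(distance_bp, gene_length_bp) {
    ok <- !is.na(distance_bp) & !is.na(gene_length_bp)
    if (any(ok & (distance_bp < 0 | distance_bp > gene_length_bp)))
        stop("distance must lie within [0, gene_length]")
    distance_bp / gene_length_bp
}

#' Assemble the per-sgRNA regression covariate table
#'
#' Applies the binning and binarization rules to a raw annotation table and
#' merges in sequence-level covariates: chromatin marks binned 0/1/2 with
#' their bin-1 drop masks, binarized copy number and replication timing,
#' gene-length halves (genes > 200 kb removed), scaled 5'-end distance,
#' CpG counts, MMEJ candidacy, PAM context class and optional motif counts.
#' Split points are returned so binnings are reproducible.
#'
#' @param library guide table from [generateGuideLibrary()] (or equivalent
#'   with `sgrna_id`, `gene`, `pam4`, `strand`, `context_seq`, `cut_index`,
#'   `is_nontargeting`).
#' @param annotations raw per-sgRNA feature table (see
#'   [generateAnnotations()]); rows matched by `sgrna_id`.
#' @param motif_covariates optional list of [MotifCovariate-class] objects;
#'   each adds a `motif_<id>` column.
#' @param genome_weights optional genome-territory weights for the
#'   chromatin binning.
#' @param expression_mode `"binary"` pools expression into high versus low
#'   at the median; `"continuous"` keeps log-scale expression.
#' @param drop_missing_d2 drop sgRNAs without a D2 score instead of
#'   flagging them.
#' @return list with `table` (DataFrame, one row per gene-targeting sgRNA),
#'   `drop_masks` (per-mark logical bin-1 masks plus `rt_zero` and
#'   `missing_d2`) and `splits` (named list of split points).
#' @export
assembleFeatureTable <- function(library, annotations,
                                 motif_covariates = NULL,
                                 genome_weights = NULL,
                                 expression_mode = c("binary", "continuous"),
                                 drop_missing_d2 = FALSE) {
    expression_mode <- match.arg(expression_mode)
    keep <- !library$is_nontargeting
    ids <- library$sgrna_id[keep]
    ann <- annotations[match(ids, annotations$sgrna_id), , drop = FALSE]
    ft <- DataFrame(sgrna_id = ids, gene = library$gene[keep],
                    row.names = ids)
    masks <- list()
    splits <- list()
    for (m in intersect(.CHROMATIN_MARKS, colnames(ann))) {
        b <- binChromatin(ann[[m]], genome_weights)
        ft[[paste0(m, "_bin")]] <- b$bin
        masks[[m]] <- b$drop_mask
        splits[[m]] <- b$split
    }
    if (!is.null(ann$cn_bin)) ft$cn_high <- binarizeCN(ann$cn_bin)
    if (!is.null(ann$rt_bin)) {
        ft$rt_early <- binarizeRT(ann$rt_bin)
        masks$rt_zero <- is.na(ft$rt_early) & !is.na(ann$rt_bin)
    }
    for (fl in intersect(c("lamin", "ctcf", "cohesin"), colnames(ann)))
        ft[[fl]] <- ann[[fl]]
    if (!is.null(ann$expression)) {
        if (expression_mode == "binary") {
            med <- stats::median(ann$expression, na.rm = TRUE)
            ft$expr_high <- ann$expression > med
            splits$expression <- med
        } else ft$log_expression <- log(ann$expression + 1)
    }
    if (!is.null(ann$gene_length)) {
        glen <- tapply(ann$gene_length, ft$gene, `[`, 1L)
        gb <- geneLengthBins(glen)
        ft$gene_length_bin <- gb[match(ft$gene, names(glen))]
        splits$gene_length <- stats::median(glen[glen <= 2e5], na.rm = TRUE)
        if (!is.null(ann$dist5p))
            ft$dist5p_scaled <- scaleDist5p(ann$dist5p, ann$gene_length)
    }
    if (!is.null(ann$d2)) {
        ft$d2 <- ann$d2
        masks$missing_d2 <- is.na(ft$d2)
        if (drop_missing_d2 && any(masks$missing_d2)) {
            ft <- ft[!masks$missing_d2, , drop = FALSE]
            masks <- lapply(masks, `[`, !masks$missing_d2)
        }
    }
    ctx_ok <- !is.na(library$context_seq[keep])
    if (any(ctx_ok)) {
        cpg <- rep(NA_integer_, length(ids))
        cpg[ctx_ok] <- countCpG(library$context_seq[keep][ctx_ok])
        ft$cpg <- cpg
        mh <- rep(NA, length(ids))
        mh[ctx_ok] <- vapply(which(ctx_ok), function(i)
            isMMEJCandidate(library$context_seq[keep][i],
                            library$cut_index[keep][i]), logical(1L))
        ft$mh <- mh
        pam_ok <- !is.na(library$pam4[keep])
        pc <- rep(NA_character_, length(ids))
        pc[pam_ok] <- extractPAMContext(library$pam4[keep][pam_ok])$class
        ft$pam_class <- pc
    }
    for (mc in motif_covariates)
        ft[[paste0("motif_", mc@motif_id)]] <- unname(mc@counts[ids])
    list(table = ft, drop_masks = masks, splits = splits)
}
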