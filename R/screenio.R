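#' Median-of-ratios count normalization on a reference guide set
#'
#' Emulates median normalization of screen counts on a reference set:
#' for reference sgRNAs i with all-positive counts, `g_i` is the geometric
#' mean of the raw counts of i across samples, and the size factor of sample
#' j is `s_j = median_i(c_ij / g_i)`. Normalized counts are `c_ij / s_j`,
#' which equalizes the median normalized reference count across samples.
#' Three reference modes are exposed: all sgRNAs, the non-targeting control
#' set, or a supplied non-essential gene set.
#'
#' @param se a count [SummarizedExperiment::SummarizedExperiment] with raw
#'   integer assay `counts` (rowData needs `gene` and `is_nontargeting`).
#' @param reference `"all"`, `"nontargeting"`, or `"genes"`.
#' @param ref_genes gene symbols of the reference set when
#'   `reference = "genes"` (e.g. non-essential genes).
#' @return The experiment with an added assay `normcounts`,
#'   `metadata$size_factors`, `metadata$normalized = TRUE` and
#'   `metadata$reference_set_used`.
#' @export
medianNormalize <- function(se, reference = c("all", "nontargeting", "genes"),
                            ref_genes = NULL) {
    reference <- match.arg(reference)
    counts <- SummarizedExperiment::assay(se, "counts")
    if (any(counts < 0)) stop("raw counts must be non-negative")
    rd <- SummarizedExperiment::rowData(se)
    ref <- switch(reference,
        all = rep(TRUE, nrow(se)),
        nontargeting = rd$is_nontargeting,
        genes = {
            if (is.null(ref_genes)) stop("ref_genes required for reference='genes'")
            !is.na(rd$gene) & rd$gene %in% ref_genes
        })
    if (sum(ref, na.rm = TRUE) < 10L)
        stop("reference set intersects fewer than 10 sgRNAs in the matrix")
    sf <- .sizeFactors(counts, which(ref))
    if (any(!is.finite(sf) | sf <= 0))
        stop("zero or undefined size factor for sample ",
             colnames(counts)[which(!is.finite(sf) | sf <= 0)[1L]])
    SummarizedExperiment::assay(se, "normcounts") <-
        sweep(counts, 2L, sf, "/")
    metadata(se)$size_factors <- sf
    metadata(se)$normalized <- TRUE
    metadata(se)$reference_set_used <- reference
    se
}

## DESeq-style median-of-ratios size factors restricted to reference rows
.sizeFactors <- function(counts, ref_rows) {
    refc <- counts[ref_rows, , drop = FALSE]
    pos <- rowSums(refc <= 0) == 0L
    if (!any(pos)) stop("reference set has no sgRNA with all-positive counts")
    refc <- refc[pos, , drop = FALSE]
    g <- exp(rowMeans(log(refc)))
    apply(refc, 2L, function(cj) stats::median(cj / g))
}

#' Merge technical batches by summing raw counts
#'
#' Sums raw counts of samples within each group before normalization; group
#' metadata is inherited from the first member. Merging samples with
#' different genotypes is refused.
#'
#' @param se a raw count experiment.
#' @param batch_map factor or character vector (one entry per sample) naming
#'   the merge group of each sample; samples sharing a group label are
#'   summed. Singleton groups pass through unchanged.
#' @return A merged [SummarizedExperiment::SummarizedExperiment] (raw
#'   counts; offsets recomputed from the merged non-targeting totals when
#'   possible).
#' @export
mergeBatches <- function(se, batch_map) {
    if (length(batch_map) != ncol(se))
        stop("batch_map must have one entry per sample")
    if (isTRUE(metadata(se)$normalized))
        stop("merge batches before normalization, on raw counts")
    batch_map <- as.character(batch_map)
    cd <- SummarizedExperiment::colData(se)
    for (g in unique(batch_map)) {
        gt <- unique(cd$genotype[batch_map == g])
        if (length(gt) > 1L)
            stop("refusing to merge across genotypes in group '", g, "'")
    }
    counts <- SummarizedExperiment::assay(se, "counts")
    groups <- unique(batch_map)
    merged <- sapply(groups, function(g)
        rowSums(counts[, batch_map == g, drop = FALSE]))
    dimnames(merged) <- list(rownames(counts), groups)
    first <- match(groups, batch_map)
    cd2 <- cd[first, , drop = FALSE]
    rownames(cd2) <- groups
    cd2$sample_id <- groups
    cd2$batch <- vapply(groups, function(g)
        paste(cd$batch[batch_map == g], collapse = "+"), "")
    rd <- SummarizedExperiment::rowData(se)
    if (!is.null(rd$is_nontargeting) && any(rd$is_nontargeting))
        cd2$offset <- log(colSums(merged[rd$is_nontargeting, , drop = FALSE]))
    out <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = merged), rowData = rd, colData = cd2)
    metadata(out) <- metadata(se)
    metadata(out)$normalized <- FALSE
    out
}

#' Per-sgRNA log2 fold changes between paired samples
#'
#' `LFC = log2((n_treated + pc) / (n_control + pc))` on normalized counts,
#' for each requested (treated, control) pair -- e.g. TP53 wild-type
#' (pseudo-treatment) versus TP53-knockout (pseudo-control) samples matched
#' by arm and time point.
#'
#' @param se a normalized experiment (run [medianNormalize()] first).
#' @param pairs data.frame with columns `treated`, `control` (sample ids)
#'   and optionally `name` (column label, default `treated_vs_control`).
#' @param pseudocount added to both counts; the default 1 keeps LFCs finite
#'   on dropouts.
#' @param drop_zero_baseline optional baseline sample id; sgRNAs with a zero
#'   raw count in that sample are dropped (the remove-0 behaviour).
#' @return numeric matrix, sgRNAs x pairs.
#' @export
computeLFC <- function(se, pairs, pseudocount = 1,
                       drop_zero_baseline = NULL) {
    if (!isTRUE(metadata(se)$normalized))
        stop("counts are not normalized; run medianNormalize() first")
    norm <- SummarizedExperiment::assay(se, "normcounts")
    missing <- setdiff(unique(c(pairs$treated, pairs$control)), colnames(norm))
    if (length(missing))
        stop("pairs reference unknown samples: ",
             paste(missing, collapse = ", "))
    if (!is.null(drop_zero_baseline)) {
        raw <- SummarizedExperiment::assay(se, "counts")
        keep <- raw[, drop_zero_baseline] > 0
        norm <- norm[keep, , drop = FALSE]
    }
    lfc <- sapply(seq_len(nrow(pairs)), function(k)
        log2((norm[, pairs$treated[k]] + pseudocount) /
             (norm[, pairs$control[k]] + pseudocount)))
    colnames(lfc) <- if (!is.null(pairs$name)) pairs$name
                     else paste0(pairs$treated, "_vs_", pairs$control)
    rownames(lfc) <- rownames(norm)
    lfc
}

#' All wild-type-versus-knockout comparison pairs of a design
#'
#' Builds the (treated = wt, control = ko) sample pairs matched on
#' pseudo-replicate and time point, by default restricted to the later time
#' points (baseline excluded).
#'
#' @param se a screen experiment with the standard colData columns.
#' @param later_only exclude the baseline (first) time point.
#' @return data.frame with columns `treated`, `control`, `name`.
#' @export
wtKoPairs <- function(se, later_only = TRUE) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    gl <- levels(cd$genotype)
    tps <- unique(cd$time_point)
    if (later_only) tps <- setdiff(tps, tps[cd$time_index[match(tps, cd$time_point)] == 0L])
    out <- NULL
    for (pr in unique(cd$pseudo_replicate)) for (tp in tps) {
        wt <- cd$sample_id[cd$genotype == gl[2L] & cd$pseudo_replicate == pr &
                           cd$time_point == tp]
        ko <- cd$sample_id[cd$genotype == gl[1L] & cd$pseudo_replicate == pr &
                           cd$time_point == tp]
        if (length(wt) == 1L && length(ko) == 1L)
            out <- rbind(out, data.frame(treated = wt, control = ko,
                                         name = paste(pr, tp, sep = "_")))
    }
    if (is.null(out)) stop("no matched wt/ko sample pairs found")
    out
}

# ---------------------------------------------------------------------------
# Plain-text round-trip IO
# ---------------------------------------------------------------------------

#' Write / read a screen experiment as TSV tables
#'
#' `writeScreenTSV()` writes three tab-separated files into `dir`:
#' `counts.tsv` (first column `sgrna_id`, one column per sample),
#' `samples.tsv` (the sample metadata) and `library.tsv` (the guide table).
#' `readScreenTSV()` reconstructs the experiment; integer counts round-trip
#' bit-exactly.
#'
#' @param se the experiment to write.
#' @param dir output directory (created if needed).
#' @return `writeScreenTSV()` the directory, invisibly; `readScreenTSV()` a
#'   [SummarizedExperiment::SummarizedExperiment].
#' @export
writeScreenTSV <- function(se, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    counts <- SummarizedExperiment::assay(se, "counts")
    writeTSV(data.frame(sgrna_id = rownames(counts), counts,
                        check.names = FALSE),
             file.path(dir, "counts.tsv"))
    writeTSV(as.data.frame(SummarizedExperiment::colData(se)),
             file.path(dir, "samples.tsv"))
    lib <- as.data.frame(SummarizedExperiment::rowData(se))
    writeTSV(lib, file.path(dir, "library.tsv"))
    invisible(dir)
}

#' @rdname writeScreenTSV
#' @export
readScreenTSV <- function(dir) {
    counts_df <- readTSV(file.path(dir, "counts.tsv"))
    counts <- as.matrix(counts_df[, -1L, drop = FALSE])
    rownames(counts) <- counts_df$sgrna_id
    cd <- readTSV(file.path(dir, "samples.tsv"))
    rownames(cd) <- cd$sample_id
    if (!is.null(cd$genotype)) cd$genotype <- factor(cd$genotype,
        levels = unique(cd$genotype[order(cd$genotype != cd$genotype[1L])]))
    lib <- readTSV(file.path(dir, "library.tsv"))
    rownames(lib) <- lib$sgrna_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts[, cd$sample_id, drop = FALSE]),
        rowData = lib[rownames(counts), , drop = FALSE],
        colData = as(cd, "DataFrame"))
    metadata(se)$normalized <- FALSE
    se
}

#' Tab-separated table IO helpers
#'
#' Thin wrappers with the conventions used throughout this package: header,
#' no quoting, no row names, tabs, `NA` literal. Lines starting with `#`
#' are stamp/comment lines and are skipped on read, so stamped tables
#' round-trip.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @param stamp optional `#`-prefixed provenance line written first.
#' @return `readTSV()` returns a data.frame.
#' @export
writeTSV <- function(x, path, stamp = NULL) {
    if (!is.null(stamp)) {
        writeLines(stamp, path)
        suppressWarnings(utils::write.table(
            x, path, sep = "\t", quote = FALSE, row.names = FALSE,
            append = TRUE))
    } else {
        utils::write.table(x, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) {
    if (!file.exists(path)) stop("missing input file: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "#")
}

#' Read a gene list (one symbol per line)
#'
#' @param path text file, one gene symbol per line; `#` comments allowed.
#' @return character vector of symbols, case-normalized to upper case.
#' @export
readGeneList <- function(path) {
    ln <- trimws(readLines(path))
    toupper(ln[!grepl("^\\s*(#|$)", ln)])
}
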