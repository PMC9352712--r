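makeToySE <- function(counts, nontargeting = rep(FALSE, nrow(counts)),
                      gene = paste0("G", seq_len(nrow(counts)))) {
    gene[nontargeting] <- NA
    rownames(counts) <- paste0("sg", seq_len(nrow(counts)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(
            sgrna_id = rownames(counts), gene = gene,
            is_nontargeting = nontargeting, row.names = rownames(counts)),
        colData = S4Vectors::DataFrame(
            sample_id = colnames(counts), row.names = colnames(counts)))
    S4Vectors::metadata(se)$normalized <- FALSE
    se
}

test_that("size factors are symmetric and scale-equivariant", {
    m <- matrix(rpois(40, 50) + 1L, ncol = 2L,
                dimnames = list(NULL, c("a", "b")))
    m[, 2L] <- m[, 1L]
    se <- medianNormalize(makeToySE(m), "all")
    sf <- S4Vectors::metadata(se)$size_factors
    expect_equal(unname(sf[1L]), unname(sf[2L]))
    # doubling one sample doubles its size factor; normalized counts agree
    m2 <- m; m2[, 2L] <- 2L * m2[, 1L]
    se2 <- medianNormalize(makeToySE(m2), "all")
    sf2 <- S4Vectors::metadata(se2)$size_factors
    expect_equal(unname(sf2[2L] / sf2[1L]), 2)
    norm <- SummarizedExperiment::assay(se2, "normcounts")
    expect_equal(norm[, 1L], norm[, 2L])
    # equal-depth samples: all size factors equal (normalization idempotent
    # up to a common constant)
    expect_lt(diff(range(sf)), 1e-12)
})

test_that("size factors equal the brute-force median-of-ratios and DESeq2's", {
    set.seed(8)
    # odd row count: the arithmetic and log-scale medians coincide there,
    # so all three routes must agree exactly
    m <- matrix(rpois(63, 80) + 1L, ncol = 3L,
                dimnames = list(NULL, c("a", "b", "c")))
    m[, 2L] <- round(m[, 2L] * 1.7); m[, 3L] <- round(m[, 3L] * 0.6)
    se <- medianNormalize(makeToySE(m), "all")
    sf <- S4Vectors::metadata(se)$size_factors
    # brute force: per sample, median over rows of count / geometric mean
    g <- exp(rowMeans(log(m)))
    brute <- apply(m, 2L, function(cj) median(cj / g))
    expect_equal(unname(sf), unname(brute), tolerance = 1e-12)
    # independent cross-check against DESeq2's median-of-ratios
    ds <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(sf), unname(ds), tolerance = 1e-8)
})

test_that("reference modes and degenerate references behave as specified", {
    set.seed(9)
    m <- matrix(rpois(300, 100) + 1L, ncol = 3L,
                dimnames = list(NULL, c("a", "b", "c")))
    nt <- c(rep(FALSE, 80L), rep(TRUE, 20L))
    se <- makeToySE(m, nontargeting = nt)
    expect_s4_class(medianNormalize(se, "nontargeting"),
                    "SummarizedExperiment")
    genes <- paste0("G", 1:15)
    expect_s4_class(medianNormalize(se, "genes", ref_genes = genes),
                    "SummarizedExperiment")
    expect_error(medianNormalize(se, "genes", ref_genes = paste0("G", 1:5)),
                 "fewer than 10")
    expect_error(medianNormalize(se, "genes"), "ref_genes")
})

test_that("batch merging sums raw counts within groups only", {
    m <- matrix(c(10L, 20L, 10L, 20L, 5L, 6L), ncol = 3L,
                dimnames = list(NULL, c("s1", "s2", "s3")))
    se <- makeToySE(m)
    SummarizedExperiment::colData(se)$genotype <- factor(c("ko", "ko", "wt"),
                                                         levels = c("ko", "wt"))
    SummarizedExperiment::colData(se)$batch <- c("b1", "b2", "b1")
    merged <- mergeBatches(se, c("g1", "g1", "g2"))
    mm <- SummarizedExperiment::assay(merged, "counts")
    expect_equal(unname(mm[, "g1"]), unname(m[, 1L] + m[, 2L]))
    expect_equal(unname(mm[, "g2"]), unname(m[, 3L]))  # singleton = identity
    # two equal batches -> merged = 2x each
    expect_equal(unname(mm[, "g1"]), unname(2L * m[, 1L]))
    expect_error(mergeBatches(se, c("g1", "g2", "g1")), "genotypes")
    expect_error(mergeBatches(medianNormalize(makeToySE(
        matrix(rpois(40, 50) + 1L, ncol = 2L,
               dimnames = list(NULL, c("a", "b"))), ), "all"),
        c("g", "g")), "raw")
})

test_that("LFC has its closed form, is antisymmetric, and needs normalization", {
    m <- matrix(c(7L, 100L, 12L, 3L, 25L, 12L), ncol = 2L,
                dimnames = list(NULL, c("t", "c")))
    se <- makeToySE(m)
    expect_error(computeLFC(se, data.frame(treated = "t", control = "c")),
                 "not normalized")
    # bypass size factors for the closed-form checks
    SummarizedExperiment::assay(se, "normcounts", withDimnames = FALSE) <-
        SummarizedExperiment::assay(se, "counts")
    S4Vectors::metadata(se)$normalized <- TRUE
    pairs <- data.frame(treated = "t", control = "c", name = "p")
    lfc <- computeLFC(se, pairs, pseudocount = 1)
    expect_equal(unname(lfc["sg1", "p"]), log2(8 / 4))   # (7,3,pc=1) -> 1
    lfc0 <- computeLFC(se, pairs, pseudocount = 0)
    expect_equal(unname(lfc0["sg2", "p"]), 2)            # 100 = 4 x 25
    expect_equal(unname(lfc0["sg3", "p"]), 0)            # equal counts
    # pair swap flips the sign with a common pseudocount
    swapped <- computeLFC(se, data.frame(treated = "c", control = "t",
                                         name = "p"), pseudocount = 1)
    expect_equal(unname(lfc[, "p"]), -unname(swapped[, "p"]))
    expect_error(computeLFC(se, data.frame(treated = "zz", control = "c")),
                 "unknown samples")
    # remove-0: guides at zero in the baseline sample are dropped
    lfc_rm <- computeLFC(se, pairs, drop_zero_baseline = "c")
    expect_equal(nrow(lfc_rm), 3L)
    m2 <- m; m2[2L, "c"] <- 0L
    se2 <- makeToySE(m2)
    SummarizedExperiment::assay(se2, "normcounts", withDimnames = FALSE) <- m2
    S4Vectors::metadata(se2)$normalized <- TRUE
    expect_equal(rownames(computeLFC(se2, pairs, drop_zero_baseline = "c")),
                 c("sg1", "sg3"))
})

test_that("screen tables round-trip bit-exactly through TSV", {
    se <- simulateScreen(SimConfig(n_genes = 8L, n_nontargeting = 5L,
                                   seed = 77L))
    dir <- tempfile()
    writeScreenTSV(se, dir)
    back <- readScreenTSV(dir)
    expect_identical(SummarizedExperiment::assay(back, "counts"),
                     SummarizedExperiment::assay(se, "counts"))
    expect_identical(back$sample_id, se$sample_id)
    expect_equal(back$offset, se$offset)
    # stamped tables round-trip too
    f <- tempfile()
    df <- data.frame(a = 1:3, b = c("x", "y", "z"))
    writeTSV(df, f, stamp = "# stamp line")
    expect_identical(readTSV(f), df)
    expect_error(readTSV(tempfile()), "missing input file")
})
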