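test_that("library composition follows the configuration", {
    lib <- generateGuideLibrary(SimConfig(n_genes = 2L, sgrnas_per_gene = 4L,
                                          n_nontargeting = 3L, seed = 5L))
    expect_equal(nrow(lib), 11L)
    expect_equal(sum(!lib$is_nontargeting), 8L)
    expect_true(all(grepl("^[ACGT]{20}$", lib$protospacer)))
    ctx <- lib$context_seq[!lib$is_nontargeting]
    expect_true(all(nchar(ctx) == 201L))
    # the protospacer+PAM are embedded around the cut (cut between
    # protospacer positions 17/18; PAM NGG 3 bp downstream of the cut)
    ctr <- lib$cut_index[1L]
    expect_equal(substr(ctx, ctr - 16L, ctr + 3L),
                 lib$protospacer[!lib$is_nontargeting])
    expect_true(all(substr(lib$pam4[!lib$is_nontargeting], 3L, 4L) == "GG"))
    expect_true(all(is.na(lib$gene[lib$is_nontargeting])))
    expect_error(SimConfig(n_genes = 0L), "n_genes")
    expect_error(SimConfig(dispersion = -1), "dispersion")
})

test_that("identical seed and configuration reproduce the simulation exactly", {
    cfg <- SimConfig(n_genes = 20L, n_nontargeting = 10L, seed = 42L)
    lib1 <- generateGuideLibrary(cfg)
    lib2 <- generateGuideLibrary(cfg)
    expect_identical(as.data.frame(lib1), as.data.frame(lib2))
    se1 <- simulateScreen(cfg)
    se2 <- simulateScreen(cfg)
    expect_identical(SummarizedExperiment::assay(se1, "counts"),
                     SummarizedExperiment::assay(se2, "counts"))
    se3 <- simulateScreen(SimConfig(n_genes = 20L, n_nontargeting = 10L,
                                    seed = 43L))
    expect_false(identical(SummarizedExperiment::assay(se1, "counts"),
                           SummarizedExperiment::assay(se3, "counts")))
})

test_that("planted microhomology fraction is recovered by the scanner", {
    cfg <- SimConfig(n_genes = 50L, sgrnas_per_gene = 4L, n_nontargeting = 0L,
                     mh_fraction = 0.5, seed = 7L)
    lib <- generateGuideLibrary(cfg)
    detected <- vapply(seq_len(nrow(lib)), function(i)
        isMMEJCandidate(lib$context_seq[i], lib$cut_index[i]), logical(1L))
    # scanner agrees with the planting flags guide-by-guide
    expect_identical(detected, as.logical(lib$mh_planted))
    # detected fraction within the binomial 99% CI around 0.5
    n <- nrow(lib)
    ci <- 0.5 + c(-1, 1) * stats::qnorm(0.995) * sqrt(0.25 / n)
    expect_gt(mean(detected), ci[1L])
    expect_lt(mean(detected), ci[2L])
})

test_that("annotation abundances carry the configured cross-mark correlation", {
    cfg <- SimConfig(n_genes = 2500L, sgrnas_per_gene = 4L,
                     n_nontargeting = 0L, seed = 2L)
    lib <- generateGuideLibrary(cfg)
    # independent marks: all off-diagonal sample correlations near zero
    ann0 <- generateAnnotations(lib, EffectSpec(), seed = 3L)
    marks <- chromatinMarks()
    cm0 <- cor(as.matrix(as.data.frame(ann0[, marks])))
    expect_lt(max(abs(cm0[upper.tri(cm0)])), 0.1)
    # configured latent correlation 0.7 between DHS and H3K27ac
    rho <- matrix(c(1, 0.7, 0.7, 1), 2L,
                  dimnames = list(c("DHS", "H3K27ac"), c("DHS", "H3K27ac")))
    eff <- EffectSpec(features = data.frame(feature = c("DHS", "H3K27ac"),
                                            fraction = 0.5, beta_main = 0,
                                            beta_interaction = 0),
                      correlation = rho)
    ann <- generateAnnotations(lib, eff, seed = 3L)
    r <- cor(ann$DHS, ann$H3K27ac)
    expect_gt(r, 0.6); expect_lt(r, 0.8)
    # unknown feature names are refused
    bad <- rho; dimnames(bad) <- list(c("DHS", "NOTAMARK"),
                                      c("DHS", "NOTAMARK"))
    eff_bad <- EffectSpec(features = data.frame(feature = c("DHS", "NOTAMARK"),
                                                fraction = 0.5, beta_main = 0,
                                                beta_interaction = 0),
                          correlation = bad)
    eff_bad@features <- eff_bad@features[1L, , drop = FALSE]
    expect_error(generateAnnotations(lib, eff_bad, seed = 1L),
                 "unknown feature")
})

test_that("null counts match the offset+baseline mean and NB variance law", {
    cfg <- SimConfig(n_genes = 100L, sgrnas_per_gene = 4L,
                     n_nontargeting = 1000L, dispersion = 1e6, seed = 9L)
    eff <- EffectSpec(features = data.frame(feature = "DHS", fraction = 0.5,
                                            beta_main = 0,
                                            beta_interaction = 0),
                      beta_d2 = 0)
    se <- simulateScreen(cfg, eff)
    counts <- SummarizedExperiment::assay(se, "counts")
    cd <- SummarizedExperiment::colData(se)
    # per-sample mean across the (many) non-targeting guides within 3 MC-SE
    # of exp(baseline + log depth)
    nt <- SummarizedExperiment::rowData(se)$is_nontargeting
    for (j in seq_len(ncol(se))) {
        mu <- exp(log(500) + log(cd$depth_factor[j]))
        mcse <- sqrt(mu / sum(nt))   # theta huge -> Poisson-like
        expect_lt(abs(mean(counts[nt, j]) - mu), 3 * mcse + 1)
    }
    # NB mean/variance law across a dispersion grid
    set.seed(4L)
    for (theta in c(1, 10, 100)) {
        cfg2 <- SimConfig(n_genes = 1L, sgrnas_per_gene = 1L,
                          n_nontargeting = 5000L, dispersion = theta,
                          seed = 21L)
        se2 <- simulateScreen(cfg2, eff)
        x <- SummarizedExperiment::assay(se2, "counts")[-1L, 1L]
        mu <- mean(x)
        expect_lt(abs(var(x) - (mu + mu^2 / theta)) / (mu + mu^2 / theta),
                  0.15)
    }
    # variance/mean ratio grows as theta falls, at equal means
    v <- sapply(c(1, 100), function(theta) {
        se2 <- simulateScreen(SimConfig(n_genes = 1L, sgrnas_per_gene = 1L,
                                        n_nontargeting = 3000L,
                                        dispersion = theta, seed = 22L), eff)
        x <- SummarizedExperiment::assay(se2, "counts")[-1L, 1L]
        var(x) / mean(x)
    })
    expect_gt(v[1L], v[2L])
})

test_that("planted genotype interaction appears as the wt-vs-ko carrier contrast", {
    cfg <- SimConfig(n_genes = 1250L, sgrnas_per_gene = 4L,
                     n_nontargeting = 100L, seed = 13L)
    se <- simulateScreen(cfg, EffectSpec())   # beta interaction -0.3 on DHS
    counts <- SummarizedExperiment::assay(se, "counts")
    rd <- SummarizedExperiment::rowData(se)
    carrier <- rd$true_DHS == 1 & !rd$is_nontargeting
    noncar <- rd$true_DHS == 0 & !rd$is_nontargeting
    contrast <- function(s) log(mean(counts[carrier, s])) -
        log(mean(counts[noncar, s]))
    # at t9 (time index 1) the carrier/non-carrier log-ratio differs between
    # genotypes by the planted interaction
    d <- contrast("wt_pr1_t9") - contrast("ko_pr1_t9")
    expect_lt(abs(d - (-0.3)), 0.06)
    # baseline counts are drawn before effects act
    d0 <- contrast("wt_pr1_t0") - contrast("ko_pr1_t0")
    expect_lt(abs(d0), 0.06)
})

test_that("overflowing means are rejected naming the offending parameter", {
    cfg <- SimConfig(n_genes = 5L, sgrnas_per_gene = 2L, n_nontargeting = 0L,
                     seed = 1L)
    lib <- generateGuideLibrary(cfg)
    eff <- EffectSpec(features = data.frame(feature = "DHS", fraction = 0.5,
                                            beta_main = 40,
                                            beta_interaction = 0))
    ann <- generateAnnotations(lib, eff, seed = 2L)
    expect_error(simulateCounts(lib, ann, eff, cfg), "beta\\[DHS\\]")
    # annotations must cover the gene-targeting guides
    expect_error(simulateCounts(lib, ann[1:3, ], EffectSpec(), cfg),
                 "cover")
})
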