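# shared small simulated screen: 500 genes x 4 guides, interaction -0.3 on
# a 50% feature, theta = 10
simScreen <- function(seed, beta_int = -0.3, beta_main = 0, n_genes = 500L,
                      theta = 10) {
    cfg <- SimConfig(n_genes = n_genes, sgrnas_per_gene = 4L,
                     n_nontargeting = 100L, dispersion = theta, seed = seed)
    eff <- EffectSpec(features = data.frame(feature = "DHS", fraction = 0.5,
                                            beta_main = beta_main,
                                            beta_interaction = beta_int))
    simulateScreen(cfg, eff)
}

fitSim <- function(se, ...) {
    cd <- SummarizedExperiment::colData(se)
    later <- cd$sample_id[cd$time_index > 0L]
    rd <- SummarizedExperiment::rowData(se)
    fitFeatureInteraction(se, rd$true_DHS, rd$true_d2, samples = later,
                          effect_exposure = cd[later, "time_index"], ...)
}

test_that("the planted interaction and dispersion are recovered", {
    se <- simScreen(101L)
    fit <- fitSim(se)
    expect_true(isConverged(fit))
    est <- termEstimate(fit)
    expect_lt(abs(est$estimate - (-0.3)), 2 * est$se)
    # dispersion recovered within 25%
    expect_lt(abs(dispersionTheta(fit) - 10) / 10, 0.25)
    # reference levels: knockout genotype, feature absent
    tt <- coefTable(fit)
    expect_true(any(grepl("genotypewt", tt$term)))
    expect_output(show(fit), "interaction")
})

test_that("permuting genotype labels attenuates the interaction", {
    se <- simScreen(102L, n_genes = 300L)
    fit <- fitSim(se)
    b0 <- abs(termEstimate(fit)$estimate)
    cd <- SummarizedExperiment::colData(se)
    set.seed(1)
    smaller <- 0L
    for (i in 1:12) {
        sep <- se
        SummarizedExperiment::colData(sep)$genotype <-
            sample(cd$genotype)
        bp <- abs(termEstimate(fitSim(sep))$estimate)
        smaller <- smaller + (bp < b0)
    }
    expect_gte(smaller, 11L)
})

test_that("coefficients are invariant to depth absorbed by the offset", {
    # NB working weights theta*mu/(theta+mu) are scale-invariant in the
    # overdispersion-dominated limit; theta is held at its true value since
    # c x NB(mu, theta) is not NB(c mu, theta)
    cfg <- SimConfig(n_genes = 150L, sgrnas_per_gene = 4L,
                     n_nontargeting = 100L, baseline_log_mean = log(5e4),
                     seed = 103L)
    se <- simulateScreen(cfg, EffectSpec())
    fit1 <- fitSim(se, theta = 10)
    se2 <- se
    SummarizedExperiment::assay(se2, "counts", withDimnames = FALSE) <-
        SummarizedExperiment::assay(se, "counts") * 4L
    SummarizedExperiment::colData(se2)$offset <-
        SummarizedExperiment::colData(se)$offset + log(4)
    fit2 <- fitSim(se2, theta = 10)
    expect_lt(abs(termEstimate(fit1)$estimate - termEstimate(fit2)$estimate),
              1e-6)
})

test_that("on a balanced 2x2 design with tiny dispersion the interaction is the log contrast of group means", {
    set.seed(31)
    n <- 4000L
    x <- rep(c(0, 1), each = n / 2)
    gt <- factor(rep(c("ko", "wt"), times = n / 2), levels = c("ko", "wt"))
    mu <- exp(log(300) + 0.2 * x + -0.4 * x * (gt == "wt"))
    counts <- rnbinom(n, mu = mu, size = 1e6)
    m <- tapply(counts, list(x, as.character(gt)), mean)
    contrast <- log(m["1", "wt"]) - log(m["0", "wt"]) -
        (log(m["1", "ko"]) - log(m["0", "ko"]))
    df <- data.frame(count = counts, x = x, genotype = gt, d2 = 0, off = 0)
    fit <- suppressWarnings(
        MASS::glm.nb(count ~ x * genotype + offset(off), data = df))
    expect_lt(abs(unname(coef(fit)["x:genotypewt"]) - contrast), 1e-6)
})

test_that("the wild-type-only model recovers per-feature effects", {
    # planted feature main effect -0.2, no interaction
    se <- simScreen(104L, beta_int = 0, beta_main = -0.2, n_genes = 400L)
    rd <- SummarizedExperiment::rowData(se)
    cd <- SummarizedExperiment::colData(se)
    wt_later <- cd$sample_id[cd$time_index > 0L & cd$genotype == "wt"]
    fit <- fitWtOnly(se, rd$true_DHS, rd$true_d2,
                     effect_exposure = cd[wt_later, "time_index"])
    est <- termEstimate(fit, "feature_main")
    expect_lt(abs(est$estimate - (-0.2)), 2 * est$se)
    # null: no planted effects at all
    se0 <- simScreen(105L, beta_int = 0, beta_main = 0, n_genes = 400L)
    rd0 <- SummarizedExperiment::rowData(se0)
    cd0 <- SummarizedExperiment::colData(se0)
    wt0 <- cd0$sample_id[cd0$time_index > 0L & cd0$genotype == "wt"]
    fit0 <- fitWtOnly(se0, rd0$true_DHS, rd0$true_d2,
                      effect_exposure = cd0[wt0, "time_index"])
    est0 <- termEstimate(fit0, "feature_main")
    expect_lt(abs(est0$estimate), 3 * est0$se)
    # degenerate single-level feature is refused
    expect_error(fitWtOnly(se, rep(1, nrow(se)), rd$true_d2),
                 "single level")
})

test_that("pairwise conditioning adjusts for a correlated toxic cofeature", {
    # cofeature correlated with the feature carries the true interaction;
    # the marginal fit of the feature is confounded, conditioning fixes it
    set.seed(41)
    cfg <- SimConfig(n_genes = 500L, sgrnas_per_gene = 4L,
                     n_nontargeting = 100L, seed = 106L)
    rho <- matrix(c(1, 0.7, 0.7, 1), 2L,
                  dimnames = list(c("DHS", "H3K27ac"),
                                  c("DHS", "H3K27ac")))
    eff <- EffectSpec(features = data.frame(
        feature = c("DHS", "H3K27ac"),
        fraction = 0.5, beta_main = 0,
        beta_interaction = c(0, -0.4)), correlation = rho)
    se <- simulateScreen(cfg, eff)
    rd <- SummarizedExperiment::rowData(se)
    cd <- SummarizedExperiment::colData(se)
    later <- cd$sample_id[cd$time_index > 0L]
    expo <- cd[later, "time_index"]
    marginal <- fitFeatureInteraction(se, rd$true_DHS, rd$true_d2,
                                      samples = later,
                                      effect_exposure = expo)
    conditioned <- fitPairwiseConditioned(se, rd$true_DHS, rd$true_H3K27ac,
                                          rd$true_d2, samples = later,
                                          effect_exposure = expo)
    bm <- termEstimate(marginal)$estimate
    bc <- termEstimate(conditioned)
    expect_lt(bm, -0.05)                       # confounded toward the cofeature
    expect_lt(abs(bc$estimate - 0), 3 * bc$se) # conditioning recovers the null
    # an exact copy of the feature is rank-deficient
    dup <- fitPairwiseConditioned(se, rd$true_DHS, rd$true_DHS, rd$true_d2,
                                  samples = later, effect_exposure = expo)
    expect_true(dup@rank_deficient)
    # an independent cofeature leaves the estimate essentially unchanged
    se2 <- simScreen(107L, n_genes = 300L)
    rd2 <- SummarizedExperiment::rowData(se2)
    cd2 <- SummarizedExperiment::colData(se2)
    later2 <- cd2$sample_id[cd2$time_index > 0L]
    expo2 <- cd2[later2, "time_index"]
    set.seed(5)
    indep <- as.numeric(runif(nrow(se2)) < 0.5)
    f_marg <- fitFeatureInteraction(se2, rd2$true_DHS, rd2$true_d2,
                                    samples = later2, effect_exposure = expo2)
    f_cond <- fitPairwiseConditioned(se2, rd2$true_DHS, indep, rd2$true_d2,
                                     samples = later2, effect_exposure = expo2)
    expect_lt(abs(termEstimate(f_marg)$estimate -
                  termEstimate(f_cond)$estimate),
              2 * termEstimate(f_marg)$se)
})

test_that("status-only and D2-only models capture global effects", {
    # global wild-type toxicity -0.1 via a feature carried by every guide;
    # many non-targeting guides keep the per-sample offset noise well below
    # the effect size (the status contrast spans only six samples)
    cfg <- SimConfig(n_genes = 400L, sgrnas_per_gene = 4L,
                     n_nontargeting = 2000L, seed = 108L)
    eff <- EffectSpec(features = data.frame(feature = "GLOBAL",
                                            fraction = 0.999,
                                            beta_main = 0,
                                            beta_interaction = -0.1))
    se <- simulateScreen(cfg, eff)
    rd <- SummarizedExperiment::rowData(se)
    cd <- SummarizedExperiment::colData(se)
    # the categorical status term cannot carry a per-sample exposure, so
    # recover the per-time-unit global toxicity at the first later time
    # point (exposure 1)
    t9 <- cd$sample_id[cd$time_index == 1L]
    fit <- fitStatusOnly(se, rd$true_d2, samples = t9)
    est <- termEstimate(fit, "status_main")
    expect_lt(abs(est$estimate - (-0.1)), max(2.5 * est$se, 0.02))
    # D2 slope sign matches the planted essentiality effect (0.5)
    fd2 <- fitD2Only(se, rd$true_d2, samples = t9)
    d2est <- termEstimate(fd2, "d2")
    expect_gt(d2est$estimate, 0)
    expect_lt(abs(d2est$estimate - 0.5), max(4 * d2est$se, 0.03))
    # null: no status effect
    se0 <- simScreen(109L, beta_int = 0, n_genes = 300L)
    rd0 <- SummarizedExperiment::rowData(se0)
    cd0 <- SummarizedExperiment::colData(se0)
    later0 <- cd0$sample_id[cd0$time_index > 0L]
    fit0 <- fitStatusOnly(se0, rd0$true_d2, samples = later0,
                          effect_exposure = cd0[later0, "time_index"])
    est0 <- termEstimate(fit0, "status_main")
    expect_lt(abs(est0$estimate), 3 * est0$se)
})

test_that("panel TP53-by-HR and feature-by-HR models recover planted interactions", {
    set.seed(51)
    n_sg <- 400L; n_line <- 40L
    gene <- rep(paste0("G", 1:100), each = 4L)
    tp53 <- rep(c("mut", "wt"), each = n_line / 2)
    hr <- rep(c("mut", "wt"), times = n_line / 2)
    tissue <- sample(c("breast", "ovary", "pancreas", "prostate"), n_line,
                     replace = TRUE)
    d2 <- rnorm(n_sg, -0.3, 0.4)
    x <- as.numeric(runif(n_sg) < 0.5)
    ness <- paste0("G", 1:30)                 # offset reference genes
    ids <- paste0("sg", 1:n_sg)
    affected <- !(gene %in% ness)             # modelled locus set
    # planted on the locus set: TP53wt toxicity -0.3, alleviated by +0.15
    # in HRwt; the offset genes carry no planted effect, as the offset is a
    # pure depth term
    mu <- exp(log(300) + outer(0.3 * d2, rep(1, n_line)) +
              outer(-0.3 * affected, as.numeric(tp53 == "wt")) +
              outer(0.15 * affected, as.numeric(tp53 == "wt" & hr == "wt")))
    counts <- matrix(rnbinom(n_sg * n_line, mu = mu, size = 10), n_sg,
                     dimnames = list(ids, paste0("L", 1:n_line)))
    df <- prepareHRDesign(counts, gene, tp53, hr, tissue, ness, d2,
                          guides = ids[affected])
    fit <- fitTP53HR(df)
    est <- termEstimate(fit)
    expect_lt(abs(est$estimate - 0.15), 2.5 * est$se)
    sm <- termEstimate(fit, "status_main")
    expect_lt(abs(sm$estimate - (-0.3)), 2.5 * sm$se)
    # no tissue effect was planted: tissue terms compatible with zero
    tis <- coefTable(fit)[coefTable(fit)$role == "tissue", ]
    expect_true(all(abs(tis$estimate) < 4 * tis$se))
    # feature-by-HR: planted feature toxicity -0.2, alleviated +0.1 in HRwt
    mu2 <- exp(log(300) + outer(0.3 * d2, rep(1, n_line)) +
               outer(-0.2 * x * affected, rep(1, n_line)) +
               outer(0.1 * x * affected, as.numeric(hr == "wt")))
    counts2 <- matrix(rnbinom(n_sg * n_line, mu = mu2, size = 10), n_sg,
                      dimnames = dimnames(counts))
    df2 <- prepareHRDesign(counts2, gene, tp53, hr, tissue, ness, d2, x = x,
                           guides = ids[affected])
    fit2 <- fitFeatureHR(df2)
    est2 <- termEstimate(fit2)
    expect_lt(abs(est2$estimate - 0.1), 2.5 * est2$se)
    # single-tissue panels drop the tissue term with a warning
    expect_warning(fitTP53HR(transform(df, tissue = "breast")),
                   "single tissue")
})

test_that("FDR adjustment matches the step-up by hand and Storey shrinks toward BH", {
    expect_equal(adjustFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustFDR(rep(1, 5)), rep(1, 5))
    expect_equal(adjustFDR(0.03), 0.03)          # single p: q = p under BH
    expect_error(adjustFDR(c(0.5, 1.5)), "0, 1")
    # qvalue falls back to BH below 100 p-values
    p_small <- runif(50)
    expect_equal(adjustFDR(p_small, "qvalue"), adjustFDR(p_small))
    # with many true nulls plus signal, q <= BH and order is preserved
    set.seed(61)
    p <- c(runif(450), rbeta(50, 0.2, 8))
    q <- adjustFDR(p, "qvalue")
    bh <- adjustFDR(p)
    expect_true(all(q <= bh + 1e-12))
    expect_equal(order(q), order(bh))
    # fitTable collects terms and adjusts the interaction role
    se <- simScreen(110L, n_genes = 100L)
    f1 <- fitSim(se, model_id = "m1")
    tab <- fitTable(list(f1, f1))
    expect_true(all(c("model_id", "fdr") %in% colnames(tab)))
    expect_equal(sum(!is.na(tab$fdr)), 2L)
})
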