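#' Default run configuration
#'
#' All pipeline thresholds with their defaults: LFC cutoffs for target
#' (-0.5) and non-selected (0.5) calls, the off-target CFD percentile
#' (0.95), microhomology geometry (5/15/15), motif cap (5) and prevalence
#' threshold (0.10), FDR cutoff (0.25), conditional-hit SD threshold (2),
#' panel effect-size thresholds (-0.4 and +/-0.04), the normalization
#' reference mode and the seed.
#'
#' @return named list of defaults.
#' @export
defaultRunConfig <- function() {
    list(seed = 1L, n_genes = 250L, sgrnas_per_gene = 4L,
         n_nontargeting = 100L, lfc_target = -0.5, lfc_ns = 0.5,
         cfd_percentile = 0.95, mh_min = 5L, mh_max = 15L, mh_window = 15L,
         motif_cap = 5L, prevalence = 0.10, fdr = 0.25, sd_threshold = 2,
         panel_target = -0.4, panel_band = 0.04, pseudocount = 1,
         norm_reference = "nontargeting")
}

#' Read a plain-text run configuration
#'
#' Parses `key = value` lines (comments with `#`); unknown keys are an
#' error, missing keys take their defaults. Values are coerced to the type
#' of the default.
#'
#' @param path file path.
#' @return named list, see [defaultRunConfig()].
#' @export
readRunConfig <- function(path) {
    cfg <- defaultRunConfig()
    ln <- readLines(path)
    ln <- trimws(sub("#.*$", "", ln))
    ln <- ln[nzchar(ln)]
    for (l in ln) {
        kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L) stop("malformed config line: ", l)
        key <- trimws(kv[1L]); val <- trimws(kv[2L])
        if (!key %in% names(cfg)) stop("unknown config key: ", key)
        cfg[[key]] <- if (is.character(cfg[[key]])) val
                      else if (is.integer(cfg[[key]])) as.integer(val)
                      else as.numeric(val)
    }
    cfg
}

#' Serialize a run configuration
#'
#' @param cfg configuration list.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
    writeLines(paste(names(cfg), unlist(cfg), sep = " = "), path)
    invisible(path)
}

#' Run the full synthetic-screen analysis pipeline
#'
#' Executes the stages in dependency order on a simulated isogenic-pair
#' screen: simulate library/annotations/counts, write the screen tables,
#' median-normalize, compute all wt-vs-ko LFCs, call target / background /
#' non-selected loci, assemble the binned covariate table, fit the
#' genotype-by-feature NB interaction regression per chromatin feature
#' (bin-1 guides masked), FDR-adjust the interaction terms, calibrate
#' feature effects in copy-number-equivalent ploidy units, and score all
#' guides with the example linear toxicity score. Every output table is
#' stamped with the seed and a configuration hash; reruns with the same
#' seed are byte-identical.
#'
#' @param config configuration list (see [defaultRunConfig()]) or the path
#'   of a `key = value` config file.
#' @param outdir output directory.
#' @return named list of output paths plus the fit table, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(is.list(config))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    cfgfile <- file.path(outdir, "config.txt")
    writeRunConfig(config, cfgfile)
    stamp <- paste0("# dsbtox seed=", config$seed, " config_md5=",
                    unname(tools::md5sum(cfgfile)))
    log <- file.path(outdir, "run.log")
    logmsg <- function(...) cat(..., "\n", sep = "", file = log,
                                append = TRUE)
    cat("", file = log)

    simcfg <- SimConfig(n_genes = config$n_genes,
                        sgrnas_per_gene = config$sgrnas_per_gene,
                        n_nontargeting = config$n_nontargeting,
                        seed = config$seed)
    se <- simulateScreen(simcfg, EffectSpec())
    writeScreenTSV(se, file.path(outdir, "screen"))
    logmsg("simulated ", nrow(se), " sgRNAs x ", ncol(se), " samples")

    se <- medianNormalize(se, reference = config$norm_reference)
    pairs <- wtKoPairs(se)
    lfc <- computeLFC(se, pairs, pseudocount = config$pseudocount)
    out_lfc <- file.path(outdir, "lfc.tsv")
    writeTSV(data.frame(sgrna_id = rownames(lfc), lfc, check.names = FALSE),
             out_lfc, stamp)

    lib <- SummarizedExperiment::rowData(se)
    calls <- callLoci(lfc, lib, lfc_target = config$lfc_target,
                      lfc_ns = config$lfc_ns)
    out_calls <- file.path(outdir, "locus_calls.tsv")
    writeTSV(as.data.frame(locusLabels(calls)), out_calls, stamp)
    logmsg("targets: ", length(locusSet(calls, "target")),
           "; background: ", length(locusSet(calls, "background")),
           "; non-selected: ", length(locusSet(calls, "non_selected")))

    ann <- metadata(se)$annotations
    ftab <- assembleFeatureTable(lib, ann)
    cd <- SummarizedExperiment::colData(se)
    later <- cd$sample_id[cd$time_index > 0L]
    expo <- cd[later, "time_index"]

    ## analysis guide set: target + background loci when populated
    tb <- c(locusSet(calls, "target"), locusSet(calls, "background"))
    ids <- ftab$table$sgrna_id
    use <- if (length(tb) >= 50L) ids %in% tb else rep(TRUE, length(ids))
    d2 <- stats::setNames(ftab$table$d2, ids)
    fits <- list()
    for (m in intersect(.CHROMATIN_MARKS, sub("_bin$", "",
                        grep("_bin$", colnames(ftab$table), value = TRUE)))) {
        bin <- ftab$table[[paste0(m, "_bin")]]
        x <- ifelse(bin == 1L, NA_real_, as.numeric(bin == 2L))  # mask bin 1
        x[!use] <- NA_real_
        names(x) <- ids
        fits[[m]] <- tryCatch(
            fitFeatureInteraction(se, x, d2, samples = later,
                                  effect_exposure = expo, model_id = m),
            error = function(e) { logmsg("fit ", m, " failed: ",
                                         conditionMessage(e)); NULL })
    }
    xcn <- stats::setNames(as.numeric(ftab$table$cn_high), ids)
    xcn[!use] <- NA_real_
    fits$CN <- tryCatch(
        fitFeatureInteraction(se, xcn, d2, samples = later,
                              effect_exposure = expo, model_id = "CN"),
        error = function(e) NULL)
    fits <- fits[!vapply(fits, is.null, logical(1L))]
    tab <- fitTable(fits, fdr_role = "interaction")
    out_fits <- file.path(outdir, "fits.tsv")
    writeTSV(tab, out_fits, stamp)

    out_calib <- NULL
    if (!is.null(fits$CN)) {
        bcn <- termEstimate(fits$CN)$estimate
        marks <- setdiff(names(fits), "CN")
        if (length(marks) && is.finite(bcn) && bcn != 0) {
            betas <- vapply(fits[marks],
                            function(f) termEstimate(f)$estimate, numeric(1L))
            names(betas) <- marks
            out_calib <- file.path(outdir, "calibration.tsv")
            writeTSV(ploidyCalibrationTable(betas, bcn), out_calib, stamp)
        }
    }

    w <- scoreWeightsFromFits(fits)
    fm <- sapply(names(w), function(m) {
        if (m == "CN") as.numeric(ftab$table$cn_high)
        else as.numeric(ftab$table[[paste0(m, "_bin")]] == 2L)
    })
    rownames(fm) <- ids
    scores <- scoreSgRNA(fm, w)
    out_scores <- file.path(outdir, "scores.tsv")
    writeTSV(scores, out_scores, stamp)
    logmsg("done")

    invisible(list(screen_dir = file.path(outdir, "screen"), lfc = out_lfc,
                   locus_calls = out_calls, fits = out_fits,
                   calibration = out_calib, scores = out_scores,
                   fit_table = tab, config = cfgfile))
}
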