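#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Chromatin marks with per-sgRNA ChIP fold-enrichment style abundances that
## the simulator and the binning code know about.
.CHROMATIN_MARKS <- c("DHS", "H3K9ac", "H3K27ac", "H3K4me1", "H3K4me2",
                      "H3K4me3", "H4K20me1", "H2A.Z", "H3K79me2", "H3K36me3",
                      "H3K9me3", "H3K27me3")

#' Chromatin marks known to the simulator and binning code
#'
#' @return Character vector of mark names.
#' @export
chromatinMarks <- function() .CHROMATIN_MARKS

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Configuration of a synthetic isogenic-pair screen
#'
#' Describes the design of a simulated pooled CRISPR screen on a TP53
#' wild-type / knockout isogenic pair: library size, pseudo-replicate arms,
#' time points (first entry is the baseline), sequencing depth and
#' negative-binomial dispersion.
#'
#' @slot n_genes number of gene-targeting genes.
#' @slot sgrnas_per_gene guides per gene.
#' @slot n_nontargeting number of non-targeting control guides.
#' @slot pseudo_replicates labels of the pseudo-replicate (treatment) arms.
#' @slot time_points ordered time-point labels; the first is the baseline and
#'   receives effect multiplier 0, later points receive 1, 2, 3, ...
#' @slot genotypes genotype labels, reference first (default `ko`, `wt`).
#' @slot baseline_log_mean natural-log mean count of an unaffected guide
#'   (log(500) emulates 400-500x screening coverage).
#' @slot dispersion negative-binomial size parameter theta (> 0).
#' @slot context_length length (odd, nt) of the context window centred on the
#'   cut position.
#' @slot mh_fraction fraction of gene-targeting guides that carry a planted
#'   microhomology arm pair; `NA` leaves context sequences fully random.
#' @slot seed integer seed; identical seed + config give identical output.
#' @export
setClass("SimConfig", representation(
    n_genes = "integer",
    sgrnas_per_gene = "integer",
    n_nontargeting = "integer",
    pseudo_replicates = "character",
    time_points = "character",
    genotypes = "character",
    baseline_log_mean = "numeric",
    dispersion = "numeric",
    context_length = "integer",
    mh_fraction = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (object@n_genes < 1L) msg <- c(msg, "n_genes must be >= 1")
    if (object@sgrnas_per_gene < 1L)
        msg <- c(msg, "sgrnas_per_gene must be >= 1 (every gene has >= 1 sgRNA)")
    if (object@n_nontargeting < 0L) msg <- c(msg, "n_nontargeting must be >= 0")
    if (!is.finite(object@dispersion) || object@dispersion <= 0)
        msg <- c(msg, "dispersion (NB size theta) must be > 0")
    if (length(object@time_points) < 1L || anyDuplicated(object@time_points))
        msg <- c(msg, "time_points must be non-empty and unique (first = baseline)")
    if (length(object@genotypes) != 2L)
        msg <- c(msg, "exactly two genotypes are required (reference first)")
    if (length(object@pseudo_replicates) < 1L)
        msg <- c(msg, "at least one pseudo-replicate is required")
    if (object@context_length < 61L || object@context_length %% 2L == 0L)
        msg <- c(msg, "context_length must be odd and >= 61")
    if (!is.na(object@mh_fraction) &&
        (object@mh_fraction < 0 || object@mh_fraction > 1))
        msg <- c(msg, "mh_fraction must be in [0, 1] or NA")
    if (is.null(msg)) TRUE else msg
})

#' Create a synthetic-screen configuration
#'
#' Defaults emulate the isogenic-pair design this package models: three
#' pseudo-replicate arms, four time points (t0 baseline plus three later
#' points), two genotypes, 400-500x coverage and moderate count
#' overdispersion (theta = 10).
#'
#' @param n_genes,sgrnas_per_gene,n_nontargeting library composition.
#' @param pseudo_replicates,time_points,genotypes design labels; the first
#'   time point is the baseline, the first genotype the model reference.
#' @param baseline_log_mean natural-log mean count of an unaffected guide.
#' @param dispersion NB size parameter theta.
#' @param context_length odd window length (nt) centred on the cut.
#' @param mh_fraction fraction of guides with a planted microhomology pair
#'   (remaining guides are guaranteed microhomology-free); `NA` = random.
#' @param seed integer seed.
#' @return A [SimConfig-class] object.
#' @export
SimConfig <- function(n_genes = 1250L, sgrnas_per_gene = 4L,
                      n_nontargeting = 100L,
                      pseudo_replicates = c("pr1", "pr2", "pr3"),
                      time_points = c("t0", "t9", "t12", "t15"),
                      genotypes = c("ko", "wt"),
                      baseline_log_mean = log(500),
                      dispersion = 10,
                      context_length = 201L,
                      mh_fraction = NA_real_,
                      seed = 1L) {
    new("SimConfig",
        n_genes = as.integer(n_genes),
        sgrnas_per_gene = as.integer(sgrnas_per_gene),
        n_nontargeting = as.integer(n_nontargeting),
        pseudo_replicates = as.character(pseudo_replicates),
        time_points = as.character(time_points),
        genotypes = as.character(genotypes),
        baseline_log_mean = as.numeric(baseline_log_mean),
        dispersion = as.numeric(dispersion),
        context_length = as.integer(context_length),
        mh_fraction = as.numeric(mh_fraction),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@n_genes, "genes x", object@sgrnas_per_gene,
        "sgRNAs +", object@n_nontargeting, "non-targeting\n")
    cat("  arms:", paste(object@pseudo_replicates, collapse = ", "),
        "| time points:", paste(object@time_points, collapse = ", "), "\n")
    cat("  genotypes:", paste(object@genotypes, collapse = "/"),
        "| baseline log-mean:", format(object@baseline_log_mean, digits = 4),
        "| theta:", object@dispersion, "| seed:", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# EffectSpec
# ---------------------------------------------------------------------------

#' Planted effects of a synthetic screen
#'
#' Holds the generative coefficients of the simulator: per-feature carrier
#' fractions, main effects, genotype-by-feature interaction effects (acting in
#' the non-reference, wild-type genotype), the essentiality (D2) effect and
#' the latent cross-feature correlation used when drawing chromatin
#' abundances.
#'
#' @slot features data.frame with columns `feature`, `fraction`, `beta_main`,
#'   `beta_interaction`.
#' @slot beta_d2 essentiality slope on the D2 covariate.
#' @slot correlation named latent correlation matrix across features
#'   (positive semi-definite, unit diagonal).
#' @slot zero_inflation fraction of guides with zero abundance for each mark.
#' @export
setClass("EffectSpec", representation(
    features = "data.frame",
    beta_d2 = "numeric",
    correlation = "matrix",
    zero_inflation = "numeric"
))

setValidity("EffectSpec", function(object) {
    msg <- NULL
    f <- object@features
    need <- c("feature", "fraction", "beta_main", "beta_interaction")
    if (!all(need %in% names(f)))
        msg <- c(msg, paste("features must have columns",
                            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(f$feature)) msg <- c(msg, "duplicated feature names")
        if (any(f$fraction <= 0 | f$fraction >= 1))
            msg <- c(msg, "feature fractions must lie in (0, 1)")
    }
    cm <- object@correlation
    if (length(cm)) {
        if (is.null(rownames(cm)) || !identical(rownames(cm), colnames(cm)))
            msg <- c(msg, "correlation matrix must have matching dimnames")
        else if (max(abs(cm - t(cm))) > 1e-8)
            msg <- c(msg, "correlation matrix must be symmetric")
        else {
            if (any(abs(diag(cm) - 1) > 1e-8))
                msg <- c(msg, "correlation matrix must have unit diagonal")
            ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
            if (min(ev) < -1e-8)
                msg <- c(msg, "correlation matrix must be positive semi-definite")
        }
    }
    if (object@zero_inflation < 0 || object@zero_inflation >= 1)
        msg <- c(msg, "zero_inflation must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' Create a planted-effect specification
#'
#' The default plants a single accessible-chromatin feature (`DHS`) on half
#' of the guides with a genotype-interaction effect of -0.3 per time-index
#' unit (more toxic in the wild type), no feature main effect, and an
#' essentiality slope of 0.5 on the D2 score (lower D2 = more essential =
#' stronger dropout).
#'
#' @param features data.frame(feature, fraction, beta_main, beta_interaction).
#' @param beta_d2 essentiality slope.
#' @param correlation named latent correlation matrix across features
#'   (defaults to identity over the features present).
#' @param zero_inflation fraction of guides with zero mark abundance; the
#'   default 0.5 populates bin 0 and bins 1/2 about equally downstream.
#' @return An [EffectSpec-class] object.
#' @export
EffectSpec <- function(features = data.frame(feature = "DHS", fraction = 0.5,
                                             beta_main = 0,
                                             beta_interaction = -0.3),
                       beta_d2 = 0.5,
                       correlation = NULL,
                       zero_inflation = 0.5) {
    features$feature <- as.character(features$feature)
    if (is.null(correlation)) {
        correlation <- diag(nrow(features))
        dimnames(correlation) <- list(features$feature, features$feature)
    }
    new("EffectSpec", features = features, beta_d2 = as.numeric(beta_d2),
        correlation = correlation, zero_inflation = as.numeric(zero_inflation))
}

setMethod("show", "EffectSpec", function(object) {
    cat("EffectSpec with", nrow(object@features), "feature(s); beta_d2 =",
        object@beta_d2, "\n")
    print(object@features, row.names = FALSE)
})

# ---------------------------------------------------------------------------
# NBFit
# ---------------------------------------------------------------------------

#' Result of one negative-binomial toxicity regression
#'
#' @slot model_id short label of the fitted model.
#' @slot formula_str the model formula as a string.
#' @slot terms data.frame with one row per coefficient: `term`, `estimate`,
#'   `se`, `z`, `p`, and a `role` tag (`feature_main`, `status_main`,
#'   `interaction`, `d2`, `cofeature`, `tissue`, `intercept`, `other`).
#' @slot theta estimated NB dispersion (size); `NA` for the Poisson fallback.
#' @slot n_obs number of observations used.
#' @slot converged logical convergence flag.
#' @slot poisson_fallback `TRUE` when the NB fit failed and a Poisson GLM was
#'   reported instead.
#' @slot rank_deficient `TRUE` when coefficients were aliased (separation or
#'   collinearity).
#' @export
setClass("NBFit", representation(
    model_id = "character",
    formula_str = "character",
    terms = "data.frame",
    theta = "numeric",
    n_obs = "integer",
    converged = "logical",
    poisson_fallback = "logical",
    rank_deficient = "logical"
))

setValidity("NBFit", function(object) {
    msg <- NULL
    tt <- object@terms
    need <- c("term", "estimate", "se", "z", "p", "role")
    if (!all(need %in% names(tt)))
        msg <- c(msg, paste("terms must have columns", paste(need, collapse = ", ")))
    else {
        ok <- is.finite(tt$p)
        if (any(tt$p[ok] < 0 | tt$p[ok] > 1)) msg <- c(msg, "p-values outside [0, 1]")
        if (object@converged && any(is.finite(tt$se) & tt$se <= 0))
            msg <- c(msg, "converged fit must have positive SEs")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "NBFit", function(object) {
    cat("NBFit '", object@model_id, "': ", object@formula_str, "\n", sep = "")
    cat("  n =", object@n_obs, "| theta =",
        ifelse(is.na(object@theta), "NA (Poisson fallback)",
               format(object@theta, digits = 4)),
        "| converged:", object@converged, "\n")
    key <- object@terms[object@terms$role %in%
                        c("feature_main", "status_main", "interaction"), ]
    if (nrow(key)) print(key, row.names = FALSE, digits = 4)
})

#' @describeIn NBFit-class coefficient table (one row per term).
#' @param object,x an `NBFit`.
#' @export
setGeneric("coefTable", function(object) standardGeneric("coefTable"))

#' @rdname NBFit-class
#' @export
setMethod("coefTable", "NBFit", function(object) object@terms)

#' @describeIn NBFit-class estimate/SE/p of the term with a given role
#'   (default the genotype-by-feature interaction).
#' @param role term role to extract.
#' @export
setGeneric("termEstimate",
           function(object, role = "interaction") standardGeneric("termEstimate"))

#' @rdname NBFit-class
#' @export
setMethod("termEstimate", "NBFit", function(object, role = "interaction") {
    row <- object@terms[object@terms$role == role, , drop = FALSE]
    if (!nrow(row)) stop("no term with role '", role, "' in model ",
                         object@model_id)
    row[1L, , drop = FALSE]
})

#' @describeIn NBFit-class estimated NB dispersion theta.
#' @export
setGeneric("dispersionTheta", function(object) standardGeneric("dispersionTheta"))

#' @rdname NBFit-class
#' @export
setMethod("dispersionTheta", "NBFit", function(object) object@theta)

#' @describeIn NBFit-class convergence flag.
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname NBFit-class
#' @export
setMethod("isConverged", "NBFit", function(object) object@converged)

# ---------------------------------------------------------------------------
# LocusCalls
# ---------------------------------------------------------------------------

#' Per-sgRNA toxic-locus classification
#'
#' Partition of a guide library into `target` (p53-toxic), `background`
#' (same-gene non-toxic controls), `non_selected` and `unclassified` guides,
#' with the provenance of every exclusion-filter removal.
#'
#' @slot calls DataFrame with columns `sgrna_id`, `gene`, `label`, and
#'   `filters_failed` (comma-separated tags, `""` if none).
#' @slot thresholds list of the thresholds used (lfc_target, lfc_ns,
#'   cfd_cutoff, ...).
#' @export
setClass("LocusCalls", representation(
    calls = "DataFrame",
    thresholds = "list"
))

setValidity("LocusCalls", function(object) {
    msg <- NULL
    cc <- object@calls
    need <- c("sgrna_id", "gene", "label", "filters_failed")
    if (!all(need %in% colnames(cc)))
        msg <- c(msg, paste("calls must have columns", paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(cc$sgrna_id))
            msg <- c(msg, "labels must be mutually exclusive (one row per sgRNA)")
        bad <- setdiff(unique(cc$label),
                       c("target", "background", "non_selected", "unclassified"))
        if (length(bad)) msg <- c(msg, paste("unknown label:", bad[1L]))
        tg <- cc$gene[cc$label == "target"]
        bg <- cc$gene[cc$label == "background"]
        if (length(bg) && !all(bg %in% tg))
            msg <- c(msg, "background sgRNAs must share a gene with >= 1 target")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "LocusCalls", function(object) {
    tab <- table(factor(object@calls$label,
                        levels = c("target", "background", "non_selected",
                                   "unclassified")))
    cat("LocusCalls over", nrow(object@calls), "sgRNAs:\n")
    print(tab)
    if (!is.null(object@thresholds$cfd_cutoff))
        cat("  CFD cutoff (95th pct of non-selected):",
            format(object@thresholds$cfd_cutoff, digits = 4), "\n")
})

#' @describeIn LocusCalls-class the calls table.
#' @param object a `LocusCalls`.
#' @export
setGeneric("locusLabels", function(object) standardGeneric("locusLabels"))

#' @rdname LocusCalls-class
#' @export
setMethod("locusLabels", "LocusCalls", function(object) object@calls)

#' @describeIn LocusCalls-class sgRNA ids carrying a given label.
#' @param label one of target, background, non_selected, unclassified.
#' @export
setGeneric("locusSet", function(object, label) standardGeneric("locusSet"))

#' @rdname LocusCalls-class
#' @export
setMethod("locusSet", "LocusCalls", function(object, label) {
    label <- match.arg(label, c("target", "background", "non_selected",
                                "unclassified"))
    as.character(object@calls$sgrna_id[object@calls$label == label])
})
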