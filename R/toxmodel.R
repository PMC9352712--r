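## ---------------------------------------------------------------------------
## Negative-binomial toxicity regressions
##
## All models regress raw sgRNA counts on locus covariates with a log link
## and a fixed per-sample exposure offset (the natural log of the total
## non-targeting counts), so sequencing depth is absorbed by the offset and
## counts stay raw. Dispersion is a single ML-estimated theta per model.
## ---------------------------------------------------------------------------

## coerce a covariate to a 0/1 (or numeric) regressor; reference = absence
.covariateNumeric <- function(v, what = "feature") {
    nm <- names(v)
    out <- if (is.logical(v)) {
        as.numeric(v)
    } else if (is.factor(v)) {
        if (nlevels(droplevels(v)) > 2L)
            stop(what, " has more than two levels; binarize it first")
        as.numeric(v == levels(droplevels(v))[2L])
    } else as.numeric(v)
    names(out) <- nm
    out
}

## align a per-sgRNA covariate with the experiment rows: named vectors are
## matched by sgRNA id (guides not named get NA and drop out), unnamed
## vectors must cover every row
.alignCovariate <- function(v, se, what = "covariate") {
    if (!is.null(names(v))) {
        out <- rep(NA_real_, nrow(se))
        idx <- match(names(v), rownames(se))
        if (anyNA(idx))
            stop(what, " names do not match sgRNA ids: ",
                 names(v)[is.na(idx)][1L])
        out[idx] <- as.numeric(v)
        out
    } else if (length(v) == nrow(se)) {
        as.numeric(v)
    } else stop(what, " must be named by sgRNA id or have one entry per row")
}

## long table: one row per (gene-targeting sgRNA, sample)
.longData <- function(se, x, d2, samples = NULL, cofeature = NULL,
                      effect_exposure = NULL) {
    x <- .alignCovariate(x, se, "x")
    d2 <- .alignCovariate(d2, se, "d2")
    if (!is.null(cofeature))
        cofeature <- .alignCovariate(cofeature, se, "cofeature")
    cd <- SummarizedExperiment::colData(se)
    if (is.null(samples)) {
        samples <- if (!is.null(cd$time_index)) cd$sample_id[cd$time_index > 0L]
                   else cd$sample_id
    }
    counts <- SummarizedExperiment::assay(se, "counts")[, samples, drop = FALSE]
    cds <- cd[samples, , drop = FALSE]
    keep <- !is.na(x) & !is.na(d2)
    if (!is.null(cofeature)) keep <- keep & !is.na(cofeature)
    ng <- sum(keep)
    ns <- length(samples)
    expo <- if (is.null(effect_exposure)) rep(1, ns)
            else rep_len(as.numeric(effect_exposure), ns)
    df <- data.frame(
        count = as.vector(counts[keep, , drop = FALSE]),
        x = rep(x[keep], times = ns) * rep(expo, each = ng),
        d2 = rep(d2[keep], times = ns) * rep(expo, each = ng),
        genotype = factor(rep(as.character(cds$genotype), each = ng),
                          levels = levels(cds$genotype)),
        expo = rep(expo, each = ng),
        off = rep(cds$offset, each = ng))
    if (!is.null(cofeature))
        df$xco <- rep(cofeature[keep], times = ns) * rep(expo, each = ng)
    attr(df, "n_dropped") <- sum(!keep)
    df
}

## when the exposure varies across samples, the scaled covariates acquire a
## sample-level mean component; exposure main (and exposure:genotype) terms
## absorb per-sample depth/offset noise along that component so the feature
## terms stay identified by within-sample contrasts
.hasExposure <- function(df) length(unique(df$expo)) > 1L

## fit NB GLM (ML theta, or fixed when supplied) with Poisson fallback;
## build an NBFit
.fitNBModel <- function(formula, df, model_id, roles,
                        maxit = 100L, tol = 1e-8, theta = NULL) {
    poisson_fallback <- FALSE
    fit <- if (!is.null(theta)) {
        tryCatch(suppressWarnings(stats::glm(
            formula, data = df, family = MASS::negative.binomial(theta),
            control = stats::glm.control(epsilon = tol, maxit = maxit))),
            error = function(e) NULL)
    } else {
        tryCatch(suppressWarnings(MASS::glm.nb(
            formula, data = df,
            control = stats::glm.control(epsilon = tol, maxit = maxit))),
            error = function(e) NULL)
    }
    if (is.null(fit)) {
        poisson_fallback <- TRUE
        fit <- stats::glm(formula, data = df, family = stats::poisson())
    }
    if (!is.null(theta) && !poisson_fallback) fit$theta <- theta
    sm <- summary(fit)
    co <- stats::coef(sm)
    all_names <- names(stats::coef(fit))
    rank_deficient <- any(is.na(stats::coef(fit)))
    tt <- data.frame(term = all_names,
                     estimate = stats::coef(fit)[all_names],
                     se = NA_real_, z = NA_real_, p = NA_real_,
                     role = "other", row.names = NULL)
    got <- match(rownames(co), tt$term)
    tt$se[got] <- co[, 2L]; tt$z[got] <- co[, 3L]; tt$p[got] <- co[, 4L]
    for (r in names(roles)) {
        hit <- which(tt$term %in% roles[[r]])
        if (length(hit)) tt$role[hit] <- r
    }
    tt$role[tt$term == "(Intercept)"] <- "intercept"
    new("NBFit", model_id = model_id,
        formula_str = paste(deparse(formula), collapse = ""),
        terms = tt,
        theta = if (poisson_fallback) NA_real_ else fit$theta,
        n_obs = as.integer(stats::nobs(fit)),
        converged = isTRUE(fit$converged) && !rank_deficient,
        poisson_fallback = poisson_fallback,
        rank_deficient = rank_deficient)
}

.roleNames <- function(df, with_status = TRUE, status_var = "genotype") {
    lv2 <- if (status_var %in% names(df) && is.factor(df[[status_var]]))
        paste0(status_var, levels(df[[status_var]])[2L]) else NULL
    roles <- list(feature_main = "x", d2 = "d2", cofeature = "xco",
                  exposure = "expo")
    if (with_status && !is.null(lv2)) {
        roles$status_main <- lv2
        roles$interaction <- c(paste0("x:", lv2), paste0(lv2, ":x"))
        roles$cofeature_interaction <- c(paste0("xco:", lv2),
                                         paste0(lv2, ":xco"))
        roles$exposure <- c("expo", paste0("expo:", lv2),
                            paste0(lv2, ":expo"))
    }
    roles
}

#' Fit the genotype-by-feature interaction model
#'
#' The central toxicity regression: raw sgRNA counts against a locus
#' feature, TP53 status and their interaction, adjusting for gene
#' essentiality (D2) with the per-sample log total non-targeting counts as
#' offset --
#' `counts ~ feature * TP53_status + D2 + offset`.
#' The reported interaction coefficient measures the extra log-count change
#' per feature unit in the wild type relative to the knockout: negative
#' values mean the feature increases p53-dependent cut toxicity. Reference
#' levels are feature absent and the knockout genotype.
#'
#' When the counts span several later time points of a time course in which
#' selection accumulates, `effect_exposure` supplies the per-sample
#' exposure multiplier (e.g. the time index); effect covariates are scaled
#' by it so the coefficient is a per-exposure-unit effect, and exposure
#' main-effect and exposure-by-genotype terms are added so that per-sample
#' depth/offset noise cannot leak into the scaled covariates (which
#' otherwise acquire a sample-level mean component). The default
#' (1 everywhere) reproduces the plain cross-sectional model.
#'
#' @param se a raw-count [SummarizedExperiment::SummarizedExperiment] whose
#'   colData has `genotype` (factor, reference = knockout first) and
#'   `offset`.
#' @param x numeric/logical/2-level-factor feature vector, one entry per
#'   sgRNA (NA drops the guide; apply drop masks by setting NA).
#' @param d2 per-sgRNA D2 essentiality covariate.
#' @param samples sample ids to use; default: all later-time-point samples.
#' @param effect_exposure optional per-sample exposure multiplier (aligned
#'   with `samples`).
#' @param model_id label for the fit.
#' @param theta optional fixed NB dispersion; the default estimates theta
#'   by maximum likelihood.
#' @return An [NBFit-class]; the interaction term carries role
#'   `interaction`.
#' @export
fitFeatureInteraction <- function(se, x, d2, samples = NULL,
                                  effect_exposure = NULL,
                                  model_id = "feature_x_status",
                                  theta = NULL) {
    x <- .covariateNumeric(x)
    df <- .longData(se, x, d2, samples, effect_exposure = effect_exposure)
    if (nlevels(droplevels(df$genotype)) < 2L)
        stop("both genotypes must be present")
    form <- if (.hasExposure(df))
        count ~ x * genotype + expo + expo:genotype + d2 + offset(off)
    else count ~ x * genotype + d2 + offset(off)
    .fitNBModel(form, df, model_id, .roleNames(df), theta = theta)
}

#' Fit the wild-type-only per-feature model
#'
#' `wt counts ~ feature + D2 + offset`: the toxicity of a feature per se in
#' the TP53 wild type alone, without a status term.
#'
#' @inheritParams fitFeatureInteraction
#' @export
fitWtOnly <- function(se, x, d2, samples = NULL, effect_exposure = NULL,
                      model_id = "feature_wt_only") {
    x <- .covariateNumeric(x)
    cd <- SummarizedExperiment::colData(se)
    wt <- levels(cd$genotype)[2L]
    if (is.null(samples)) {
        samples <- if (!is.null(cd$time_index))
            cd$sample_id[cd$time_index > 0L & cd$genotype == wt]
        else cd$sample_id[cd$genotype == wt]
    } else samples <- samples[cd[samples, "genotype"] == wt]
    if (!length(samples)) stop("no wild-type samples selected")
    df <- .longData(se, x, d2, samples, effect_exposure = effect_exposure)
    if (length(unique(df$x[!is.na(df$x)])) < 2L)
        stop("feature has a single level in the selected data")
    form <- if (.hasExposure(df)) count ~ x + expo + d2 + offset(off)
            else count ~ x + d2 + offset(off)
    .fitNBModel(form, df, model_id, .roleNames(df, with_status = FALSE))
}

#' Fit the interaction model conditioned on a second feature
#'
#' Adds one co-feature to the interaction model, either with its own
#' TP53 interaction (`interaction_mode = TRUE`) or as a main effect only,
#' and reports the primary feature's terms as usual. Aliased coefficients
#' (e.g. a co-feature collinear with the feature) flag the fit
#' rank-deficient.
#'
#' @inheritParams fitFeatureInteraction
#' @param cofeature second feature vector (same conventions as `x`).
#' @param interaction_mode include `cofeature:TP53` as well.
#' @export
fitPairwiseConditioned <- function(se, x, cofeature, d2, samples = NULL,
                                   effect_exposure = NULL,
                                   interaction_mode = TRUE,
                                   model_id = "feature_pairwise") {
    x <- .covariateNumeric(x)
    cofeature <- .covariateNumeric(cofeature, "cofeature")
    df <- .longData(se, x, d2, samples, cofeature = cofeature,
                    effect_exposure = effect_exposure)
    expo_terms <- if (.hasExposure(df)) "expo + expo:genotype + "
                  else ""
    form <- stats::as.formula(paste0(
        "count ~ x * genotype + ",
        if (interaction_mode) "xco * genotype + " else "xco + ",
        expo_terms, "d2 + offset(off)"))
    .fitNBModel(form, df, model_id, .roleNames(df))
}

#' Fit status-only and D2-only baseline models
#'
#' `counts ~ TP53_status + D2 + offset` captures the global wild-type
#' toxicity; `counts ~ D2 + offset` the essentiality effect alone.
#'
#' @inheritParams fitFeatureInteraction
#' @export
fitStatusOnly <- function(se, d2, samples = NULL, effect_exposure = NULL,
                          model_id = "status_only") {
    df <- .longData(se, rep(0, length(d2)), d2, samples,
                    effect_exposure = effect_exposure)
    roles <- .roleNames(df)
    roles$interaction <- NULL; roles$feature_main <- NULL
    .fitNBModel(count ~ genotype + d2 + offset(off), df, model_id, roles)
}

#' @rdname fitStatusOnly
#' @export
fitD2Only <- function(se, d2, samples = NULL, effect_exposure = NULL,
                      model_id = "d2_only") {
    df <- .longData(se, rep(0, length(d2)), d2, samples,
                    effect_exposure = effect_exposure)
    .fitNBModel(count ~ d2 + offset(off), df, model_id, list(d2 = "d2"))
}

#' Fit the TP53-by-HR panel model
#'
#' Cell-line-panel regression
#' `counts ~ TP53_status * HR_status + D2 + tissue + offset`,
#' with tissue as a correcting categorical variable (breast as reference
#' level) and the per-line offset based on the total read counts of the
#' known non-essential genes. Reference levels of both statuses are mutant,
#' so the interaction measures how the wild-type-HR background changes the
#' TP53wt toxicity.
#'
#' @param df long data.frame from [prepareHRDesign()], with columns
#'   `count`, `tp53` (factor mut/wt), `hr` (factor mut/wt), `d2`, `tissue`,
#'   `off`.
#' @param model_id label.
#' @return An [NBFit-class]; `tp53wt:hrwt` carries role `interaction`.
#' @export
fitTP53HR <- function(df, model_id = "tp53_x_hr") {
    stopifnot(all(c("count", "tp53", "hr", "d2", "tissue", "off") %in%
                  names(df)))
    single_tissue <- nlevels(droplevels(factor(df$tissue))) < 2L
    roles <- list(
        status_main = paste0("tp53", levels(df$tp53)[2L]),
        hr_main = paste0("hr", levels(df$hr)[2L]),
        interaction = c(paste0("tp53", levels(df$tp53)[2L], ":hr",
                               levels(df$hr)[2L]),
                        paste0("hr", levels(df$hr)[2L], ":tp53",
                               levels(df$tp53)[2L])),
        d2 = "d2")
    form <- if (single_tissue) {
        warning("single tissue in the panel; tissue term dropped")
        count ~ tp53 * hr + d2 + offset(off)
    } else count ~ tp53 * hr + d2 + tissue + offset(off)
    fit <- .fitNBModel(form, df, model_id, roles)
    fit@terms$role[grepl("^tissue", fit@terms$term)] <- "tissue"
    validObject(fit)
    fit
}

#' Fit the feature-by-HR panel model
#'
#' `counts ~ feature * HR_status + D2 + tissue + offset`. Positive
#' interaction coefficients indicate that the extra cut toxicity of a
#' feature is alleviated in HR-proficient cells.
#'
#' @param df long data.frame with columns `count`, `x`, `hr`, `d2`,
#'   `tissue`, `off` (see [prepareHRDesign()]).
#' @param model_id label.
#' @export
fitFeatureHR <- function(df, model_id = "feature_x_hr") {
    stopifnot(all(c("count", "x", "hr", "d2", "tissue", "off") %in%
                  names(df)))
    df$x <- .covariateNumeric(df$x)
    single_tissue <- nlevels(droplevels(factor(df$tissue))) < 2L
    lv2 <- paste0("hr", levels(df$hr)[2L])
    roles <- list(feature_main = "x", hr_main = lv2,
                  interaction = c(paste0("x:", lv2), paste0(lv2, ":x")),
                  d2 = "d2")
    form <- if (single_tissue) {
        warning("single tissue in the panel; tissue term dropped")
        count ~ x * hr + d2 + offset(off)
    } else count ~ x * hr + d2 + tissue + offset(off)
    fit <- .fitNBModel(form, df, model_id, roles)
    fit@terms$role[grepl("^tissue", fit@terms$term)] <- "tissue"
    validObject(fit)
    fit
}

#' False-discovery-rate adjustment
#'
#' `"bh"` is the Benjamini-Hochberg monotone step-up (the default).
#' `"qvalue"` is a Storey q-value: pi0 is estimated on a lambda grid
#' (0.05-0.95) with a cubic smoothing spline evaluated at the largest
#' lambda, and q = pi0 x BH; when fewer than 100 p-values are supplied or
#' the pi0 estimate is unstable, it falls back to BH (pi0 = 1).
#'
#' @param p numeric vector of p-values.
#' @param method `"bh"` or `"qvalue"`.
#' @return numeric vector of q-values.
#' @export
adjustFDR <- function(p, method = c("bh", "qvalue")) {
    method <- match.arg(method)
    if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
    bh <- stats::p.adjust(p, method = "BH")
    if (method == "bh") return(bh)
    ok <- !is.na(p)
    if (sum(ok) < 100L) return(bh)
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0l <- vapply(lambda, function(l) mean(p[ok] > l) / (1 - l), numeric(1L))
    pi0 <- tryCatch({
        sp <- stats::smooth.spline(lambda, pi0l, df = 3)
        stats::predict(sp, x = max(lambda))$y
    }, error = function(e) NA_real_)
    if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) return(bh)
    pmin(pi0 * bh, 1)
}

#' Collect fit results into one table
#'
#' One row per model and term, with FDR over a chosen role across models.
#'
#' @param fits list of [NBFit-class] objects.
#' @param fdr_role term role to FDR-adjust across models (default the
#'   interaction), or `NULL` for no adjustment.
#' @param method FDR method, see [adjustFDR()].
#' @return data.frame with columns `model_id`, `term`, `role`, `estimate`,
#'   `se`, `z`, `p`, `theta`, `converged`, and `fdr` for the adjusted role.
#' @export
fitTable <- function(fits, fdr_role = "interaction", method = "bh") {
    rows <- lapply(fits, function(f) {
        tt <- coefTable(f)
        tt$model_id <- f@model_id
        tt$theta <- f@theta
        tt$converged <- f@converged
        tt
    })
    out <- do.call(rbind, rows)
    out <- out[, c("model_id", "term", "role", "estimate", "se", "z", "p",
                   "theta", "converged")]
    if (!is.null(fdr_role)) {
        out$fdr <- NA_real_
        sel <- out$role == fdr_role
        out$fdr[sel] <- adjustFDR(out$p[sel], method)
    }
    rownames(out) <- NULL
    out
}
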