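#' Call p53-toxic target loci from wild-type-versus-knockout LFCs
#'
#' An sgRNA is negatively selected in the TP53 wild type relative to the
#' knockout -- a target locus -- when its LFC is below the threshold in
#' every comparison (every pseudo-replicate at every later time point;
#' 3 x 3 = 9 comparisons in the default design).
#'
#' @param lfc numeric matrix, sgRNAs x comparisons, from [computeLFC()] over
#'   all wt-vs-ko comparisons.
#' @param threshold LFC threshold (default -0.5).
#' @param required_comparisons optional character vector of comparison
#'   column names that must be present; missing ones are an error.
#' @return character vector of target sgRNA ids.
#' @export
callTargetLoci <- function(lfc, threshold = -0.5,
                           required_comparisons = NULL) {
    .checkComparisons(lfc, required_comparisons)
    hit <- rowSums(lfc < threshold) == ncol(lfc) & stats::complete.cases(lfc)
    rownames(lfc)[hit]
}

#' Call confidently non-selected loci
#'
#' sgRNAs with `|LFC| < threshold` in every comparison; disjoint from the
#' target set by construction.
#'
#' @inheritParams callTargetLoci
#' @param threshold absolute LFC bound (default 0.5).
#' @return character vector of non-selected sgRNA ids.
#' @export
callNonSelected <- function(lfc, threshold = 0.5,
                            required_comparisons = NULL) {
    .checkComparisons(lfc, required_comparisons)
    hit <- rowSums(abs(lfc) < threshold) == ncol(lfc) &
        stats::complete.cases(lfc)
    rownames(lfc)[hit]
}

.checkComparisons <- function(lfc, required) {
    if (is.null(dim(lfc)) || is.null(rownames(lfc)))
        stop("lfc must be a matrix with sgRNA row names")
    if (!is.null(required)) {
        missing <- setdiff(required, colnames(lfc))
        if (length(missing))
            stop("missing comparison columns: ",
                 paste(missing, collapse = ", "))
    }
}

#' Define background loci for a target set
#'
#' Background loci are all gene-targeting sgRNAs in genes that contain at
#' least one target sgRNA, minus the target sgRNAs themselves: same-gene
#' controls that do not show the TP53-dependent toxicity.
#'
#' @param targets character vector of target sgRNA ids.
#' @param library guide table with columns `sgrna_id`, `gene`,
#'   `is_nontargeting`.
#' @param exclude_positive optional LFC matrix; when supplied, sgRNAs
#'   positively selected in every comparison (`LFC > +0.5`) are excluded
#'   from the background (off by default).
#' @return character vector of background sgRNA ids.
#' @export
defineBackground <- function(targets, library, exclude_positive = NULL) {
    if (!all(targets %in% library$sgrna_id))
        stop("targets must be a subset of the library")
    tg_genes <- unique(library$gene[library$sgrna_id %in% targets])
    tg_genes <- tg_genes[!is.na(tg_genes)]
    bg <- library$sgrna_id[!library$is_nontargeting &
                           library$gene %in% tg_genes &
                           !(library$sgrna_id %in% targets)]
    if (!is.null(exclude_positive)) {
        pos <- rownames(exclude_positive)[
            rowSums(exclude_positive > 0.5) == ncol(exclude_positive) &
            stats::complete.cases(exclude_positive)]
        bg <- setdiff(bg, pos)
    }
    as.character(bg)
}

#' Remove target loci in excluded gene sets and gene families
#'
#' Drops target sgRNAs located within TP53-interactor genes, genes from
#' enriched GO terms, or gene families prone to paralogous sequence
#' (olfactory receptor OR*, ubiquitin-specific peptidase USP*, family with
#' sequence similarity FAM* by default). Symbols are compared
#' case-insensitively; every removal is tagged with the responsible filter.
#'
#' @param targets character vector of target sgRNA ids.
#' @param library guide table with `sgrna_id` and `gene`.
#' @param tp53_interactors,go_genes gene symbol vectors (may be empty).
#' @param family_prefixes symbol prefixes removed as families; a prefix
#'   matches `<PREFIX><digit...>` symbols.
#' @param family_overrides symbols exempted from the family rule.
#' @return list with `kept` (sgRNA ids) and `removed` (data.frame
#'   `sgrna_id`, `gene`, `filter`).
#' @export
applyExclusionFilters <- function(targets, library,
                                  tp53_interactors = character(),
                                  go_genes = character(),
                                  family_prefixes = c("OR", "USP", "FAM"),
                                  family_overrides = character()) {
    gene <- toupper(library$gene[match(targets, library$sgrna_id)])
    tp53_interactors <- toupper(tp53_interactors)
    go_genes <- toupper(go_genes)
    family_overrides <- toupper(family_overrides)
    fam_re <- if (length(family_prefixes))
        paste0("^(", paste(family_prefixes, collapse = "|"), ")[0-9]")
    else NULL
    filt <- character(length(targets))
    filt[!is.na(gene) & gene %in% tp53_interactors] <- "tp53_interactor"
    todo <- filt == "" & !is.na(gene) & gene %in% go_genes
    filt[todo] <- "go_term"
    if (!is.null(fam_re)) {
        todo <- filt == "" & !is.na(gene) & grepl(fam_re, gene) &
            !(gene %in% family_overrides)
        filt[todo] <- "gene_family"
    }
    list(kept = targets[filt == ""],
         removed = data.frame(sgrna_id = targets[filt != ""],
                              gene = gene[filt != ""],
                              filter = filt[filt != ""]))
}

#' Remove high-off-targeting target loci
#'
#' A target sgRNA is removed when it has any exact-match off-target and/or a
#' total CFD score (sum of the CFD scores of its top-5 off-targets) above
#' the 95th percentile of the non-selected loci. The percentile uses linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param targets character vector of target sgRNA ids.
#' @param profiles data.frame with columns `sgrna_id`,
#'   `has_exact_offtarget_match` (logical), `total_cfd` (>= 0); must cover
#'   targets and non-selected loci.
#' @param non_selected character vector of non-selected sgRNA ids (defines
#'   the cutoff).
#' @param probs percentile for the cutoff (default 0.95).
#' @return list with `kept`, `removed` (data.frame `sgrna_id`, `reason`) and
#'   `cutoff`.
#' @export
offtargetFilter <- function(targets, profiles, non_selected, probs = 0.95) {
    if (!length(non_selected)) stop("non_selected set is empty")
    need <- unique(c(targets, non_selected))
    if (!all(need %in% profiles$sgrna_id))
        stop("profiles must cover all target and non-selected sgRNAs")
    if (any(profiles$total_cfd < 0)) stop("total_cfd must be >= 0")
    idx <- match(non_selected, profiles$sgrna_id)
    cutoff <- unname(stats::quantile(profiles$total_cfd[idx], probs = probs,
                                     type = 7L))
    ti <- match(targets, profiles$sgrna_id)
    exact <- profiles$has_exact_offtarget_match[ti]
    high <- profiles$total_cfd[ti] > cutoff
    reason <- ifelse(exact & high, "offtarget_exact,offtarget_cfd",
              ifelse(exact, "offtarget_exact",
              ifelse(high, "offtarget_cfd", "")))
    list(kept = targets[reason == ""],
         removed = data.frame(sgrna_id = targets[reason != ""],
                              reason = reason[reason != ""]),
         cutoff = cutoff)
}

#' Classify a whole library into locus classes
#'
#' Runs the full calling chain: target and non-selected calls from the LFC
#' matrix, exclusion filters, the off-target CFD filter (when profiles are
#' given), and background definition from the surviving targets. Guides in
#' none of the three classes are `unclassified`; removed targets are
#' unclassified with their filter recorded.
#'
#' @inheritParams callTargetLoci
#' @param library guide table (`sgrna_id`, `gene`, `is_nontargeting`).
#' @param tp53_interactors,go_genes,family_prefixes see
#'   [applyExclusionFilters()].
#' @param profiles optional off-target profile table, see
#'   [offtargetFilter()].
#' @param lfc_target,lfc_ns thresholds for the target and non-selected
#'   calls.
#' @return A [LocusCalls-class].
#' @export
callLoci <- function(lfc, library, lfc_target = -0.5, lfc_ns = 0.5,
                     tp53_interactors = character(),
                     go_genes = character(),
                     family_prefixes = c("OR", "USP", "FAM"),
                     profiles = NULL) {
    targets <- callTargetLoci(lfc, lfc_target)
    nonsel <- callNonSelected(lfc, lfc_ns)
    ex <- applyExclusionFilters(targets, library, tp53_interactors, go_genes,
                                family_prefixes)
    removed <- ex$removed
    names(removed)[names(removed) == "filter"] <- "reason"
    removed$gene <- NULL
    cutoff <- NULL
    kept <- ex$kept
    if (!is.null(profiles)) {
        ot <- offtargetFilter(kept, profiles, nonsel)
        kept <- ot$kept
        removed <- rbind(removed, ot$removed)
        cutoff <- ot$cutoff
    }
    bg <- defineBackground(kept, library)
    label <- rep("unclassified", nrow(library))
    names(label) <- library$sgrna_id
    label[nonsel] <- "non_selected"
    label[bg] <- "background"
    label[removed$sgrna_id] <- "unclassified"   # filtered-out targets drop out
    label[kept] <- "target"
    filters <- setNames(rep("", nrow(library)), library$sgrna_id)
    filters[removed$sgrna_id] <- removed$reason
    calls <- DataFrame(sgrna_id = library$sgrna_id,
                       gene = library$gene,
                       label = unname(label),
                       filters_failed = unname(filters),
                       row.names = library$sgrna_id)
    new("LocusCalls", calls = calls,
        thresholds = list(lfc_target = lfc_target, lfc_ns = lfc_ns,
                          cfd_cutoff = cutoff))
}
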