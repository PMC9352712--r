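#' Enumerate microhomology arm pairs flanking a cut site
#'
#' Finds every pair of identical sequences (arms) of length `min_len` to
#' `max_len` where one arm lies entirely 5' of the cut and the other entirely
#' 3' of it, and the cut-proximal end of each arm is within `window` bp of
#' the cut. Such arm pairs make the site a candidate for
#' microhomology-mediated end joining (MMEJ) upon a double-strand break.
#' Arms containing `N` never match. Both maximal and non-maximal arms are
#' reported; the result is unique by (arm sequence, offsets).
#'
#' Offsets count the bases between the cut and the arm's cut-proximal end
#' (0 = arm abuts the cut), and the proximal-end constraint is
#' `offset <= window` for both arms.
#'
#' @param context_seq a single character string over A/C/G/T/N.
#' @param cut_index 1-based index of the base immediately 5' of the blunt
#'   cut; must satisfy `1 <= cut_index < nchar(context_seq)`.
#' @param min_len,max_len arm length bounds (bp), default 5-15.
#' @param window maximum distance (bp) of each arm's cut-proximal end from
#'   the cut, default 15.
#' @return data.frame with columns `arm_seq`, `arm_len`, `upstream_offset`,
#'   `downstream_offset`; zero rows when the site has no microhomology.
#' @export
findMHPairs <- function(context_seq, cut_index, min_len = 5L, max_len = 15L,
                        window = 15L) {
    stopifnot(length(context_seq) == 1L, min_len >= 1L, max_len >= min_len)
    n <- nchar(context_seq)
    if (is.na(cut_index) || cut_index < 1L || cut_index >= n)
        stop("cut_index out of range: must satisfy 1 <= cut_index < sequence length")
    out <- vector("list", max_len - min_len + 1L)
    for (L in min_len:max_len) {
        u <- 0:window
        e <- cut_index - u                       # upstream arm end positions
        okU <- e - L + 1L >= 1L
        d <- 0:window
        s <- cut_index + 1L + d                  # downstream arm starts
        okD <- s + L - 1L <= n
        if (!any(okU) || !any(okD)) next
        ups <- substring(context_seq, e[okU] - L + 1L, e[okU])
        dns <- substring(context_seq, s[okD], s[okD] + L - 1L)
        g <- expand.grid(ui = seq_along(ups), di = seq_along(dns))
        hit <- ups[g$ui] == dns[g$di] & !grepl("N", ups[g$ui], fixed = TRUE)
        if (any(hit))
            out[[L - min_len + 1L]] <- data.frame(
                arm_seq = ups[g$ui[hit]], arm_len = L,
                upstream_offset = u[okU][g$ui[hit]],
                downstream_offset = d[okD][g$di[hit]])
    }
    out <- out[!vapply(out, is.null, logical(1L))]
    if (!length(out))
        return(data.frame(arm_seq = character(), arm_len = integer(),
                          upstream_offset = integer(),
                          downstream_offset = integer()))
    res <- do.call(rbind, out)
    res[order(res$arm_len, res$upstream_offset, res$downstream_offset), ,
        drop = FALSE]
}

#' Is a cut site an MMEJ candidate?
#'
#' `TRUE` iff [findMHPairs()] finds at least one microhomology arm pair
#' under the given geometry.
#'
#' @inheritParams findMHPairs
#' @return logical scalar.
#' @export
isMMEJCandidate <- function(context_seq, cut_index, min_len = 5L,
                            max_len = 15L, window = 15L) {
    nrow(findMHPairs(context_seq, cut_index, min_len, max_len, window)) > 0L
}

#' PAM 1-bp-upstream context category
#'
#' Collapses the 4-mer formed by the base immediately 5' of the PAM plus the
#' NGG PAM into its upstream-context class (e.g. `CAGG` and `CGGG` are both
#' class `CNGG`). For records whose 4-mer is given in genome orientation on
#' the minus strand, the 4-mer is reverse-complemented first so the upstream
#' base is always protospacer-proximal.
#'
#' @param pam4 character vector of 4-mers (upstream base + NGG).
#' @param strand `"+"`/`"-"` per record (recycled).
#' @param orientation `"guide"` when `pam4` already reads in protospacer
#'   orientation (the default convention of this package), `"genome"` when
#'   it reads on the genomic plus strand.
#' @return data.frame with columns `pam4` (guide-oriented) and `class`.
#' @export
extractPAMContext <- function(pam4, strand = "+",
                              orientation = c("guide", "genome")) {
    orientation <- match.arg(orientation)
    strand <- rep_len(strand, length(pam4))
    if (orientation == "genome") {
        flip <- strand == "-"
        if (any(flip))
            pam4[flip] <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAStringSet(pam4[flip])))
    }
    if (any(nchar(pam4) != 4L | substr(pam4, 3L, 4L) != "GG"))
        stop("malformed PAM 4-mer: expected <upstream base>NGG")
    data.frame(pam4 = pam4, class = paste0(substr(pam4, 1L, 1L), "NGG"))
}

#' Count CpG dimers in context sequences
#'
#' Overlap-free 5'-to-3' count of `CG` dimers (CG cannot overlap itself, so
#' this equals the plain match count).
#'
#' @param context_seq character vector or
#'   [Biostrings::DNAStringSet] of sequences.
#' @return integer vector of counts.
#' @export
countCpG <- function(context_seq) {
    if (!is(context_seq, "DNAStringSet"))
        context_seq <- Biostrings::DNAStringSet(as.character(context_seq))
    Biostrings::vcountPattern("CG", context_seq)
}

# ---------------------------------------------------------------------------
# Motif covariates
# ---------------------------------------------------------------------------

#' A motif-occurrence covariate over a set of loci
#'
#' @slot motif_id,consensus motif label and IUPAC consensus.
#' @slot window_half_width half-width (bp) of the scan window centred on the
#'   cut.
#' @slot cap maximum occurrences counted per locus.
#' @slot counts named integer vector, capped occurrence count per locus.
#' @slot prevalence fraction of loci with at least one occurrence.
#' @export
setClass("MotifCovariate", representation(
    motif_id = "character", consensus = "character",
    window_half_width = "integer", cap = "integer",
    counts = "integer", prevalence = "numeric"))

setValidity("MotifCovariate", function(object) {
    if (any(object@counts > object@cap))
        return("counts exceed the cap")
    if (object@prevalence < 0 || object@prevalence > 1)
        return("prevalence must be in [0, 1]")
    TRUE
})

setMethod("show", "MotifCovariate", function(object) {
    cat("MotifCovariate '", object@motif_id, "' (", object@consensus,
        "), window +/-", object@window_half_width, "bp, cap ", object@cap,
        "\n  loci: ", length(object@counts), ", prevalence ",
        format(object@prevalence, digits = 3), "\n", sep = "")
})

#' @describeIn MotifCovariate-class capped occurrence counts per locus.
#' @param object a `MotifCovariate`.
#' @export
setGeneric("motifCounts", function(object) standardGeneric("motifCounts"))

#' @rdname MotifCovariate-class
#' @export
setMethod("motifCounts", "MotifCovariate", function(object) object@counts)

#' @describeIn MotifCovariate-class fraction of loci with >= 1 occurrence.
#' @export
setGeneric("motifPrevalence",
           function(object) standardGeneric("motifPrevalence"))

#' @rdname MotifCovariate-class
#' @export
setMethod("motifPrevalence", "MotifCovariate", function(object)
    object@prevalence)

.iupacPattern <- function(consensus) {
    bad <- setdiff(strsplit(toupper(consensus), "")[[1L]],
                   names(Biostrings::IUPAC_CODE_MAP))
    if (length(bad))
        stop("invalid IUPAC symbol in consensus: ", paste(bad, collapse = ""))
    Biostrings::DNAString(toupper(consensus))
}

#' Scan context sequences for an IUPAC consensus motif around the cut
#'
#' Counts exact IUPAC-consensus matches on both strands whose span
#' intersects the window centred on the cut position (positions
#' `cut_index - window_half_width + 1` to `cut_index + window_half_width`;
#' e.g. half-widths 8, 25 and 50 give the 16, 50 and 100 bp search lengths).
#' Counts are capped at `cap`; prevalence is the fraction of supplied loci
#' with at least one occurrence, so the sequences passed in define the locus
#' universe.
#'
#' @param context_seqs named character vector or
#'   [Biostrings::DNAStringSet] of context sequences (the locus universe).
#' @param consensus IUPAC consensus string.
#' @param cut_index 1-based cut position, scalar or one per sequence.
#' @param window_half_width half-width of the scan window (bp).
#' @param cap maximum occurrences counted per locus (default 5).
#' @param motif_id label, defaults to the consensus.
#' @param binary when `TRUE` counts are truncated to presence/absence (the
#'   "abundance versus absence" encoding).
#' @return A [MotifCovariate-class].
#' @export
scanMotif <- function(context_seqs, consensus, cut_index,
                      window_half_width = 8L, cap = 5L,
                      motif_id = consensus, binary = FALSE) {
    if (!is(context_seqs, "DNAStringSet"))
        context_seqs <- Biostrings::DNAStringSet(as.character(context_seqs))
    n <- length(context_seqs)
    cut_index <- rep_len(as.integer(cut_index), n)
    pat <- .iupacPattern(consensus)
    rcp <- Biostrings::reverseComplement(pat)
    strands <- if (as.character(rcp) == as.character(pat)) list(pat)
               else list(pat, rcp)
    counts <- integer(n)
    for (p in strands) {
        m <- Biostrings::vmatchPattern(p, context_seqs, fixed = FALSE)
        for (i in seq_len(n)) {
            r <- m[[i]]
            if (!length(r)) next
            lo <- cut_index[i] - window_half_width + 1L
            hi <- cut_index[i] + window_half_width
            counts[i] <- counts[i] +
                sum(BiocGenerics::start(r) <= hi & BiocGenerics::end(r) >= lo)
        }
    }
    counts <- pmin(counts, as.integer(cap))
    if (binary) counts <- as.integer(counts > 0L)
    names(counts) <- names(context_seqs)
    new("MotifCovariate", motif_id = motif_id, consensus = consensus,
        window_half_width = as.integer(window_half_width),
        cap = as.integer(cap), counts = counts,
        prevalence = mean(counts > 0L))
}

#' Scan with a position weight matrix instead of a consensus
#'
#' Alternative matching mode: occurrences are PWM matches on either strand
#' scoring at least `min_score` (default 80% of the maximal score) whose
#' span intersects the cut-centred window.
#'
#' @param pwm a 4-row (A, C, G, T) position weight matrix as accepted by
#'   [Biostrings::matchPWM()].
#' @inheritParams scanMotif
#' @param min_score score threshold, e.g. `"80%"`.
#' @return A [MotifCovariate-class].
#' @export
scanPWM <- function(context_seqs, pwm, cut_index, window_half_width = 8L,
                    cap = 5L, motif_id = "pwm", min_score = "80%",
                    binary = FALSE) {
    if (!is(context_seqs, "DNAStringSet"))
        context_seqs <- Biostrings::DNAStringSet(as.character(context_seqs))
    n <- length(context_seqs)
    cut_index <- rep_len(as.integer(cut_index), n)
    counts <- integer(n)
    rc <- Biostrings::reverseComplement(pwm)
    for (i in seq_len(n)) {
        lo <- cut_index[i] - window_half_width + 1L
        hi <- cut_index[i] + window_half_width
        for (p in list(pwm, rc)) {
            r <- Biostrings::matchPWM(p, context_seqs[[i]],
                                      min.score = min_score)
            if (length(r))
                counts[i] <- counts[i] +
                    sum(BiocGenerics::start(r) <= hi &
                        BiocGenerics::end(r) >= lo)
        }
    }
    counts <- pmin(counts, as.integer(cap))
    if (binary) counts <- as.integer(counts > 0L)
    names(counts) <- names(context_seqs)
    new("MotifCovariate", motif_id = motif_id, consensus = "",
        window_half_width = as.integer(window_half_width),
        cap = as.integer(cap), counts = counts,
        prevalence = mean(counts > 0L))
}

#' Drop rare motif covariates
#'
#' Retains covariates represented at least once in `min_prevalence` of the
#' locus universe (inclusive threshold: prevalence exactly at the cutoff is
#' kept).
#'
#' @param covariates list of [MotifCovariate-class] objects.
#' @param min_prevalence minimum fraction of loci with an occurrence.
#' @return The retained sub-list.
#' @export
prevalenceFilter <- function(covariates, min_prevalence = 0.10) {
    keep <- vapply(covariates, motifPrevalence, numeric(1L)) >= min_prevalence
    covariates[keep]
}

#' Read motif definitions from a simple consensus text file
#'
#' Format: one motif per line, `motif_id<whitespace>IUPAC_consensus`;
#' lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `motif_id`, `consensus`.
#' @export
readMotifs <- function(path) {
    ln <- readLines(path)
    ln <- trimws(ln[!grepl("^\\s*(#|$)", ln)])
    parts <- strsplit(ln, "\\s+")
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) stop("malformed motif line ", bad[1L], " in ", path)
    data.frame(motif_id = vapply(parts, `[`, "", 1L),
               consensus = vapply(parts, `[`, "", 2L))
}
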