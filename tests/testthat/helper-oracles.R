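# Independent brute-force oracles. These deliberately re-derive results from
# first principles (exhaustive enumeration, naive scanning, pairwise
# counting) and share no code with the implementation they check.

# exhaustive microhomology enumeration: every (upstream end, downstream
# start, length) triple, filtered by the window rule
bruteMH <- function(seq, cut, min_len = 5L, max_len = 15L, window = 15L) {
    n <- nchar(seq)
    rows <- list()
    k <- 0L
    for (L in min_len:max_len) {
        for (e in seq_len(cut)) {                 # upstream arm end
            if (e - L + 1L < 1L) next
            u <- cut - e
            if (u > window) next
            up <- substr(seq, e - L + 1L, e)
            if (grepl("N", up, fixed = TRUE)) next
            for (s in (cut + 1L):n) {             # downstream arm start
                if (s + L - 1L > n) next
                d <- s - cut - 1L
                if (d > window) next
                if (up == substr(seq, s, s + L - 1L)) {
                    k <- k + 1L
                    rows[[k]] <- c(L, u, d)
                }
            }
        }
    }
    if (!k) return(data.frame(arm_len = integer(), upstream_offset = integer(),
                              downstream_offset = integer()))
    m <- do.call(rbind, rows)
    out <- data.frame(arm_len = m[, 1L], upstream_offset = m[, 2L],
                      downstream_offset = m[, 3L])
    out[order(out$arm_len, out$upstream_offset, out$downstream_offset), ]
}

# naive position-by-position IUPAC matcher, both strands, window-intersecting
IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
naiveMotifCount <- function(seq, consensus, cut, half_width, cap = 5L) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rc <- function(s) paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
    pats <- unique(c(consensus, {
        # IUPAC reverse complement via Biostrings (input side only)
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(consensus)))
    }))
    chars <- strsplit(seq, "")[[1L]]
    lo <- cut - half_width + 1L; hi <- cut + half_width
    total <- 0L
    for (p in pats) {
        pc <- strsplit(p, "")[[1L]]
        k <- length(pc)
        for (s in seq_len(length(chars) - k + 1L)) {
            if (s > hi || s + k - 1L < lo) next
            ok <- TRUE
            for (j in seq_len(k)) {
                if (!(chars[s + j - 1L] %in% IUPAC_SETS[[pc[j]]])) {
                    ok <- FALSE; break
                }
            }
            if (ok) total <- total + 1L
        }
    }
    min(total, cap)
}

# AUROC by exhaustive pairwise comparison (ties count 1/2)
bruteAUROC <- function(scores, essential, nonessential) {
    ess <- scores[intersect(names(scores), essential)]
    non <- scores[intersect(names(scores), nonessential)]
    tot <- 0
    for (a in ess) for (b in non)
        tot <- tot + (a < b) + 0.5 * (a == b)
    tot / (length(ess) * length(non))
}

# independent permutation-null reimplementation (order(runif) shuffling)
altPermutationNull <- function(hits, is_ko, n_iter, min_hits, min_ko, max_wt,
                               seed) {
    set.seed(seed)
    n_sat <- 0L
    for (it in seq_len(n_iter)) {
        perm <- apply(hits, 2L, function(col) col[order(stats::runif(length(col)))])
        ko <- rowSums(perm[, is_ko, drop = FALSE])
        wt <- rowSums(perm[, !is_ko, drop = FALSE])
        if (sum(ko >= min_ko & wt <= max_wt) >= min_hits) n_sat <- n_sat + 1L
    }
    n_sat
}

randomDNA <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), "")
}
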