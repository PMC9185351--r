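#' Pairwise sequence identity
#'
#' Identity between two peptides is the maximal number of matched identical
#' residues over all global alignments under match = 1, mismatch = 0,
#' gap = 0 scoring (equivalently the longest-common-subsequence length),
#' divided by the length of the shorter sequence — the convention used by
#' greedy identity-clustering tools. The measure is symmetric and equals 1
#' for identical sequences.
#'
#' @param a,b Amino-acid sequences (character scalars, or single-record
#'   [PeptideSet-class]s).
#' @return Identity in \[0, 1\].
#' @examples
#' pairwiseIdentity("PEPTIDE", "PEPTIDES")  # 1: 7 matches / min length 7
#' @export
pairwiseIdentity <- function(a, b) {
    a <- .oneSequence(a)
    b <- .oneSequence(b)
    lcs_matches(a, b) / min(nchar(a), nchar(b))
}

.oneSequence <- function(x) {
    if (is(x, "PeptideSet")) {
        stopifnot(length(x) == 1)
        return(peptideSequences(x)[[1]])
    }
    stopifnot(is.character(x), length(x) == 1)
    toupper(x)
}

#' Greedy identity-based redundancy reduction
#'
#' Removes near-duplicate peptides the way greedy incremental clustering
#' (the CD-HIT strategy) does: records are visited in order of decreasing
#' length (ties by id); each record either joins the representative set or,
#' if its identity to an existing (necessarily no shorter) representative
#' strictly exceeds \code{threshold}, is discarded. Surviving records are
#' returned in the original dataset order. A cheap residue-composition
#' bound (the sum of per-residue minimum counts caps the match count)
#' prefilters pairs that cannot exceed the threshold.
#'
#' @param x A non-empty [PeptideSet-class].
#' @param threshold Identity threshold in (0, 1]; records *strictly above*
#'   it are discarded. Default 0.9 (discard >90% identity).
#' @return A [PeptideSet-class] of the surviving representatives, with an
#'   attribute \code{"discarded"}: a data.frame of discarded ids and the
#'   representative each matched.
#' @export
reduceRedundancy <- function(x, threshold = 0.9) {
    stopifnot(is(x, "PeptideSet"))
    if (length(x) == 0) stop("dataset is empty")
    stopifnot(threshold > 0, threshold <= 1)
    seqs <- peptideSequences(x)
    ids <- peptideIds(x)
    ord <- order(-nchar(seqs), ids)
    comp <- t(vapply(seqs, .residueCounts, integer(20)))
    repIdx <- integer(0)
    discarded <- character(0)
    matchedRep <- character(0)
    for (i in ord) {
        keep <- TRUE
        if (length(repIdx)) {
            minLen <- pmin(nchar(seqs[i]), nchar(seqs[repIdx]))
            # shared composition bounds the achievable match count
            bound <- colSums(pmin(t(comp[repIdx, , drop = FALSE]), comp[i, ]))
            cand <- repIdx[bound / minLen > threshold]
            if (length(cand)) {
                idn <- lcs_matches(seqs[i], seqs[cand]) /
                    pmin(nchar(seqs[i]), nchar(seqs[cand]))
                hit <- which(idn > threshold)
                if (length(hit)) {
                    keep <- FALSE
                    discarded <- c(discarded, ids[i])
                    matchedRep <- c(matchedRep, ids[cand[hit[1]]])
                }
            }
        }
        if (keep) repIdx <- c(repIdx, i)
    }
    out <- x[sort(repIdx)]
    attr(out, "discarded") <- data.frame(id = discarded,
                                         representative = matchedRep,
                                         stringsAsFactors = FALSE)
    out
}

.residueCounts <- function(s) {
    idx <- match(strsplit(s, "", fixed = TRUE)[[1]], .AA20)
    tabulate(idx, nbins = 20L)
}
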