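#' @rdname encodeDataset
#' @export
encodeAAC <- function(x) {
    seqs <- .seqsOf(x)
    out <- t(vapply(seqs, function(s) {
        idx <- .residueIndex(s)
        tabulate(idx, 20L) / length(idx)
    }, numeric(20)))
    colnames(out) <- paste0("AAC:", .AA20)
    .asFeatures(out, "AAC")
}

#' @rdname encodeDataset
#' @export
encodeDPC <- function(x) {
    seqs <- .seqsOf(x)
    short <- nchar(seqs) < 2
    if (any(short))
        stop("no dipeptide exists for record(s): ",
             paste(names(seqs)[short], collapse = ", "))
    out <- t(vapply(seqs, function(s) {
        idx <- .residueIndex(s)
        L <- length(idx)
        cell <- (idx[-L] - 1L) * 20L + idx[-1L]
        tabulate(cell, 400L) / (L - 1)
    }, numeric(400)))
    colnames(out) <- paste0("DPC:", .kmerNames(2))
    .asFeatures(out, "DPC")
}

#' @rdname encodeDataset
#' @export
encodeTPC <- function(x) {
    seqs <- .seqsOf(x)
    short <- nchar(seqs) < 3
    if (any(short))
        stop("no tripeptide exists for record(s): ",
             paste(names(seqs)[short], collapse = ", "))
    out <- t(vapply(seqs, function(s) {
        idx <- .residueIndex(s)
        L <- length(idx)
        i1 <- idx[seq_len(L - 2)]
        i2 <- idx[seq_len(L - 2) + 1L]
        i3 <- idx[seq_len(L - 2) + 2L]
        cell <- (i1 - 1L) * 400L + (i2 - 1L) * 20L + i3
        tabulate(cell, 8000L) / (L - 2)
    }, numeric(8000)))
    colnames(out) <- paste0("TPC:", .kmerNames(3))
    .asFeatures(out, "TPC")
}

#' Sequence-order correlation factor
#'
#' The tier-\eqn{n} correlation factor of a peptide is the average, over all
#' residue pairs \eqn{n} positions apart, of the correlation function
#' \eqn{I(R_i, R_j)}: the mean squared difference of the selected normalized
#' physicochemical property values between the two residues. It is zero for
#' a homopolymer and invariant under sequence reversal.
#'
#' @param x A single sequence (character scalar or 1-record
#'   [PeptideSet-class]).
#' @param n Correlation tier (distance between the paired residues);
#'   must be < sequence length.
#' @param table A [PropertyTable-class]; the shipped default when omitted.
#' @param subset Property names to use (default: all nine).
#' @param tierMode \code{"canonical"} pairs residues \eqn{n} apart;
#'   \code{"literal"} keeps adjacent pairs at every tier and only shortens
#'   the averaging window (a degenerate variant kept for comparison).
#' @return The non-negative correlation factor \eqn{\theta_n}.
#' @export
sequenceCorrelation <- function(x, n, table = defaultPropertyTable(),
                                subset = propertyNames(table),
                                tierMode = c("canonical", "literal")) {
    tierMode <- match.arg(tierMode)
    s <- .oneSequence(x)
    idx <- .residueIndex(s)
    L <- length(idx)
    n <- as.integer(n)
    if (n < 1L || n >= L)
        stop("tier n must satisfy 1 <= n < sequence length (", L, ")")
    H <- propertyValues(table)[, subset, drop = FALSE]
    gap <- if (tierMode == "canonical") n else 1L
    k <- seq_len(L - n)
    d <- H[idx[k + gap], , drop = FALSE] - H[idx[k], , drop = FALSE]
    mean(rowMeans(d^2))
}

#' @rdname encodeDataset
#' @param table A [PropertyTable-class] used by the PseAAC correlation
#'   factors.
#' @export
encodeIPseAAC <- function(x, lambda = 1, w = 0.05,
                          table = defaultPropertyTable(),
                          subset = propertyNames(table),
                          tierMode = c("canonical", "literal")) {
    tierMode <- match.arg(tierMode)
    lambda <- as.integer(lambda)
    stopifnot(lambda >= 1, w >= 0)
    seqs <- .seqsOf(x)
    short <- nchar(seqs) <= lambda
    if (any(short))
        stop("lambda (", lambda, ") must be < sequence length for record(s): ",
             paste(names(seqs)[short], collapse = ", "))
    out <- t(vapply(seqs, function(s) {
        idx <- .residueIndex(s)
        f <- tabulate(idx, 20L) / length(idx)
        theta <- vapply(seq_len(lambda), function(n)
            sequenceCorrelation(s, n, table, subset, tierMode), numeric(1))
        denom <- sum(f) + w * sum(theta)
        c(f, w * theta) / denom
    }, numeric(20 + lambda)))
    colnames(out) <- c(paste0("PSE:", .AA20),
                       paste0("PSE:theta", seq_len(lambda)))
    .asFeatures(out, sprintf("IPseAAC(lambda=%d,w=%g)", lambda, w))
}

#' Encode peptides into fixed-length feature vectors
#'
#' The four encoders map a peptide of length \eqn{L} onto probability
#' vectors: amino acid composition (AAC, 20 residue frequencies
#' \eqn{n_j/L}), dipeptide composition (DPC, 400 adjacent-pair frequencies
#' over \eqn{L-1} windows), tripeptide composition (TPC, 8000 triple
#' frequencies over \eqn{L-2} windows) and the improved pseudo amino acid
#' composition (IPseAAC, the 20 residue frequencies augmented with
#' \eqn{\lambda} physicochemical sequence-order correlation factors, jointly
#' normalized with weight \eqn{w} so the \eqn{20+\lambda} components sum
#' to 1). \code{encodeDataset} concatenates any ordered subset of the four
#' into one feature matrix with encoder-prefixed column names (all four at
#' \eqn{\lambda=1} give \eqn{20+400+8000+21 = 8441} columns).
#'
#' @param x A [PeptideSet-class] (or named character vector of sequences).
#' @param encoders Ordered subset of \code{c("AAC","DPC","TPC","IPseAAC")}.
#' @param lambda Number of PseAAC correlation tiers (default 1).
#' @param w PseAAC correlation weight (default 0.05).
#' @inheritParams sequenceCorrelation
#'
#' @return A numeric matrix, rows named by record id, columns by
#'   \code{encoder:descriptor}, with an \code{"encoder"} attribute carrying
#'   provenance.
#' @examples
#' ps <- peptideSet(c(a = "GLWSK", b = "KKKKK"), name = "demo")
#' dim(encodeDataset(ps, c("AAC", "IPseAAC")))
#' @export
encodeDataset <- function(x, encoders = c("AAC", "DPC", "TPC", "IPseAAC"),
                          lambda = 1, w = 0.05,
                          table = defaultPropertyTable(),
                          tierMode = "canonical") {
    encoders <- match.arg(encoders, several.ok = TRUE)
    seqs <- .seqsOf(x)
    minL <- c(AAC = 1, DPC = 2, TPC = 3, IPseAAC = as.integer(lambda) + 1)
    for (e in encoders) {
        bad <- nchar(seqs) < minL[[e]]
        if (any(bad))
            stop(e, " requires length >= ", minL[[e]],
                 "; offending record(s): ",
                 paste(names(seqs)[bad], collapse = ", "))
    }
    parts <- lapply(encoders, function(e) switch(e,
        AAC = encodeAAC(seqs),
        DPC = encodeDPC(seqs),
        TPC = encodeTPC(seqs),
        IPseAAC = encodeIPseAAC(seqs, lambda = lambda, w = w,
                                table = table, tierMode = tierMode)))
    out <- do.call(cbind, parts)
    .asFeatures(out, paste(vapply(parts, attr, "", "encoder"),
                           collapse = "+"))
}

.seqsOf <- function(x) {
    if (is(x, "PeptideSet")) return(peptideSequences(x))
    stopifnot(is.character(x))
    s <- toupper(x)
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
    s
}

.residueIndex <- function(s) {
    idx <- match(strsplit(s, "", fixed = TRUE)[[1]], .AA20)
    if (anyNA(idx)) stop("non-canonical residue in sequence")
    idx
}

.kmerNames <- function(k) {
    grid <- do.call(expand.grid,
                    c(rev(replicate(k, .AA20, simplify = FALSE)),
                      stringsAsFactors = FALSE))
    do.call(paste0, rev(grid))
}

.asFeatures <- function(m, tag) {
    storage.mode(m) <- "double"
    attr(m, "encoder") <- tag
    m
}
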