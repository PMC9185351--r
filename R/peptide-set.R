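#' Construct a PeptideSet
#'
#' @param sequences Named character vector of amino-acid sequences, or an
#'   [Biostrings::AAStringSet]. Lowercase letters are accepted and
#'   normalized to uppercase; only the 20 canonical residues are valid.
#' @param labels Optional character/factor of \code{"ACP"}/\code{"NACP"}
#'   labels (recycled \code{NA} when omitted).
#' @param name Dataset name.
#'
#' @return A [PeptideSet-class] object.
#' @examples
#' ps <- peptideSet(c(ACP_1 = "GLWSKIKEVGKEAAKAAAKAAGKAALGAVSEAV"),
#'                  labels = "ACP")
#' peptideLengths(ps)
#' @export
peptideSet <- function(sequences, labels = NULL, name = "dataset") {
    if (is(sequences, "AAStringSet")) {
        seqs <- toupper(as.character(sequences))
        names(seqs) <- names(sequences)
    } else {
        seqs <- toupper(as.character(sequences))
        names(seqs) <- names(sequences)
    }
    if (is.null(labels)) labels <- rep(NA_character_, length(seqs))
    labels <- as.character(labels)
    bad <- !is.na(labels) & !labels %in% .CLASS_LEVELS
    if (any(bad))
        stop("unknown label(s): ", paste(unique(labels[bad]), collapse = ", "))
    new("PeptideSet",
        sequences = Biostrings::AAStringSet(seqs),
        labels = factor(labels, levels = .CLASS_LEVELS),
        name = as.character(name))
}

#' @describeIn peptideSet Record identifiers, in dataset order.
#' @param x A \code{PeptideSet}.
#' @export
peptideIds <- function(x) names(x@sequences)

#' @describeIn peptideSet Sequences as a named character vector.
#' @export
peptideSequences <- function(x) {
    out <- as.character(x@sequences)
    names(out) <- names(x@sequences)
    out
}

#' @describeIn peptideSet Class labels as a factor (NA when unlabelled).
#' @export
peptideLabels <- function(x) {
    out <- x@labels
    names(out) <- peptideIds(x)
    out
}

#' @describeIn peptideSet Residue counts per record.
#' @export
peptideLengths <- function(x) {
    out <- Biostrings::width(x@sequences)
    names(out) <- peptideIds(x)
    out
}

#' @describeIn peptideSet Dataset name.
#' @export
datasetName <- function(x) x@name

#' @export
setMethod("length", "PeptideSet", function(x) length(x@sequences))

#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, peptideIds(x))
    initialize(x, sequences = x@sequences[i],
               labels = factor(as.character(x@labels[i]),
                               levels = .CLASS_LEVELS))
})

#' @export
setMethod("show", "PeptideSet", function(object) {
    tab <- table(object@labels, useNA = "ifany")
    cat(sprintf("PeptideSet '%s': %d record(s)\n", object@name,
                length(object)))
    if (length(object)) {
        w <- Biostrings::width(object@sequences)
        cat(sprintf("  lengths %d..%d; labels: %s\n", min(w), max(w),
                    paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                          collapse = " ")))
    }
    invisible(object)
})
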