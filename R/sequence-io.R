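#' Read labelled peptide sequences from FASTA
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file of peptide
#' sequences, validates every record against the 20-letter canonical
#' amino-acid alphabet, and attaches ACP/NACP class labels according to an
#' explicit policy. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param labelPolicy How labels are attached: \code{"from_header_prefix"}
#'   reads the token before the first underscore of each id (must be
#'   \code{ACP} or \code{NACP}); \code{"from_table"} looks ids up in a
#'   two-column tab-separated file \code{id<TAB>label}; \code{"unlabeled"}
#'   attaches no labels.
#' @param labelPath Path to the label table (required for
#'   \code{"from_table"}).
#' @param name Dataset name for the returned object.
#'
#' @return A [PeptideSet-class].
#' @seealso [writePeptideFasta()], [splitDataset()]
#' @export
readPeptideFasta <- function(path,
                             labelPolicy = c("from_header_prefix",
                                             "from_table", "unlabeled"),
                             labelPath = NULL, name = NULL) {
    labelPolicy <- match.arg(labelPolicy)
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    if (file.size(path) == 0)
        return(peptideSet(character(0), name = name))
    first <- readLines(path, n = 1)
    if (!startsWith(first, ">"))
        stop("malformed FASTA (line 1 does not start with '>'): ", first)
    seqs <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(ids))
        stop("duplicate record id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(seqs) <- ids
    labels <- switch(labelPolicy,
        unlabeled = NULL,
        from_header_prefix = {
            pre <- sub("_.*$", "", ids)
            bad <- !pre %in% .CLASS_LEVELS
            if (any(bad))
                stop("header prefix is neither ACP nor NACP for id(s): ",
                     paste(ids[bad], collapse = ", "))
            pre
        },
        from_table = {
            if (is.null(labelPath) || !file.exists(labelPath))
                stop("labelPolicy 'from_table' requires an existing labelPath")
            tab <- read.delim(labelPath, header = FALSE,
                              stringsAsFactors = FALSE,
                              col.names = c("id", "label"))
            m <- match(ids, tab$id)
            if (anyNA(m))
                stop("label table is missing id(s): ",
                     paste(ids[is.na(m)], collapse = ", "))
            tab$label[m]
        })
    peptideSet(stats::setNames(as.character(seqs), ids), labels, name)
}

#' Write a PeptideSet to FASTA (and optionally a label table)
#'
#' Sequences are written unwrapped, one line per record. When labels are
#' present and \code{labelPath} is given, a two-column \code{id<TAB>label}
#' table is written alongside, so that
#' \code{readPeptideFasta(..., "from_table")} round-trips ids, sequences and
#' labels exactly.
#'
#' @param x A non-empty [PeptideSet-class].
#' @param path Output FASTA path.
#' @param labelPath Optional output path for the label table.
#' @return \code{path}, invisibly.
#' @export
writePeptideFasta <- function(x, path, labelPath = NULL) {
    stopifnot(is(x, "PeptideSet"))
    if (length(x) == 0) stop("refusing to write an empty PeptideSet")
    Biostrings::writeXStringSet(x@sequences, path,
                                width = max(peptideLengths(x)) + 1L)
    if (!is.null(labelPath)) {
        lab <- peptideLabels(x)
        write.table(data.frame(id = peptideIds(x),
                               label = as.character(lab)),
                    labelPath, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Split a PeptideSet into training and testing partitions
#'
#' The training size is \code{round(trainFraction * n)} under R's
#' round-half-to-even convention (so 344 peptides at 0.7 give 241/103 and
#' 2475 give 1732/743). With \code{stratified = TRUE} (default) the
#' per-class training counts follow a largest-remainder allocation of that
#' total, keeping class proportions as close to the overall fraction as
#' integer rounding allows. The split is a partition of the input and is
#' deterministic for a fixed seed.
#'
#' @param x A [PeptideSet-class]; must be fully labelled when
#'   \code{stratified}.
#' @param trainFraction Fraction in (0, 1) assigned to training.
#' @param stratified Preserve class proportions.
#' @param seed Integer seed.
#'
#' @return \code{list(train = , test = )} of [PeptideSet-class]s.
#' @export
splitDataset <- function(x, trainFraction = 0.7, stratified = TRUE,
                         seed = 1) {
    stopifnot(is(x, "PeptideSet"))
    if (!is.numeric(trainFraction) || trainFraction <= 0 ||
        trainFraction >= 1)
        stop("trainFraction must lie strictly between 0 and 1")
    n <- length(x)
    nTrain <- as.integer(round(trainFraction * n))
    ids <- peptideIds(x)
    lab <- as.character(x@labels)
    if (stratified && anyNA(lab))
        stop("stratified split requires every record to be labelled")
    trainIds <- withSeed(seed, {
        if (!stratified) {
            sample(ids)[seq_len(nTrain)]
        } else {
            classes <- unique(lab)
            target <- trainFraction * table(lab)[classes]
            base <- floor(target)
            rem <- nTrain - sum(base)
            if (rem > 0) {
                extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
                base[extra] <- base[extra] + 1
            } else if (rem < 0) {
                cut <- order(target - base)[seq_len(-rem)]
                base[cut] <- base[cut] - 1
            }
            unlist(lapply(classes, function(cl)
                sample(ids[lab == cl])[seq_len(base[[cl]])]),
                use.names = FALSE)
        }
    })
    inTrain <- ids %in% trainIds
    list(train = x[which(inTrain)], test = x[which(!inTrain)])
}

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}
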