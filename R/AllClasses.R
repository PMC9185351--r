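#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom stats prcomp predict sd var cov setNames
#' @importFrom utils read.delim write.table head combn
#' @importFrom e1071 svm naiveBayes
#' @importFrom randomForest randomForest
#' @importFrom Rcpp sourceCpp
#' @useDynLib pepVote, .registration = TRUE
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.CLASS_LEVELS <- c("ACP", "NACP")

#' PeptideSet: a labelled collection of peptide sequences
#'
#' Holds validated amino-acid sequences (20-letter canonical alphabet) with
#' unique identifiers and an optional binary class label per record
#' (\code{ACP}, the positive anticancer class, or \code{NACP}).
#'
#' @slot sequences An [Biostrings::AAStringSet] with unique names.
#' @slot labels A factor with levels \code{ACP}/\code{NACP}; \code{NA} where
#'   a record is unlabelled.
#' @slot name A dataset name (e.g. \code{"PSD1"}).
#'
#' @export
setClass("PeptideSet",
    representation(sequences = "AAStringSet", labels = "factor",
                   name = "character"))

setValidity("PeptideSet", function(object) {
    n <- length(object@sequences)
    ids <- names(object@sequences)
    msg <- character()
    if (n > 0 && (is.null(ids) || anyNA(ids) || any(ids == "")))
        msg <- c(msg, "every record must have a non-empty id")
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate record id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (length(object@labels) != n)
        msg <- c(msg, "labels length must equal the number of records")
    if (!identical(levels(object@labels), .CLASS_LEVELS))
        msg <- c(msg, "label levels must be ACP, NACP")
    if (length(object@name) != 1)
        msg <- c(msg, "name must be a single string")
    if (n > 0) {
        if (any(Biostrings::width(object@sequences) == 0))
            msg <- c(msg, "sequences must be non-empty")
        bad <- .nonCanonical(as.character(object@sequences))
        if (length(bad))
            msg <- c(msg, sprintf(
                "non-canonical residue(s): %s",
                paste(sprintf("%s in record %s", bad, names(bad)),
                      collapse = "; ")))
    }
    if (length(msg)) msg else TRUE
})

# first offending character per offending record, named by record id
.nonCanonical <- function(seqs) {
    out <- character()
    for (i in seq_along(seqs)) {
        ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
        off <- ch[!ch %in% .AA20]
        if (length(off)) {
            out <- c(out, off[1])
            names(out)[length(out)] <- names(seqs)[i]
        }
    }
    out
}

#' PropertyTable: nine physicochemical scales over the 20 residues
#'
#' @slot raw 20 x 9 numeric matrix of literature scale values, rows named by
#'   residue, columns by property.
#' @slot normalized The same matrix with each scale standardized to mean 0
#'   and population standard deviation 1 across the 20 residues.
#' @slot version Provenance string for the shipped table.
#'
#' @export
setClass("PropertyTable",
    representation(raw = "matrix", normalized = "matrix",
                   version = "character"))

setValidity("PropertyTable", function(object) {
    msg <- character()
    if (!identical(rownames(object@raw), .AA20))
        msg <- c(msg, "rows must be the 20 canonical residues, A..Y")
    if (ncol(object@raw) != 9)
        msg <- c(msg, "exactly 9 property scales are required")
    if (!identical(dim(object@raw), dim(object@normalized)))
        msg <- c(msg, "raw and normalized shapes must agree")
    mu <- colMeans(object@normalized)
    s2 <- colMeans(sweep(object@normalized, 2, mu)^2)
    if (any(abs(mu) > 1e-9) || any(abs(s2 - 1) > 1e-9))
        msg <- c(msg, "normalized scales must have mean 0, population SD 1")
    if (length(msg)) msg else TRUE
})

#' PCAModel: fitted principal-component pruning model
#'
#' @slot center Per-column training means.
#' @slot eigenvalues Non-increasing eigenvalues of the sample covariance
#'   matrix (divisor Q-1), one per computed component.
#' @slot rotation Orthonormal eigenvector matrix (columns are components),
#'   sign-fixed so each component's largest-magnitude loading is positive.
#' @slot k Retained dimension.
#' @slot evr Cumulative explained-variance ratio per component.
#'
#' @export
setClass("PCAModel",
    representation(center = "numeric", eigenvalues = "numeric",
                   rotation = "matrix", k = "integer", evr = "numeric"))

setValidity("PCAModel", function(object) {
    msg <- character()
    ev <- object@eigenvalues
    if (any(diff(ev) > 1e-9)) msg <- c(msg, "eigenvalues must be non-increasing")
    if (any(ev < -1e-9)) msg <- c(msg, "eigenvalues must be non-negative")
    if (object@k < 1L || object@k > ncol(object@rotation))
        msg <- c(msg, "k out of range")
    if (length(msg)) msg else TRUE
})

#' EnsembleModel: three fitted base classifiers plus voting weights
#'
#' @slot svm Fitted radial-basis SVM (with its selected cost/gamma).
#' @slot rf Fitted random forest.
#' @slot nb Fitted Gaussian naive Bayes.
#' @slot weights Non-negative voting weights for (SVM, RF, NB).
#' @slot tieBreak \code{"svm"} (default; the strongest individual learner
#'   decides exact weight ties) or \code{"majority_class"}.
#' @slot majorityClass Training majority class, used by the
#'   \code{majority_class} tie-break.
#' @slot levels Class levels, \code{c("ACP", "NACP")}.
#' @slot cvAccuracy Cross-validated training accuracy of each base (set when
#'   weights were derived from it, otherwise \code{NA}).
#'
#' @export
setClass("EnsembleModel",
    representation(svm = "ANY", rf = "ANY", nb = "ANY",
                   weights = "numeric", tieBreak = "character",
                   majorityClass = "character", levels = "character",
                   cvAccuracy = "numeric"))

setValidity("EnsembleModel", function(object) {
    msg <- character()
    if (length(object@weights) != 3 || any(object@weights < 0))
        msg <- c(msg, "weights must be three non-negative reals")
    if (all(object@weights == 0))
        msg <- c(msg, "at least one weight must be positive")
    if (!object@tieBreak %in% c("svm", "majority_class"))
        msg <- c(msg, "tieBreak must be 'svm' or 'majority_class'")
    if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: binary confusion counts with ACP positive
#'
#' @slot tp ACPs predicted ACP.
#' @slot tn NACPs predicted NACP.
#' @slot fp NACPs predicted ACP.
#' @slot fn ACPs predicted NACP.
#'
#' @export
setClass("ConfusionMatrix",
    representation(tp = "integer", tn = "integer",
                   fp = "integer", fn = "integer"))

setValidity("ConfusionMatrix", function(object) {
    counts <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(counts < 0)) "counts must be non-negative" else TRUE
})

#' PeptidePipeline: a fitted end-to-end classification pipeline
#'
#' Bundles the training-fitted components (encoder configuration, property
#' table, optional PCA model, ensemble) together with the train/test record
#' ids and the held-out evaluation, so that new sequences can be encoded and
#' classified exactly as the training data were.
#'
#' @slot encoders Encoder names used, in order.
#' @slot lambda,w Improved-PseAAC configuration.
#' @slot tierMode Correlation-tier convention (\code{"canonical"} or
#'   \code{"literal"}).
#' @slot propertyTable The [PropertyTable] used by the PseAAC encoder.
#' @slot pca A fitted [PCAModel], or \code{NULL} when pruning was disabled.
#' @slot ensemble The fitted [EnsembleModel].
#' @slot trainIds,testIds Record ids in each partition (after redundancy
#'   reduction).
#' @slot metrics Named numeric vector of held-out test metrics.
#' @slot confusion The held-out [ConfusionMatrix].
#' @slot log Named integer vector auditing dataset sizes through the stages.
#' @slot config Full configuration list sufficient to reproduce the run.
#'
#' @export
setClass("PeptidePipeline",
    representation(encoders = "character", lambda = "integer", w = "numeric",
                   tierMode = "character", propertyTable = "PropertyTable",
                   pca = "ANY", ensemble = "EnsembleModel",
                   trainIds = "character", testIds = "character",
                   metrics = "numeric", confusion = "ConfusionMatrix",
                   log = "integer", config = "list"))
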