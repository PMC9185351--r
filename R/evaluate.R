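#' Confusion matrix with ACP as the positive class
#'
#' @param truth,predicted Equal-length vectors/factors over
#'   \code{ACP}/\code{NACP}.
#' @return A [ConfusionMatrix-class].
#' @export
confusionCounts <- function(truth, predicted) {
    truth <- as.character(truth)
    predicted <- as.character(predicted)
    if (length(truth) != length(predicted))
        stop("truth and predicted differ in length")
    known <- c(truth, predicted) %in% .CLASS_LEVELS
    if (!all(known))
        stop("unknown label(s): ",
             paste(unique(c(truth, predicted)[!known]), collapse = ", "))
    new("ConfusionMatrix",
        tp = sum(truth == "ACP" & predicted == "ACP"),
        tn = sum(truth == "NACP" & predicted == "NACP"),
        fp = sum(truth == "NACP" & predicted == "ACP"),
        fn = sum(truth == "ACP" & predicted == "NACP"))
}

#' The five evaluation metrics
#'
#' Computes accuracy, sensitivity (recall on ACP), specificity, F1 and the
#' Matthews correlation coefficient from a confusion matrix:
#' \deqn{Acc = (TP+TN)/n, \quad Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP),}
#' \deqn{F1 = 2 \cdot Prec \cdot Sn / (Prec + Sn), \quad
#'   MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' A ratio with a zero denominator is reported as \code{NA} and the reason
#' is recorded in the \code{"undefined"} attribute — never silently 0.
#'
#' @param cm A [ConfusionMatrix-class] with at least one record.
#' @return Named numeric vector \code{accuracy, sensitivity, specificity,
#'   precision, f1, mcc} (proportions in \[0,1\], MCC in \[-1,1\]), with an
#'   \code{"undefined"} attribute naming any undefined metrics.
#' @export
classificationMetrics <- function(cm) {
    stopifnot(is(cm, "ConfusionMatrix"))
    tp <- as.numeric(cm@tp); tn <- as.numeric(cm@tn)
    fp <- as.numeric(cm@fp); fn <- as.numeric(cm@fn)
    n <- tp + tn + fp + fn
    if (n == 0) stop("empty confusion matrix")
    reasons <- character(0)
    frac <- function(num, den, what) {
        if (den == 0) {
            reasons[[what]] <<- sprintf("%s undefined: zero denominator",
                                        what)
            return(NA_real_)
        }
        num / den
    }
    acc <- (tp + tn) / n
    sn <- frac(tp, tp + fn, "sensitivity")
    sp <- frac(tn, tn + fp, "specificity")
    prec <- frac(tp, tp + fp, "precision")
    f1 <- if (is.na(sn) || is.na(prec) || (prec + sn) == 0) {
        reasons[["f1"]] <- "f1 undefined: precision + recall is 0 or undefined"
        NA_real_
    } else 2 * prec * sn / (prec + sn)
    mccDen <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
    mcc <- if (mccDen == 0) {
        reasons[["mcc"]] <- "mcc undefined: a marginal total is 0"
        NA_real_
    } else (tp * tn - fp * fn) / mccDen
    out <- c(accuracy = acc, sensitivity = sn, specificity = sp,
             precision = prec, f1 = f1, mcc = mcc)
    attr(out, "undefined") <- unname(unlist(reasons))
    out
}

#' @export
setMethod("show", "ConfusionMatrix", function(object) {
    m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
                dimnames = list(truth = c("ACP", "NACP"),
                                predicted = c("ACP", "NACP")))
    cat("ConfusionMatrix (ACP positive)\n")
    print(m)
    invisible(object)
})

#' Evaluate a fitted pipeline on held-out peptides
#'
#' Encodes the test records with the training-fitted encoder configuration
#' and PCA model, predicts with the ensemble, and reports the confusion
#' matrix and the five metrics. Any overlap between test ids and the
#' pipeline's training ids is an error (leakage guard).
#'
#' @param x A labelled [PeptideSet-class] of held-out records.
#' @param pipeline A fitted [PeptidePipeline-class].
#' @param reportPath Optional path; when given, a tab-separated
#'   \code{metric<TAB>value} report is written there.
#' @return \code{list(metrics = , confusion = , predictions = )}.
#' @export
evaluatePipeline <- function(x, pipeline, reportPath = NULL) {
    stopifnot(is(x, "PeptideSet"), is(pipeline, "PeptidePipeline"))
    if (length(x) == 0) stop("empty test set")
    leak <- intersect(peptideIds(x), pipeline@trainIds)
    if (length(leak))
        stop("test records overlap the training set: ",
             paste(head(leak, 5), collapse = ", "))
    lab <- peptideLabels(x)
    if (anyNA(lab)) stop("test records must be labelled")
    pred <- predictPipeline(pipeline, x)
    cm <- confusionCounts(lab, pred$label)
    met <- classificationMetrics(cm)
    if (!is.null(reportPath)) {
        write.table(data.frame(metric = names(met),
                               value = as.numeric(met)),
                    reportPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    list(metrics = met, confusion = cm, predictions = pred)
}
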