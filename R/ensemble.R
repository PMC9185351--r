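#' Fit the SVM + RF + NB voting ensemble
#'
#' Trains the three base classifiers on the same feature matrix and
#' combines them by weighted majority voting. Under
#' \code{weightMode = "equal"} (default) each base casts a unit vote;
#' under \code{"cv_accuracy"} the weights are proportional to each base's
#' seeded \code{folds}-fold cross-validated training accuracy (the SVM is
#' cross-validated at its grid-selected cost/gamma). Exact weight ties at
#' prediction time are resolved by \code{tieBreak}: the SVM's vote
#' (default) or the training majority class.
#'
#' @inheritParams baseClassifiers
#' @param svmArgs List of arguments passed on to [trainSVM()]
#'   (e.g. \code{cRange}, \code{gammaRange}).
#' @param weightMode \code{"equal"} or \code{"cv_accuracy"}.
#' @param tieBreak \code{"svm"} or \code{"majority_class"}.
#' @return An [EnsembleModel-class].
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 2), 20), matrix(rnorm(40, -2), 20))
#' y <- factor(rep(c("ACP", "NACP"), each = 20))
#' em <- fitEnsemble(x, y, svmArgs = list(cRange = 1, gammaRange = 0.5))
#' table(ensemblePredict(em, x), y)
#' @export
fitEnsemble <- function(x, y, svmArgs = list(), nTrees = 100,
                        weightMode = c("equal", "cv_accuracy"), folds = 5,
                        seed = 1, tieBreak = c("svm", "majority_class")) {
    weightMode <- match.arg(weightMode)
    tieBreak <- match.arg(tieBreak)
    d <- .checkXY(x, y)
    svmFit <- do.call(trainSVM, c(list(x = d$x, y = d$y, folds = folds,
                                       seed = seed), svmArgs))
    rfFit <- trainRF(d$x, d$y, nTrees = nTrees, seed = seed + 1L)
    nbFit <- trainNB(d$x, d$y)
    cvAcc <- rep(NA_real_, 3)
    if (weightMode == "equal") {
        weights <- c(1, 1, 1)
    } else {
        fold <- withSeed(seed + 2L,
                         sample(rep(seq_len(folds), length.out = nrow(d$x))))
        hits <- c(svm = 0L, rf = 0L, nb = 0L)
        for (f in seq_len(folds)) {
            tr <- fold != f
            xt <- d$x[tr, , drop = FALSE]; yt <- droplevels(d$y[tr])
            xv <- d$x[!tr, , drop = FALSE]; yv <- d$y[!tr]
            if (nlevels(yt) < 2) stop("degenerate fold: a class is absent")
            sf <- e1071::svm(xt, yt, kernel = "radial", cost = svmFit$C,
                             gamma = svmFit$gamma, scale = FALSE)
            rf <- withSeed(seed + 10L + f,
                           randomForest::randomForest(xt, yt,
                                                      ntree = nTrees))
            nb <- trainNB(xt, yt)
            hits["svm"] <- hits["svm"] + sum(predict(sf, xv) == yv)
            hits["rf"] <- hits["rf"] + sum(predict(rf, xv) == yv)
            hits["nb"] <- hits["nb"] + sum(predictLabels(nb, xv) == yv)
        }
        cvAcc <- as.numeric(hits) / nrow(d$x)
        weights <- cvAcc
        if (all(weights == 0)) weights <- c(1, 1, 1)
    }
    maj <- names(which.max(table(d$y)))
    new("EnsembleModel", svm = svmFit, rf = rfFit, nb = nbFit,
        weights = weights, tieBreak = tieBreak, majorityClass = maj,
        levels = levels(d$y), cvAccuracy = cvAcc)
}

#' Weighted-majority ensemble prediction
#'
#' Each base classifier casts its predicted class per row; a class's score
#' is the sum of the weights of the bases voting for it and the
#' highest-scoring class wins. Exact score ties follow the model's
#' tie-break rule.
#'
#' @param model An [EnsembleModel-class].
#' @param x Feature matrix with the training dimensionality.
#' @param type \code{"label"} (default) or \code{"votes"} (a data.frame
#'   with the three base votes and the final label).
#' @return Factor of predictions, or a data.frame when
#'   \code{type = "votes"}.
#' @export
ensemblePredict <- function(model, x, type = c("label", "votes")) {
    type <- match.arg(type)
    stopifnot(is(model, "EnsembleModel"))
    x <- as.matrix(x)
    votes <- list(svm = predictLabels(model@svm, x),
                  rf = predictLabels(model@rf, x),
                  nb = predictLabels(model@nb, x))
    pred <- voteTally(do.call(cbind, lapply(votes, as.character)),
                      model@weights, model@levels, model@tieBreak,
                      model@majorityClass)
    if (type == "label") return(pred)
    data.frame(svm = votes$svm, rf = votes$rf, nb = votes$nb,
               label = pred, row.names = rownames(x))
}

# weighted vote counting over a n x 3 character matrix of base votes
voteTally <- function(voteMat, weights, levels, tieBreak = "svm",
                      majorityClass = levels[1]) {
    scores <- vapply(levels, function(cl)
        as.numeric((voteMat == cl) %*% weights), numeric(nrow(voteMat)))
    if (nrow(voteMat) == 1L) scores <- matrix(scores, nrow = 1)
    top <- apply(scores, 1, max)
    tied <- rowSums(abs(scores - top) < 1e-12) > 1
    winner <- levels[max.col(scores, ties.method = "first")]
    if (any(tied))
        winner[tied] <- if (tieBreak == "svm") voteMat[tied, 1]
                        else majorityClass
    factor(winner, levels = levels)
}

#' @describeIn fitEnsemble Voting weights (SVM, RF, NB).
#' @param object An \code{EnsembleModel}.
#' @export
ensembleWeights <- function(object) {
    stats::setNames(object@weights, c("svm", "rf", "nb"))
}

#' @export
setMethod("show", "EnsembleModel", function(object) {
    w <- ensembleWeights(object)
    cat(sprintf(
        "EnsembleModel (SVM + RF + NB): weights %.3g/%.3g/%.3g, tie-break %s\n",
        w[1], w[2], w[3], object@tieBreak))
    cat(sprintf("  SVM: C=%g gamma=%g (cv acc %.3f); RF: %d trees\n",
                object@svm$C, object@svm$gamma, object@svm$cvAccuracy,
                object@rf$nTrees))
    invisible(object)
})
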