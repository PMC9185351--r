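#' Train the base classifiers
#'
#' @description
#' Three base learners feed the voting ensemble:
#' \itemize{
#'   \item \code{trainSVM}: a radial-basis-kernel support vector machine
#'     \eqn{K(x_i,x_j) = \exp(-\gamma \|x_i - x_j\|^2)} (libsvm via
#'     \pkg{e1071}). Cost \eqn{C} and \eqn{\gamma} are selected by seeded
#'     \code{folds}-fold cross-validated accuracy over a grid (default: the
#'     canonical \eqn{C \in 2^{-5..15}}, \eqn{\gamma \in 2^{-15..3}} grid in
#'     steps of \eqn{2^2}), ties broken toward smaller \eqn{C} then smaller
#'     \eqn{\gamma}; the winner is refit on all training rows.
#'   \item \code{trainRF}: a 100-tree bootstrap-bagged random forest with
#'     random feature subsetting at each split (\pkg{randomForest});
#'     deterministic for a fixed seed.
#'   \item \code{trainNB}: Gaussian class-conditional naive Bayes with
#'     per-class feature means and variances, variances floored at
#'     \code{1e-9} so constant features contribute nothing to the posterior
#'     ratio.
#'   \item \code{trainKNN}: k-nearest-neighbour (Euclidean distance,
#'     odd \code{k}, distance ties broken by lower training-row index) —
#'     available as a standalone learner for ablations, not part of the
#'     default ensemble.
#' }
#'
#' @param x Numeric feature matrix (rows = peptides).
#' @param y Factor of class labels (two classes, >= 2 samples each).
#' @param cRange,gammaRange SVM grid values.
#' @param folds Cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment / bootstrap.
#' @param nTrees Number of random-forest trees.
#' @param k Neighbourhood size for KNN (odd, <= number of training rows).
#' @return A fitted base-classifier object usable with [predictLabels()].
#' @name baseClassifiers
NULL

.checkXY <- function(x, y) {
    x <- as.matrix(x)
    y <- droplevels(as.factor(y))
    if (nlevels(y) < 2)
        stop("training labels contain a single class")
    if (any(table(y) < 2))
        stop("each class needs at least 2 training samples")
    stopifnot(nrow(x) == length(y))
    list(x = x, y = y)
}

#' @rdname baseClassifiers
#' @export
trainSVM <- function(x, y, cRange = 2^seq(-5, 15, by = 2),
                     gammaRange = 2^seq(-15, 3, by = 2), folds = 5,
                     seed = 1) {
    d <- .checkXY(x, y)
    stopifnot(length(cRange) >= 1, length(gammaRange) >= 1, folds >= 2)
    grid <- expand.grid(C = sort(cRange), gamma = sort(gammaRange))
    grid <- grid[order(grid$C, grid$gamma), ]
    n <- nrow(d$x)
    fold <- withSeed(seed, sample(rep(seq_len(folds), length.out = n)))
    best <- NULL
    bestAcc <- -Inf
    for (g in seq_len(nrow(grid))) {
        hits <- 0L
        ok <- TRUE
        for (f in seq_len(folds)) {
            tr <- fold != f
            if (nlevels(droplevels(d$y[tr])) < 2) { ok <- FALSE; break }
            fit <- e1071::svm(d$x[tr, , drop = FALSE], d$y[tr],
                              kernel = "radial", cost = grid$C[g],
                              gamma = grid$gamma[g], scale = FALSE)
            hits <- hits + sum(predict(fit, d$x[!tr, , drop = FALSE]) ==
                               d$y[!tr])
        }
        if (!ok) next
        acc <- hits / n
        if (acc > bestAcc + 1e-12) {   # strict: earlier (smaller C, gamma) wins ties
            bestAcc <- acc
            best <- grid[g, ]
        }
    }
    if (is.null(best)) stop("no admissible grid point (degenerate folds)")
    fit <- e1071::svm(d$x, d$y, kernel = "radial", cost = best$C,
                      gamma = best$gamma, scale = FALSE)
    structure(list(model = fit, C = best$C, gamma = best$gamma,
                   cvAccuracy = bestAcc, levels = levels(d$y),
                   folds = folds, seed = seed),
              class = "pepSVMFit")
}

#' @rdname baseClassifiers
#' @export
trainRF <- function(x, y, nTrees = 100, seed = 1) {
    d <- .checkXY(x, y)
    fit <- withSeed(seed,
        randomForest::randomForest(d$x, d$y, ntree = nTrees))
    structure(list(model = fit, nTrees = nTrees, seed = seed,
                   levels = levels(d$y)),
              class = "pepRFFit")
}

#' @rdname baseClassifiers
#' @export
trainNB <- function(x, y) {
    d <- .checkXY(x, y)
    cls <- levels(d$y)
    mu <- do.call(rbind, lapply(cls, function(cl)
        colMeans(d$x[d$y == cl, , drop = FALSE])))
    v <- do.call(rbind, lapply(cls, function(cl)
        apply(d$x[d$y == cl, , drop = FALSE], 2, stats::var)))
    v <- pmax(v, 1e-9)
    prior <- as.numeric(table(d$y)[cls]) / length(d$y)
    structure(list(mean = mu, var = v, prior = prior, levels = cls),
              class = "pepNBFit")
}

#' @rdname baseClassifiers
#' @export
trainKNN <- function(x, y, k = 5) {
    d <- .checkXY(x, y)
    k <- as.integer(k)
    if (k %% 2L == 0L) stop("k must be odd (prevents vote ties)")
    if (k > nrow(d$x)) stop("k exceeds the training size")
    structure(list(x = d$x, y = d$y, k = k, levels = levels(d$y)),
              class = "pepKNNFit")
}

#' Predict class labels from a fitted base classifier
#'
#' @param fit A fitted object from [trainSVM()], [trainRF()], [trainNB()]
#'   or [trainKNN()].
#' @param x Numeric matrix with the training dimensionality.
#' @return Factor of predicted labels.
#' @export
predictLabels <- function(fit, x) {
    x <- as.matrix(x)
    UseMethod("predictLabels")
}

#' @export
predictLabels.pepSVMFit <- function(fit, x) {
    factor(as.character(predict(fit$model, x)), levels = fit$levels)
}

#' @export
predictLabels.pepRFFit <- function(fit, x) {
    if (is.null(colnames(x)))
        colnames(x) <- rownames(fit$model$importance)
    factor(as.character(predict(fit$model, x)), levels = fit$levels)
}

#' @export
predictLabels.pepNBFit <- function(fit, x) {
    if (ncol(x) != ncol(fit$mean)) stop("dimension mismatch")
    logPost <- vapply(seq_along(fit$levels), function(ci) {
        mu <- fit$mean[ci, ]
        v <- fit$var[ci, ]
        const <- -0.5 * sum(log(2 * pi * v)) + log(fit$prior[ci])
        const - 0.5 * colSums((t(x) - mu)^2 / v)
    }, numeric(nrow(x)))
    if (nrow(x) == 1L) logPost <- matrix(logPost, nrow = 1)
    factor(fit$levels[max.col(logPost, ties.method = "first")],
           levels = fit$levels)
}

#' @export
predictLabels.pepKNNFit <- function(fit, x) {
    if (ncol(x) != ncol(fit$x)) stop("dimension mismatch")
    pred <- vapply(seq_len(nrow(x)), function(i) {
        d2 <- colSums((t(fit$x) - x[i, ])^2)
        nn <- order(d2)[seq_len(fit$k)]  # stable: ties keep lower row index
        votes <- table(fit$y[nn])
        names(votes)[which.max(votes)]
    }, character(1))
    factor(pred, levels = fit$levels)
}
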