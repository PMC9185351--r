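#' Fit a principal-component pruning model
#'
#' Columns are centered at their training means; the eigenvalues and
#' orthonormal eigenvectors of the sample covariance matrix (divisor
#' \eqn{Q-1} over the \eqn{Q} training rows) are computed via singular value
#' decomposition and sorted in non-increasing order. The retained dimension
#' \eqn{K} is the smallest number of leading components whose cumulative
#' explained-variance ratio reaches \code{retention} (default 0.95), or an
#' explicit \code{k}; in either case \eqn{K} is capped below the number of
#' training rows. Eigenvector signs are fixed so each component's
#' largest-magnitude loading is positive, making fitted models reproducible.
#'
#' @param x Numeric training matrix (rows = peptides, >= 2 rows, all
#'   entries finite).
#' @param retention Cumulative explained-variance target in (0, 1].
#' @param k Optional explicit retained dimension (overrides
#'   \code{retention}).
#' @return A [PCAModel-class].
#' @seealso [transformPCA()]
#' @export
fitPCA <- function(x, retention = 0.95, k = NULL) {
    x <- as.matrix(x)
    if (nrow(x) < 2) stop("PCA requires at least 2 rows")
    if (!all(is.finite(x))) stop("non-finite entries in feature matrix")
    stopifnot(retention > 0, retention <= 1)
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    ev <- pr$sdev^2
    rot <- pr$rotation
    # sign convention: largest-magnitude loading positive
    flip <- vapply(seq_len(ncol(rot)), function(j) {
        jmax <- which.max(abs(rot[, j]))
        rot[jmax, j] < 0
    }, logical(1))
    rot[, flip] <- -rot[, flip, drop = FALSE]
    totalVar <- sum(apply(x, 2, stats::var))
    evr <- cumsum(ev) / totalVar
    kMax <- min(ncol(rot), nrow(x) - 1L)
    if (is.null(k)) {
        k <- which(evr >= retention - 1e-12)[1]
        if (is.na(k)) k <- kMax
    }
    k <- as.integer(min(max(1L, as.integer(k)), kMax))
    new("PCAModel", center = pr$center, eigenvalues = ev, rotation = rot,
        k = k, evr = evr)
}

#' Project a feature matrix onto a fitted PCA model
#'
#' Rows are centered with the training means and projected onto the first
#' \eqn{K} eigenvectors. Projecting the training matrix itself yields
#' scores whose covariance is diagonal with the retained eigenvalues.
#'
#' @param model A [PCAModel-class].
#' @param x Numeric matrix with the model's input dimension.
#' @return Score matrix with \eqn{K} columns named \code{PC1..PCK}.
#' @export
transformPCA <- function(model, x) {
    stopifnot(is(model, "PCAModel"))
    x <- as.matrix(x)
    if (ncol(x) != length(model@center))
        stop("dimension mismatch: data has ", ncol(x),
             " columns, model expects ", length(model@center))
    sc <- sweep(x, 2, model@center) %*%
        model@rotation[, seq_len(model@k), drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(model@k))
    sc
}

#' @describeIn fitPCA Retained dimension K.
#' @param object A \code{PCAModel}.
#' @export
retainedDim <- function(object) object@k

#' @describeIn fitPCA Eigenvalues of the sample covariance matrix.
#' @export
eigenValues <- function(object) object@eigenvalues

#' @describeIn fitPCA Cumulative explained-variance ratio.
#' @export
explainedVariance <- function(object) object@evr

#' @export
setMethod("show", "PCAModel", function(object) {
    cat(sprintf(
        "PCAModel: %d -> %d dims (%.1f%% variance retained)\n",
        length(object@center), object@k,
        100 * object@evr[object@k]))
    invisible(object)
})
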