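#' Train the end-to-end classification pipeline
#'
#' Runs the full workflow on a labelled peptide dataset: identity-based
#' redundancy reduction, stratified 70/30 train/test split, feature
#' encoding (default: all four encoders fused, \eqn{\lambda = 1}),
#' PCA pruning fit on the training rows only, ensemble fitting, and
#' held-out evaluation. The returned [PeptidePipeline-class] carries every
#' fitted component plus a size audit of each stage and a config list that
#' reproduces the run.
#'
#' @param dataset A labelled [PeptideSet-class].
#' @param encoders Ordered subset of \code{c("AAC","DPC","TPC","IPseAAC")}.
#' @param lambda,w,tierMode Improved-PseAAC settings (see
#'   [encodeIPseAAC()]).
#' @param propertyTable A [PropertyTable-class].
#' @param identityThreshold Redundancy threshold; \code{NULL} skips the
#'   filter.
#' @param trainFraction,stratified Split settings (see [splitDataset()]).
#' @param retention,pcaK PCA settings (see [fitPCA()]); set
#'   \code{usePCA = FALSE} to classify in the raw fused space.
#' @param usePCA Apply PCA pruning (default TRUE).
#' @param svmArgs,nTrees,weightMode,folds,tieBreak Ensemble settings (see
#'   [fitEnsemble()]).
#' @param seed Integer seed driving the split, fold assignment and forest.
#' @return A fitted [PeptidePipeline-class].
#' @examples
#' \donttest{
#' ps <- generatePeptides(60, 60, effectSize = 2, seed = 1)
#' pl <- trainPipeline(ps, encoders = c("AAC", "IPseAAC"),
#'                     svmArgs = list(cRange = 2^(0:4), gammaRange = 2^(-4:0)))
#' pipelineMetrics(pl)
#' }
#' @export
trainPipeline <- function(dataset,
                          encoders = c("AAC", "DPC", "TPC", "IPseAAC"),
                          lambda = 1, w = 0.05, tierMode = "canonical",
                          propertyTable = defaultPropertyTable(),
                          identityThreshold = 0.9, trainFraction = 0.7,
                          stratified = TRUE, retention = 0.95, pcaK = NULL,
                          usePCA = TRUE, svmArgs = list(), nTrees = 100,
                          weightMode = "equal", folds = 5,
                          tieBreak = "svm", seed = 1) {
    stopifnot(is(dataset, "PeptideSet"))
    if (anyNA(peptideLabels(dataset)))
        stop("training requires a fully labelled dataset")
    sizes <- c(input = length(dataset))
    if (!is.null(identityThreshold)) {
        dataset <- reduceRedundancy(dataset, identityThreshold)
    }
    sizes["after_redundancy"] <- length(dataset)
    parts <- splitDataset(dataset, trainFraction, stratified, seed)
    sizes["train"] <- length(parts$train)
    sizes["test"] <- length(parts$test)
    xTrain <- encodeDataset(parts$train, encoders, lambda, w,
                            propertyTable, tierMode)
    pca <- NULL
    if (usePCA) {
        pca <- fitPCA(xTrain, retention = retention, k = pcaK)
        xTrain <- transformPCA(pca, xTrain)
    }
    ens <- fitEnsemble(xTrain, peptideLabels(parts$train),
                       svmArgs = svmArgs, nTrees = nTrees,
                       weightMode = weightMode, folds = folds,
                       seed = seed, tieBreak = tieBreak)
    pl <- new("PeptidePipeline", encoders = encoders,
              lambda = as.integer(lambda), w = w, tierMode = tierMode,
              propertyTable = propertyTable, pca = pca, ensemble = ens,
              trainIds = peptideIds(parts$train),
              testIds = peptideIds(parts$test),
              metrics = numeric(0),
              confusion = new("ConfusionMatrix", tp = 0L, tn = 0L,
                              fp = 0L, fn = 0L),
              log = as.integer(sizes),
              config = list(encoders = encoders, lambda = lambda, w = w,
                            tierMode = tierMode,
                            identityThreshold = identityThreshold,
                            trainFraction = trainFraction,
                            stratified = stratified,
                            retention = retention, pcaK = pcaK,
                            usePCA = usePCA, svmArgs = svmArgs,
                            nTrees = nTrees, weightMode = weightMode,
                            folds = folds, tieBreak = tieBreak,
                            seed = seed))
    names(pl@log) <- names(sizes)
    ev <- evaluatePipeline(parts$test, pl)
    pl@metrics <- stats::setNames(as.numeric(ev$metrics),
                                  names(ev$metrics))
    pl@confusion <- ev$confusion
    pl
}

#' Classify new peptides with a fitted pipeline
#'
#' @param pipeline A fitted [PeptidePipeline-class].
#' @param x A [PeptideSet-class] of sequences meeting the pipeline's
#'   encoder length preconditions.
#' @return A data.frame with \code{id}, the three base-classifier votes and
#'   the final \code{label}.
#' @export
predictPipeline <- function(pipeline, x) {
    stopifnot(is(pipeline, "PeptidePipeline"), is(x, "PeptideSet"))
    if (length(x) == 0) {
        return(data.frame(id = character(0), svm = character(0),
                          rf = character(0), nb = character(0),
                          label = character(0)))
    }
    feat <- encodeDataset(x, pipeline@encoders, pipeline@lambda,
                          pipeline@w, pipeline@propertyTable,
                          pipeline@tierMode)
    if (!is.null(pipeline@pca)) feat <- transformPCA(pipeline@pca, feat)
    votes <- ensemblePredict(pipeline@ensemble, feat, type = "votes")
    cbind(data.frame(id = peptideIds(x)), votes)
}

#' @describeIn trainPipeline Held-out test metrics of the fitted pipeline.
#' @param pipeline A fitted \code{PeptidePipeline}.
#' @export
pipelineMetrics <- function(pipeline) pipeline@metrics

#' @export
setMethod("show", "PeptidePipeline", function(object) {
    cat(sprintf("PeptidePipeline: %s, lambda=%d%s\n",
                paste(object@encoders, collapse = "+"), object@lambda,
                if (!is.null(object@pca))
                    sprintf(", PCA -> %d dims", object@pca@k) else ""))
    cat("  sizes:", paste(sprintf("%s=%d", names(object@log), object@log),
                          collapse = " "), "\n")
    if (length(object@metrics)) {
        m <- object@metrics
        cat(sprintf(
            "  test: acc %.2f%% sn %.2f%% sp %.2f%% F1 %.2f%% MCC %.2f\n",
            100 * m["accuracy"], 100 * m["sensitivity"],
            100 * m["specificity"], 100 * m["f1"], m["mcc"]))
    }
    invisible(object)
})

#' Run the 13-model ablation design
#'
#' Evaluates the full ablation grid on one dataset: the four single
#' encoders, the six pairwise fusions, and the all-four fusion with PCA at
#' \eqn{\lambda \in \{1, 2, 3\}} — thirteen pipelines sharing the same
#' redundancy filter, split seed and ensemble settings — and tabulates the
#' five metrics per model.
#'
#' @inheritParams trainPipeline
#' @param lambdaValues Lambda values for the fused + PCA rows.
#' @return A data.frame with one row per model: \code{model},
#'   \code{n_features}, \code{pca_dims}, and the five metrics (proportions;
#'   MCC on its native scale).
#' @export
runAblation <- function(dataset, lambdaValues = c(1, 2, 3),
                        identityThreshold = 0.9, svmArgs = list(),
                        nTrees = 100, weightMode = "equal",
                        retention = 0.95, seed = 1, ...) {
    single <- as.list(c("AAC", "DPC", "TPC", "IPseAAC"))
    pairs <- utils::combn(c("AAC", "DPC", "TPC", "IPseAAC"), 2, simplify = FALSE)
    specs <- c(lapply(c(single, pairs), function(e)
                   list(encoders = e, lambda = 1, usePCA = FALSE)),
               lapply(lambdaValues, function(l)
                   list(encoders = c("AAC", "DPC", "TPC", "IPseAAC"),
                        lambda = l, usePCA = TRUE)))
    rows <- lapply(specs, function(sp) {
        pl <- trainPipeline(dataset, encoders = sp$encoders,
                            lambda = sp$lambda, usePCA = sp$usePCA,
                            identityThreshold = identityThreshold,
                            svmArgs = svmArgs, nTrees = nTrees,
                            weightMode = weightMode, retention = retention,
                            seed = seed, ...)
        nFeat <- sum(c(AAC = 20, DPC = 400, TPC = 8000,
                       IPseAAC = 20 + sp$lambda)[sp$encoders])
        m <- pipelineMetrics(pl)
        data.frame(model = if (sp$usePCA)
                       sprintf("fused+PCA (lambda=%d)", sp$lambda)
                   else paste(sp$encoders, collapse = "+"),
                   n_features = nFeat,
                   pca_dims = if (sp$usePCA) pl@pca@k else NA_integer_,
                   accuracy = m[["accuracy"]],
                   sensitivity = m[["sensitivity"]],
                   specificity = m[["specificity"]],
                   mcc = m[["mcc"]], f1 = m[["f1"]])
    })
    do.call(rbind, rows)
}
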