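test_that("grid-searched SVM separates blobs and honours forced grids", {
    bl <- makeBlobs(n = 25, seed = 101)
    fit <- trainSVM(bl$x, bl$y, cRange = 2^c(-1, 1, 3),
                    gammaRange = 2^c(-3, -1), seed = 1)
    expect_identical(unname(predictLabels(fit, bl$x)), unname(bl$y))
    # grid of size 1: that point is selected
    one <- trainSVM(bl$x, bl$y, cRange = 4, gammaRange = 0.25, seed = 1)
    expect_equal(one$C, 4)
    expect_equal(one$gamma, 0.25)
    expect_error(trainSVM(bl$x, rep("ACP", nrow(bl$x))), "single class")
})

test_that("SVM cross-validated accuracy is near chance under the null", {
    set.seed(103)
    accs <- replicate(30, {
        x <- matrix(rnorm(60 * 4), 60, 4)
        y <- factor(rep(c("ACP", "NACP"), each = 30))
        trainSVM(x, y, cRange = 1, gammaRange = 0.25,
                 seed = sample.int(1e6, 1))$cvAccuracy
    })
    expect_gt(mean(accs), 0.4)
    expect_lt(mean(accs), 0.6)
})

test_that("random forest is seeded-deterministic and accurate on blobs", {
    bl <- makeBlobs(n = 30, seed = 107)
    f1 <- trainRF(bl$x, bl$y, seed = 5)
    f2 <- trainRF(bl$x, bl$y, seed = 5)
    expect_identical(predictLabels(f1, bl$x), predictLabels(f2, bl$x))
    expect_equal(f1$model$ntree, 100)
    # out-of-bag accuracy on separable data
    oob <- 1 - f1$model$err.rate[f1$model$ntree, "OOB"]
    expect_gt(oob, 0.95)
    # single-tree forest equals one bootstrapped tree's prediction
    t1 <- trainRF(bl$x, bl$y, nTrees = 1, seed = 9)
    expect_identical(predictLabels(t1, bl$x),
                     factor(as.character(predict(t1$model, bl$x)),
                            levels = t1$levels))
})

test_that("Gaussian naive Bayes has the closed-form decision boundary", {
    set.seed(109)
    # 1-D, means +-3, unit variance, equal priors: boundary at 0
    x <- matrix(c(rnorm(2000, 3), rnorm(2000, -3)), ncol = 1)
    y <- factor(rep(c("ACP", "NACP"), each = 2000))
    fit <- trainNB(x, y)
    grid <- matrix(seq(-1, 1, by = 0.01), ncol = 1)
    pred <- predictLabels(fit, grid)
    crossover <- grid[max(which(pred == "NACP" & grid < 0.5))]
    expect_lt(abs(crossover), 0.2)
    # agrees with e1071's Gaussian NB on fresh data
    ref <- e1071::naiveBayes(data.frame(f1 = x[, 1]), y)
    newx <- matrix(rnorm(100, 0, 4), ncol = 1)
    expect_identical(
        as.character(predictLabels(fit, newx)),
        as.character(predict(ref, data.frame(f1 = newx[, 1]))))
    # constant feature contributes nothing to the posterior ratio
    x2 <- cbind(x, 7)
    fit2 <- trainNB(x2, y)
    expect_identical(predictLabels(fit2, cbind(grid, 7)), pred)
    # uninformative features: posterior follows the prior
    set.seed(110)
    xu <- matrix(rnorm(90), ncol = 1)
    yu <- factor(c(rep("ACP", 60), rep("NACP", 30)))
    fitu <- trainNB(xu, yu)
    expect_equal(fitu$prior, c(2 / 3, 1 / 3))
})

test_that("KNN matches exhaustive distance enumeration", {
    # 5-point hand dataset
    x <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5), ncol = 2, byrow = TRUE)
    y <- factor(c("ACP", "ACP", "ACP", "NACP", "NACP"),
                levels = c("ACP", "NACP"))
    fit <- trainKNN(x, y, k = 3)
    queries <- matrix(c(0.2, 0.2, 5.5, 5, 2.5, 2.5, 0, 0), ncol = 2,
                      byrow = TRUE)
    got <- predictLabels(fit, queries)
    oracle <- apply(queries, 1, function(q) {
        d <- sqrt(colSums((t(x) - q)^2))
        nn <- order(d, seq_along(d))[1:3]
        names(sort(table(as.character(y[nn])), decreasing = TRUE))[1]
    })
    expect_identical(as.character(got), oracle)
    # k = 1 at a training row returns that row's label
    expect_identical(as.character(predictLabels(trainKNN(x, y, 1),
                                                x[4, , drop = FALSE])),
                     "NACP")
    # k = n: global majority everywhere
    expect_identical(as.character(predictLabels(trainKNN(x, y, 5),
                                                matrix(c(100, 100), 1))),
                     "ACP")
    expect_error(trainKNN(x, y, 2), "odd")
    expect_error(trainKNN(x, y, 7), "training size")
})

test_that("base trainers are invariant to test row order", {
    bl <- makeBlobs(n = 20, seed = 127)
    test <- makeBlobs(n = 10, seed = 128)$x
    perm <- sample(nrow(test))
    svmF <- trainSVM(bl$x, bl$y, cRange = 1, gammaRange = 0.25)
    rfF <- trainRF(bl$x, bl$y, seed = 2)
    nbF <- trainNB(bl$x, bl$y)
    for (fit in list(svmF, rfF, nbF)) {
        straight <- predictLabels(fit, test)
        permuted <- predictLabels(fit, test[perm, ])
        expect_identical(unname(straight[perm]), unname(permuted))
    }
})
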