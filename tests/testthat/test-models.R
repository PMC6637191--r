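test_that("AUC is the Mann-Whitney probability with ties at one half", {
    expect_equal(aucScore(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
    expect_equal(aucScore(1:10, c(rep(0, 5), rep(1, 5))), 1)
    expect_equal(aucScore(10:1, c(rep(0, 5), rep(1, 5))), 0)
    expect_equal(aucScore(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
    expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("linear families reproduce sigmoid(w.x + b) from exported weights", {
    set.seed(2)
    X <- matrix(rnorm(400), 80, 5)
    y <- as.integer(X[, 2] - X[, 4] + rnorm(80, sd = 0.7) > 0)
    for (fam in c("lr_l1", "lr_l2", "lr_elasticnet")) {
        fit <- fitModel(fam, X, y, hyper = list(lambda = 0.02))
        manual <- plogis(drop(X %*% modelWeights(fit)) + fit@bias)
        expect_equal(predictScore(fit, X), manual, tolerance = 1e-8)
        glmnetP <- as.numeric(predict(fit@fit, X, type = "response"))
        expect_equal(unname(predictScore(fit, X)), glmnetP,
                     tolerance = 1e-8)
    }
})

test_that("Lasso behaves at the penalty extremes", {
    set.seed(3)
    X <- cbind(c(rep(0, 20), rep(1, 20)), rnorm(40))
    y <- c(rep(0L, 20), rep(1L, 20))
    fit <- fitModel("lr_l1", X, y, hyper = list(lambda = 1e-4))
    expect_equal(aucScore(predictScore(fit, X), y), 1)    # separable
    fitInf <- fitModel("lr_l1", X, y, hyper = list(lambda = 1e6))
    expect_true(all(modelWeights(fitInf) == 0))           # penalty limit
})

test_that("number of nonzero Lasso weights is non-increasing in lambda", {
    set.seed(4)
    X <- matrix(rnorm(3000), 150, 20)
    y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(150) > 0)
    nz <- sapply(c(1e-4, 1e-3, 1e-2, 1e-1, 1), function(l)
        sum(modelWeights(fitModel("lr_l1", X, y,
                                  hyper = list(lambda = l))) != 0))
    expect_true(all(diff(nz) <= 0))
})

test_that("the random-weight model scores around 0.5 without training", {
    ds <- smallSim(nCases = 700, nControls = 1300, nSnps = 50,
                   nCausal = 5, seed = 23)
    sp <- splitTrainTest(ds, seed = 2)
    Xtr <- encodeGenotypes(sp$train, "sum")
    Xte <- encodeGenotypes(sp$test, "sum")
    fit <- fitModel("random", Xtr, phenotype(sp$train), seed = 31)
    auc <- aucScore(predictScore(fit, Xte), phenotype(sp$test))
    expect_gt(auc, 0.42); expect_lt(auc, 0.58)
    ## deterministic under seed, different across seeds
    fit2 <- fitModel("random", Xtr, phenotype(sp$train), seed = 31)
    expect_identical(modelWeights(fit), modelWeights(fit2))
    fit3 <- fitModel("random", Xtr, phenotype(sp$train), seed = 32)
    expect_false(identical(modelWeights(fit), modelWeights(fit3)))
})

test_that("every non-random family learns simulated signal", {
    ds <- simulateGenotypes(simConfig(nCases = 700, nControls = 1300,
                                      nSnps = 40, nCausal = 8,
                                      causalOrRange = c(1.5, 2.5),
                                      seed = 24))
    sp <- splitTrainTest(ds, seed = 3)
    Xtr <- encodeGenotypes(sp$train, "sum")
    Xte <- encodeGenotypes(sp$test, "sum")
    ytr <- phenotype(sp$train); yte <- phenotype(sp$test)
    for (fam in c("lr_l1", "lr_l2", "gbt", "nn_dense", "nn_residual")) {
        hyper <- switch(fam, gbt = list(nrounds = 60),
                        nn_dense = list(epochs = 15, nLayers = 2),
                        nn_residual = list(epochs = 15, nLayers = 3),
                        list(lambda = 0.01))
        fit <- fitModel(fam, Xtr, ytr, hyper = hyper, seed = 5)
        expect_gt(aucScore(predictScore(fit, Xte), yte), 0.55)
    }
})

test_that("residual networks require an odd hidden-layer count", {
    X <- matrix(rnorm(200), 50, 4); y <- rep(c(0L, 1L), 25)
    expect_error(fitModel("nn_residual", X, y,
                          hyper = list(nLayers = 2, epochs = 2)), "odd")
})

test_that("hyper-parameter selection maximizes cross-validated AUC", {
    set.seed(6)
    X <- matrix(rnorm(4000), 200, 20)
    y <- as.integer(X[, 1] + X[, 2] + rnorm(200, sd = 0.5) > 0)
    ## single-point grid: identity
    sel1 <- selectHyperparameters("lr_l1", X, y,
                                  grid = list(lambda = 0.01), k = 5)
    expect_equal(sel1$hyper$lambda, 0.01)
    ## huge vs tiny penalty on signal data: tiny wins
    sel2 <- selectHyperparameters("lr_l1", X, y,
                                  grid = list(lambda = c(1e3, 1e-3)),
                                  k = 5)
    expect_equal(sel2$hyper$lambda, 1e-3)
    expect_gt(sel2$cvAUC["mean"], 0.7)
    ## k = 10 on n = 100 gives folds of size 10
    f <- stratifiedFolds(rep(c(0L, 1L), 50), k = 10, seed = 1)
    expect_true(all(table(f) == 10))
    expect_error(stratifiedFolds(c(0L, 1L, 1L), k = 2), "class")
})

test_that("ensemble averaging is the unweighted mean of member scores", {
    set.seed(7)
    X <- matrix(rnorm(500), 100, 5)
    y <- as.integer(X[, 1] + rnorm(100, sd = 0.6) > 0)
    f1 <- fitModel("lr_l1", X, y, hyper = list(lambda = 0.01))
    f2 <- fitModel("lr_l2", X, y, hyper = list(lambda = 0.01))
    f3 <- fitModel("gbt", X, y, hyper = list(nrounds = 30))
    ens <- ensembleAverage(list(f1, f2, f3), X)
    expect_equal(ens, (predictScore(f1, X) + predictScore(f2, X) +
                       predictScore(f3, X)) / 3)
    ## identical members return member scores
    expect_equal(ensembleAverage(list(f1, f1), X), predictScore(f1, X))
    ## ensemble at least matches the weakest member on the same data
    aucs <- sapply(list(f1, f2, f3), function(f)
        aucScore(predictScore(f, X), y))
    expect_gte(aucScore(ens, y), min(aucs))
    expect_error(ensembleAverage(list(f1), X))
})
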