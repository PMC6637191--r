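#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a randomly chosen case is
#' scored above a randomly chosen control, with ties counted one half.
#'
#' @param scores numeric score vector.
#' @param y binary 0/1 labels.
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
#' @export
aucScore <- function(scores, y) {
    stopifnot(length(scores) == length(y))
    y <- as.integer(y)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute AUC")
    r <- rank(scores)
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.fmValues <- function(X) {
    if (is(X, "FeatureMatrix")) featureValues(X) else as.matrix(X)
}
.fmCoding <- function(X) if (is(X, "FeatureMatrix")) coding(X) else "sum"

.modelFamilies <- c("lr_l1", "lr_l2", "lr_elasticnet", "gbt",
                    "nn_dense", "nn_residual", "random")

#' Fit a classifier family on an encoded feature matrix
#'
#' Uniform entry point for the model families compared in this package:
#' penalized logistic regressions (\code{lr_l1} Lasso, \code{lr_l2} Ridge,
#' \code{lr_elasticnet}), gradient boosted trees (\code{gbt}), dense and
#' pre-activation residual neural networks (\code{nn_dense},
#' \code{nn_residual}) and the \code{random} null model, which assigns
#' i.i.d. standard-normal weights to the features and applies a sigmoid to
#' the weighted sum without any training. The random model calibrates what
#' feature-importance pipelines report when the classifier carries no
#' information: its held-out AUC is ~0.5 on any fold.
#'
#' Hyper-parameters (all optional, via \code{hyper}): linear families
#' \code{lambda} (penalty, default 0.01) and \code{alpha} (elastic-net
#' mixing, fixed at 1/0 for Lasso/Ridge, default 0.5 for elasticnet);
#' \code{gbt}: \code{nrounds} (150), \code{eta} (0.1), \code{maxDepth}
#' (4); networks: \code{nLayers} (1 dense, 3 residual), \code{width} (64),
#' \code{epochs} (40), \code{batch} (128), \code{lr} (1e-3).
#'
#' @param family one of the family strings above.
#' @param X a \linkS4class{FeatureMatrix} (or plain numeric matrix).
#' @param y binary 0/1 phenotype vector.
#' @param hyper named list of hyper-parameters.
#' @param seed integer seed, recorded in the fit.
#' @return A \linkS4class{FittedModel}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(600), 100, 6)
#' y <- as.integer(X[, 1] + rnorm(100, sd = .5) > 0)
#' fit <- fitModel("lr_l1", X, y, hyper = list(lambda = 0.01), seed = 1)
#' aucScore(predictScore(fit, X), y) > 0.8
#' @export
fitModel <- function(family, X, y, hyper = list(), seed = 1L) {
    family <- match.arg(family, .modelFamilies)
    Xv <- .fmValues(X)
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
    if (family != "random" && length(unique(y)) < 2L)
        stop("y must contain both classes")
    p <- ncol(Xv)
    seed <- as.integer(seed)

    if (family %in% c("lr_l1", "lr_l2", "lr_elasticnet")) {
        alpha <- switch(family, lr_l1 = 1, lr_l2 = 0,
                        lr_elasticnet = if (is.null(hyper$alpha)) 0.5
                                        else hyper$alpha)
        lambda <- if (is.null(hyper$lambda)) 0.01 else hyper$lambda
        fit <- glmnet::glmnet(Xv, y, family = "binomial", alpha = alpha,
                              lambda = lambda, standardize = TRUE)
        cf <- as.numeric(stats::coef(fit))
        w <- cf[-1]; b <- cf[1]
        return(new("FittedModel", family = family, coding = .fmCoding(X),
                   weights = stats::setNames(w, colnames(Xv)), bias = b,
                   gains = numeric(0), fit = fit,
                   hyper = list(lambda = lambda, alpha = alpha),
                   seed = seed, cvAUC = c(NA_real_, NA_real_)))
    }

    if (family == "gbt") {
        h <- utils::modifyList(list(nrounds = 150L, eta = 0.1,
                                    maxDepth = 4L), hyper)
        dtr <- xgboost::xgb.DMatrix(Xv, label = y)
        bst <- xgboost::xgb.train(
            params = list(objective = "binary:logistic", eta = h$eta,
                          max_depth = h$maxDepth, nthread = 1L,
                          seed = seed),
            data = dtr, nrounds = h$nrounds, verbose = 0)
        imp <- xgboost::xgb.importance(model = bst)
        gains <- stats::setNames(numeric(p), colnames(Xv))
        gains[imp$Feature] <- imp$Gain
        return(new("FittedModel", family = family, coding = .fmCoding(X),
                   weights = numeric(0), bias = NA_real_, gains = gains,
                   fit = bst, hyper = h, seed = seed,
                   cvAUC = c(NA_real_, NA_real_)))
    }

    if (family %in% c("nn_dense", "nn_residual")) {
        residual <- family == "nn_residual"
        h <- utils::modifyList(
            list(nLayers = if (residual) 3L else 1L, width = 64L,
                 epochs = 40L, batch = 128L, lr = 1e-3), hyper)
        fit <- mlpFit(Xv, y, nLayers = h$nLayers, width = h$width,
                      residual = residual, epochs = h$epochs,
                      batch = h$batch, lr = h$lr, seed = seed)
        return(new("FittedModel", family = family, coding = .fmCoding(X),
                   weights = numeric(0), bias = NA_real_,
                   gains = numeric(0), fit = fit, hyper = h, seed = seed,
                   cvAUC = c(NA_real_, NA_real_)))
    }

    ## random-weight null model: no training at all
    set.seed(deriveSeed(seed, "random-weights"))
    w <- stats::rnorm(p)
    new("FittedModel", family = "random", coding = .fmCoding(X),
        weights = stats::setNames(w, colnames(Xv)), bias = 0,
        gains = numeric(0), fit = NULL, hyper = list(), seed = seed,
        cvAUC = c(NA_real_, NA_real_))
}

#' Score samples with a fitted model
#'
#' @param model a \linkS4class{FittedModel}.
#' @param X a \linkS4class{FeatureMatrix} or numeric matrix with the same
#'   feature columns the model was trained on.
#' @return Numeric vector of probabilities in [0, 1]. For linear and
#'   random families this is exactly \code{sigmoid(X w + b)} computed from
#'   the exported weights.
#' @export
predictScore <- function(model, X) {
    stopifnot(is(model, "FittedModel"))
    Xv <- .fmValues(X)
    if (model@family %in% c("lr_l1", "lr_l2", "lr_elasticnet", "random"))
        return(sigmoid(drop(Xv %*% model@weights) + model@bias))
    if (model@family == "gbt")
        return(stats::predict(model@fit, xgboost::xgb.DMatrix(Xv)))
    mlpPredict(model@fit, Xv)
}

#' Stratified k-fold assignment
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold id per sample, classes balanced across folds.
#' @export
stratifiedFolds <- function(y, k, seed = 1L) {
    y <- as.integer(y)
    if (k > min(table(y))) stop("k exceeds the size of a class")
    set.seed(seed)
    fold <- integer(length(y))
    for (cls in unique(y)) {
        ix <- which(y == cls)
        fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
    fold
}

#' Select hyper-parameters by stratified cross-validated AUC
#'
#' Evaluates every point of a named grid by k-fold stratified
#' cross-validation and returns the point maximizing mean validation AUC.
#' Ties are broken toward the stronger regularization (larger penalty,
#' fewer boosting rounds, shallower trees, fewer layers).
#'
#' @param family model family string.
#' @param X feature matrix; @param y binary labels.
#' @param grid named list of hyper-parameter vectors (expanded to its
#'   Cartesian product).
#' @param k fold count (default 10).
#' @param seed integer seed.
#' @return A list with \code{hyper} (best point), \code{cvAUC}
#'   (mean, sd at the best point) and \code{tableau} (per-point results).
#' @export
selectHyperparameters <- function(family, X, y, grid, k = 10L, seed = 1L) {
    stopifnot(length(grid) >= 1)
    Xv <- .fmValues(X); y <- as.integer(y)
    pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
    ## order stronger regularization first so which.max break ties there
    strength <- rep(0, nrow(pts))
    if ("lambda" %in% names(pts)) strength <- strength + rank(pts$lambda)
    for (nm in c("nrounds", "maxDepth", "nLayers"))
        if (nm %in% names(pts)) strength <- strength - rank(pts[[nm]])
    pts <- pts[order(-strength), , drop = FALSE]
    fold <- stratifiedFolds(y, k, seed = deriveSeed(seed, "cvfolds"))
    res <- matrix(NA_real_, nrow(pts), k)
    for (i in seq_len(nrow(pts))) {
        hp <- as.list(pts[i, , drop = FALSE])
        for (f in seq_len(k)) {
            tr <- fold != f
            m <- fitModel(family, Xv[tr, , drop = FALSE], y[tr],
                          hyper = hp, seed = deriveSeed(seed, "cvfit"))
            res[i, f] <- aucScore(predictScore(m, Xv[!tr, , drop = FALSE]),
                                  y[!tr])
        }
    }
    mu <- rowMeans(res)
    best <- which.max(mu)
    list(hyper = as.list(pts[best, , drop = FALSE]),
         cvAUC = c(mean = mu[best], sd = stats::sd(res[best, ])),
         tableau = cbind(pts, meanAUC = mu))
}

#' Average-probability model ensemble
#'
#' @param models list of \linkS4class{FittedModel}s trained on the same
#'   coding.
#' @param X feature matrix to score.
#' @return Per-sample unweighted mean of the member probabilities.
#' @export
ensembleAverage <- function(models, X) {
    stopifnot(length(models) >= 2)
    cods <- vapply(models, function(m) m@coding, character(1))
    if (length(unique(cods)) != 1L)
        stop("ensemble members must share the feature coding")
    rowMeans(vapply(models, function(m) predictScore(m, X),
                    numeric(nrow(.fmValues(X)))))
}
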