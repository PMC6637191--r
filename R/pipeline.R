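#' Stratified train/test split
#'
#' Randomly permutes samples under the seed and assigns
#' \code{round(frac * n)} of them to the training set, stratified by
#' class: the training set receives \code{round(frac * n_cases)} cases
#' and the remainder in controls, so the case/control ratio of both parts
#' matches the full dataset to within one sample.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param frac training fraction in (0, 1), default 2/3.
#' @param seed integer seed.
#' @return List with \code{train} and \code{test}
#'   \linkS4class{GenotypeData} objects and the index vectors
#'   \code{trainIdx}, \code{testIdx}.
#' @export
splitTrainTest <- function(ds, frac = 2/3, seed = 1L) {
    n <- nSamples(ds)
    if (n < 3) stop("need at least 3 samples to split")
    stopifnot(frac > 0, frac < 1)
    y <- phenotype(ds)
    if (length(unique(y[!is.na(y)])) < 2)
        stop("both classes must be present")
    nTrain <- round(frac * n)
    n1 <- sum(y == 1L)
    n1t <- round(frac * n1)
    n0t <- nTrain - n1t
    set.seed(seed)
    caseIdx <- sample(which(y == 1L))
    ctrlIdx <- sample(which(y == 0L))
    trainIdx <- sort(c(caseIdx[seq_len(n1t)], ctrlIdx[seq_len(n0t)]))
    testIdx <- setdiff(seq_len(n), trainIdx)
    list(train = ds[, trainIdx], test = ds[, testIdx],
         trainIdx = trainIdx, testIdx = testIdx)
}

#' Repeated stratified splits ("refolds") for stability analyses
#'
#' Permutes the data \code{nRefolds} times and re-divides it into
#' train/test sets of the same proportion, with per-refold seeds derived
#' deterministically from the global seed. Ten refolds feed 45 intra-model
#' list pairs downstream.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param nRefolds number of independent splits (>= 2 for robustness
#'   analyses).
#' @param frac training fraction.
#' @param seed global integer seed.
#' @return List of \code{nRefolds} split lists (see
#'   \code{\link{splitTrainTest}}).
#' @export
makeRefolds <- function(ds, nRefolds = 10L, frac = 2/3, seed = 1L) {
    stopifnot(nRefolds >= 1)
    lapply(seq_len(nRefolds), function(i)
        splitTrainTest(ds, frac = frac,
                       seed = deriveSeed(seed, paste0("refold", i))))
}

#' Subsample controls to a target case/control ratio
#'
#' Removes controls at random until cases/controls reaches the target
#' (within one sample); cases are never touched.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param targetRatio desired cases/controls, must be >= the current
#'   ratio.
#' @param seed integer seed.
#' @return The subsampled \linkS4class{GenotypeData}.
#' @export
subsampleRatio <- function(ds, targetRatio, seed = 1L) {
    y <- phenotype(ds)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    cur <- n1 / n0
    if (targetRatio < cur - 1e-12)
        stop("target ratio ", targetRatio, " is below the current ratio ",
             signif(cur, 3), "; controls can only be removed")
    nKeep <- min(n0, round(n1 / targetRatio))
    set.seed(seed)
    keepCtrl <- sort(sample(which(y == 0L), nKeep))
    ds[, sort(c(which(y == 1L), keepCtrl))]
}

.defaultCriterion <- function(family) {
    switch(family, lr_l1 = , lr_l2 = , lr_elasticnet = , random = "weight",
           gbt = "gain", "PFI")
}

#' Configuration for a full experiment
#'
#' @param sim a \code{\link{simConfig}} (used when \code{data} is NULL).
#' @param data optional \linkS4class{GenotypeData} to analyse instead of
#'   simulating.
#' @param subsampleRatio optional target case/control ratio.
#' @param qc list of QC thresholds or NULL to skip QC.
#' @param impute imputation strategy string.
#' @param coding genotype coding string.
#' @param mafMin,pMax preselection thresholds.
#' @param screenFullData if TRUE, preselect once on the full dataset before
#'   splitting (reproduces published screening protocols that consult all
#'   samples); default FALSE preselects on each training split only, which
#'   avoids leaking test labels into feature selection.
#' @param trainFrac training fraction.
#' @param nRefolds number of refolds.
#' @param models list of model specs: each a list with \code{family},
#'   optional \code{hyper}, optional \code{grid} (hyper-parameter grid for
#'   cross-validated selection), optional \code{criterion} (importance
#'   criterion; defaults per family: weight for linear/random, gain for
#'   trees, PFI otherwise).
#' @param cvFolds folds for hyper-parameter selection (default 10).
#' @param xGrid prefix lengths for robustness curves.
#' @param seed global seed.
#' @return A list of class \code{"experimentConfig"}.
#' @export
experimentConfig <- function(sim = simConfig(), data = NULL,
                             subsampleRatio = NULL,
                             qc = list(sampleMissMax = 0.05,
                                       snpMissMax = 0.02,
                                       hwePMin = 1e-10),
                             impute = "HWa", coding = "sum",
                             mafMin = 0.01, pMax = 1e-4,
                             screenFullData = FALSE, trainFrac = 2/3,
                             nRefolds = 10L,
                             models = list(list(family = "lr_l1")),
                             cvFolds = 10L,
                             xGrid = c(5L, 10L, 25L, 50L), seed = 1L) {
    cfg <- as.list(environment())
    class(cfg) <- "experimentConfig"
    cfg
}

#' Run a full classification and feature-stability experiment
#'
#' Orchestrates the pipeline end to end: simulate (or take) a dataset,
#' optionally subsample controls, apply QC, impute, draw stratified
#' refolds, preselect SNPs (on the training split of each refold by
#' default), encode, fit every configured model, score the test split,
#' compute the configured feature-importance criterion, aggregate scores
#' to 500 kb loci on the original and the 250 kb-shifted ("bis")
#' partitions, and summarize intra-model robustness across refolds. Every
#' random stage derives its seed from the global seed, so a rerun with the
#' same configuration reproduces the report exactly.
#'
#' @param cfg an \code{\link{experimentConfig}}.
#' @return A list of class \code{"experimentReport"}: per-model test AUCs
#'   and rankings per refold, preselection tallies, robustness curves and
#'   the QC report.
#' @export
runExperiment <- function(cfg) {
    stopifnot(inherits(cfg, "experimentConfig"))
    ds <- if (is.null(cfg$data)) simulateGenotypes(cfg$sim) else cfg$data
    if (!is.null(cfg$subsampleRatio))
        ds <- subsampleRatio(ds, cfg$subsampleRatio,
                             seed = deriveSeed(cfg$seed, "subsample"))
    qcReport <- NULL
    if (!is.null(cfg$qc)) {
        qc <- applyQC(ds, cfg$qc$sampleMissMax, cfg$qc$snpMissMax,
                      cfg$qc$hwePMin)
        ds <- qc$data; qcReport <- qc$report
    }
    ds <- imputeGenotypes(ds, cfg$impute,
                          seed = deriveSeed(cfg$seed, "impute"))
    partFull0 <- buildPartition(ds, shiftBp = 0)
    partFullB <- buildPartition(ds, shiftBp = 250000)

    presFull <- NULL
    if (cfg$screenFullData)
        presFull <- preselectSnps(associationTests(ds), cfg$mafMin,
                                  cfg$pMax)
    folds <- makeRefolds(ds, cfg$nRefolds, cfg$trainFrac, cfg$seed)

    perFold <- vector("list", cfg$nRefolds)
    for (f in seq_len(cfg$nRefolds)) {
        sp <- folds[[f]]
        pres <- if (cfg$screenFullData) presFull
                else preselectSnps(associationTests(sp$train),
                                   cfg$mafMin, cfg$pMax)
        keep <- match(pres$union, rownames(genotypes(ds)))
        keep <- sort(keep[!is.na(keep)])
        if (length(keep) == 0)
            stop("stage preselect: empty union at refold ", f)
        trainSub <- sp$train[keep, ]; testSub <- sp$test[keep, ]
        Xtr <- encodeGenotypes(trainSub, cfg$coding)
        Xte <- encodeGenotypes(testSub, cfg$coding)
        ytr <- phenotype(trainSub); yte <- phenotype(testSub)
        part0 <- partFull0[keep, , drop = FALSE]
        partB <- partFullB[keep, , drop = FALSE]

        fits <- list()
        for (ms in cfg$models) {
            fam <- ms$family
            hyper <- if (is.null(ms$hyper)) list() else ms$hyper
            cvAUC <- c(NA_real_, NA_real_)
            if (!is.null(ms$grid)) {
                sel <- selectHyperparameters(fam, Xtr, ytr, ms$grid,
                                             k = cfg$cvFolds,
                                             seed = deriveSeed(cfg$seed,
                                                 paste0("cv", f, fam)))
                hyper <- utils::modifyList(hyper, sel$hyper)
                cvAUC <- sel$cvAUC
            }
            fit <- fitModel(fam, Xtr, ytr, hyper = hyper,
                            seed = deriveSeed(cfg$seed,
                                              paste0("fit", f, fam)))
            fit@cvAUC <- as.numeric(cvAUC)
            crit <- if (is.null(ms$criterion)) .defaultCriterion(fam)
                    else ms$criterion
            fr <- switch(crit,
                weight = weightImportance(fit, Xtr),
                gain = gainImportance(fit, Xtr),
                PFI = pfi(fit, Xte, yte,
                          seed = deriveSeed(cfg$seed,
                                            paste0("pfi", f, fam))),
                stop("unknown importance criterion: ", crit))
            nNonzero <- if (length(fit@weights))
                length(unique(fr$snp[fr$score != 0]))
            else length(unique(fr$snp[fr$score > 0]))
            fits[[fam]] <- list(
                family = fam, criterion = crit, hyper = hyper,
                cvAUC = cvAUC,
                testAUC = aucScore(predictScore(fit, Xte), yte),
                nSnpPreselected = length(keep),
                nSnpNonzero = nNonzero,
                ranking = fr,
                locusRanking = toLocusRanking(fr, part0),
                locusRankingBis = toLocusRanking(fr, partB))
        }
        perFold[[f]] <- list(fold = f, nTrain = nSamples(sp$train),
                             nTest = nSamples(sp$test),
                             preselected = pres$union, models = fits)
    }

    robustness <- NULL
    if (cfg$nRefolds >= 2) {
        rl <- lapply(stats::setNames(nm = vapply(cfg$models,
                                                 `[[`, "", "family")),
                     function(fam)
            lapply(perFold, function(pf)
                pf$models[[fam]]$locusRanking))
        okLen <- min(unlist(lapply(rl, function(fs)
            vapply(fs, nrow, 1L))))
        xg <- cfg$xGrid[cfg$xGrid <= okLen]
        if (length(xg))
            robustness <- pairwiseSummary(rl, mode = "intra", xGrid = xg)
    }
    out <- list(config = cfg, qc = qcReport, folds = perFold,
                robustness = robustness)
    class(out) <- "experimentReport"
    out
}

#' @export
print.experimentReport <- function(x, ...) {
    cat("experimentReport:", length(x$folds), "refolds\n")
    for (fam in names(x$folds[[1]]$models)) {
        aucs <- vapply(x$folds, function(f) f$models[[fam]]$testAUC, 1)
        cat(sprintf("  %-14s test AUC %.3f +/- %.3f (criterion %s)\n",
                    fam, mean(aucs), stats::sd(aucs),
                    x$folds[[1]]$models[[fam]]$criterion))
    }
    invisible(x)
}
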