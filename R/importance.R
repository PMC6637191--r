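.mkRanking <- function(feature, snp, score, criterion, family) {
    ord <- order(-score, seq_along(score))
    out <- data.frame(rank = seq_along(score), feature = feature[ord],
                      snp = snp[ord], score = score[ord],
                      criterion = criterion, family = family,
                      stringsAsFactors = FALSE)
    class(out) <- c("featureRanking", "data.frame")
    out
}

.rankingMap <- function(X, p) {
    if (is(X, "FeatureMatrix")) {
        fm <- featureMap(X)
        list(feature = fm$feature, snp = fm$snp)
    } else list(feature = if (!is.null(colnames(X))) colnames(X)
                          else sprintf("f%d", seq_len(p)),
                snp = seq_len(p))
}

#' Permutation feature importance
#'
#' Scores each feature by the average drop in test-set AUC when that
#' feature's column is randomly permuted across samples: score =
#' AUC(original) - mean over \code{nPerm} permutations of AUC(permuted).
#' Larger drops rank higher. Negative scores (permutation improved the
#' AUC, i.e. noise) are retained and rank below zero. Model-agnostic:
#' works for every family.
#'
#' @param model a \linkS4class{FittedModel}.
#' @param X test-set \linkS4class{FeatureMatrix} (or matrix).
#' @param y test-set binary labels.
#' @param nPerm permutations per feature (default 10).
#' @param seed integer seed.
#' @return A feature ranking \code{data.frame} (columns \code{rank},
#'   \code{feature}, \code{snp}, \code{score}, \code{criterion},
#'   \code{family}), ordered by score descending, ties by feature index.
#' @export
pfi <- function(model, X, y, nPerm = 10L, seed = 1L) {
    stopifnot(nPerm >= 1)
    Xv <- .fmValues(X); y <- as.integer(y)
    base <- aucScore(predictScore(model, Xv), y)
    p <- ncol(Xv)
    sc <- numeric(p)
    set.seed(deriveSeed(seed, "pfi"))
    for (j in seq_len(p)) {
        if (length(unique(Xv[, j])) == 1L) { sc[j] <- 0; next }
        drop_j <- numeric(nPerm)
        for (r in seq_len(nPerm)) {
            Xp <- Xv
            Xp[, j] <- Xv[sample.int(nrow(Xv)), j]
            drop_j[r] <- aucScore(predictScore(model, Xp), y)
        }
        sc[j] <- base - mean(drop_j)
    }
    mp <- .rankingMap(X, p)
    .mkRanking(mp$feature, mp$snp, sc, "PFI", model@family)
}

#' Weight and gain feature importance
#'
#' \code{weightImportance} ranks features by the absolute value of the
#' exported linear weights (linear and random families);
#' \code{gainImportance} by the exported tree gain — the average loss
#' reduction when the feature is used in a split (tree families).
#'
#' @param model a \linkS4class{FittedModel}.
#' @param X the \linkS4class{FeatureMatrix} the model was fitted on (used
#'   for the feature-to-SNP map; optional for plain matrices).
#' @return A feature ranking \code{data.frame}, see \code{\link{pfi}}.
#' @export
weightImportance <- function(model, X = NULL) {
    if (!length(model@weights))
        stop("family '", model@family, "' does not export weights")
    p <- length(model@weights)
    mp <- if (is.null(X)) list(feature = names(model@weights),
                               snp = seq_len(p))
          else .rankingMap(X, p)
    .mkRanking(mp$feature, mp$snp, abs(model@weights), "weight",
               model@family)
}

#' @rdname weightImportance
#' @export
gainImportance <- function(model, X = NULL) {
    if (!length(model@gains))
        stop("family '", model@family, "' does not export gains")
    p <- length(model@gains)
    mp <- if (is.null(X)) list(feature = names(model@gains),
                               snp = seq_len(p))
          else .rankingMap(X, p)
    .mkRanking(mp$feature, mp$snp, model@gains, "gain", model@family)
}

#' Partition the genome into fixed windows (loci)
#'
#' Assigns every SNP to the 500 kb window (locus) containing it:
#' window index = \code{floor((bp - 1 + shiftBp) / windowBp)} per
#' chromosome. Two SNPs in the same window belong to the same locus. The
#' "bis" partition (\code{shiftBp = 250000}) is the same grid shifted by
#' half a window, used to smooth boundary bias when comparing ranked
#' locus lists.
#'
#' @param ds a \linkS4class{GenotypeData} (or the \code{data.frame}
#'   returned by \code{snpInfo}).
#' @param windowBp window size in bp (default 500000).
#' @param shiftBp grid shift in bp, usually 0 or 250000.
#' @return A \code{data.frame} with one row per SNP: \code{snp},
#'   \code{chrom}, \code{bp}, \code{locus} (chromosome-qualified window
#'   label).
#' @export
buildPartition <- function(ds, windowBp = 5e5, shiftBp = 0) {
    info <- if (is(ds, "GenotypeData")) as.data.frame(snpInfo(ds))
            else as.data.frame(ds)
    stopifnot(all(c("snp", "chrom", "bp") %in% names(info)))
    if (any(info$bp < 1)) stop("bp positions must be >= 1")
    win <- floor((info$bp - 1 + shiftBp) / windowBp)
    data.frame(snp = info$snp, chrom = info$chrom, bp = info$bp,
               locus = sprintf("%s:%d", info$chrom, win),
               stringsAsFactors = FALSE)
}

#' Aggregate a feature ranking to a locus ranking
#'
#' Multi-column codings are first collapsed to one score per SNP (max over
#' the SNP's sub-features); each locus is then scored by the maximum score
#' of its member SNPs. Ties are broken by ascending index of the locus'
#' best SNP, so rankings are deterministic.
#'
#' @param fr a feature ranking from \code{\link{pfi}},
#'   \code{\link{weightImportance}} or \code{\link{gainImportance}}.
#' @param partition output of \code{\link{buildPartition}}. Feature
#'   rankings computed on a preselected subset may carry SNP indices into
#'   the partition's rows.
#' @return A locus ranking \code{data.frame}: \code{rank}, \code{locus},
#'   \code{score}, \code{bestSnp}.
#' @export
toLocusRanking <- function(fr, partition) {
    stopifnot(all(c("snp", "score") %in% names(fr)))
    if (any(is.na(fr$snp)) || any(fr$snp < 1) ||
        any(fr$snp > nrow(partition)))
        stop("feature ranking contains features not mapped to the partition")
    ## collapse sub-features to SNP score (max)
    snpScore <- tapply(fr$score, fr$snp, max)
    snpIdx <- as.integer(names(snpScore))
    loc <- partition$locus[snpIdx]
    ord1 <- order(loc, -as.numeric(snpScore), snpIdx)
    loc <- loc[ord1]; ss <- as.numeric(snpScore)[ord1]; si <- snpIdx[ord1]
    first <- !duplicated(loc)
    out <- data.frame(locus = loc[first], score = ss[first],
                      bestSnp = partition$snp[si[first]],
                      bestSnpIdx = si[first], stringsAsFactors = FALSE)
    ord <- order(-out$score, out$bestSnpIdx)
    out <- out[ord, c("locus", "score", "bestSnp")]
    out <- cbind(rank = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    class(out) <- c("locusRanking", "data.frame")
    out
}
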