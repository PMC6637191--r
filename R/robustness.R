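.lociOf <- function(x) {
    if (is.data.frame(x)) {
        stopifnot("locus" %in% names(x))
        as.character(x$locus)
    } else as.character(x)
}

#' Robustness of ranked locus lists
#'
#' For M ranked lists (batches) and a prefix length x, counts how often
#' each locus appears among the M top-x prefixes, takes the x loci with
#' the largest appearance counts (ties broken by locus id) and returns
#' \deqn{R = \frac{\sum_{i=1}^{x} a_i}{M x}}
#' where the \eqn{a_i} are those x largest counts. R is 1 when all lists
#' agree on their top x and 1/M when the prefixes are pairwise disjoint.
#'
#' @param lists list of M ranked locus lists (character vectors or
#'   \code{data.frame}s with a \code{locus} column, best first).
#' @param x prefix length, \code{1 <= x <= min(length)}.
#' @return R in [1/M, 1].
#' @examples
#' robustnessR(list(c("A","B","C"), c("A","B","D")), x = 3)  # 5/6
#' @export
robustnessR <- function(lists, x) {
    M <- length(lists)
    stopifnot(M >= 1, x >= 1)
    ll <- lapply(lists, .lociOf)
    if (any(vapply(ll, length, 1L) < x))
        stop("x exceeds the length of a ranked list")
    pref <- unlist(lapply(ll, function(l) l[seq_len(x)]))
    cnt <- table(pref)
    cnt <- cnt[order(-as.integer(cnt), names(cnt))]
    sum(utils::head(as.integer(cnt), x)) / (M * x)
}

#' Spearman correlation of two top-x locus lists
#'
#' Computes the Spearman rank correlation over the union of the two top-x
#' sets; a locus present in only one list receives rank x + 1 in the
#' other. This padding convention makes disjoint prefixes strongly
#' negative and identical prefixes exactly 1. With
#' \code{intersectionOnly = TRUE} the coefficient is computed on the
#' common loci instead.
#'
#' @param a,b ranked locus lists.
#' @param x prefix length (>= 2).
#' @param intersectionOnly restrict to loci in both top-x sets.
#' @return Spearman coefficient in [-1, 1] (NA if fewer than 2 common
#'   loci in intersection mode).
#' @export
spearmanTop <- function(a, b, x, intersectionOnly = FALSE) {
    stopifnot(x >= 2)
    la <- .lociOf(a); lb <- .lociOf(b)
    if (length(la) < x || length(lb) < x)
        stop("x exceeds the length of a ranked list")
    ta <- la[seq_len(x)]; tb <- lb[seq_len(x)]
    uni <- if (intersectionOnly) intersect(ta, tb) else union(ta, tb)
    if (length(uni) < 2) return(NA_real_)
    ra <- match(uni, ta); ra[is.na(ra)] <- x + 1
    rb <- match(uni, tb); rb[is.na(rb)] <- x + 1
    stats::cor(ra, rb, method = "spearman")
}

#' Common-loci curve between two ranked lists
#'
#' Entry x is the number of loci shared by the two top-x prefixes,
#' \code{|top-x(a) n top-x(b)|}. Identical lists give the diagonal
#' (1, 2, ..., xMax); the curve is non-decreasing with steps in {0, 1, 2}.
#'
#' @param a,b ranked locus lists.
#' @param xMax maximum prefix length.
#' @return Integer vector of length \code{xMax}.
#' @export
intersectionCurve <- function(a, b, xMax) {
    la <- .lociOf(a); lb <- .lociOf(b)
    stopifnot(xMax >= 1, xMax <= length(la), xMax <= length(lb))
    posB <- match(la[seq_len(xMax)], lb)
    vapply(seq_len(xMax), function(x)
        sum(!is.na(posB[seq_len(x)]) & posB[seq_len(x)] <= x), integer(1))
}

#' Combine ranked lists by order of appearance in the running intersection
#'
#' A locus enters the combined ranking at the smallest prefix length x at
#' which it belongs to every input list's top-x — equivalently at
#' \code{max} of its per-list ranks. Ties at equal entry x are broken by
#' ascending sum of per-list ranks, then by locus id. Loci absent from at
#' least one list never enter the intersection and are appended last,
#' ordered by their rank sum (missing rank = list length + 1), then id.
#'
#' @param lists list of >= 2 ranked locus lists over a shared universe.
#' @param tie tie-break among equal entry x: \code{"ranksum"} (default)
#'   or \code{"id"}.
#' @return A \code{data.frame} with columns \code{rank}, \code{locus},
#'   \code{entry} (the x at which the locus entered; NA for appended
#'   loci).
#' @export
combineRankings <- function(lists, tie = c("ranksum", "id")) {
    tie <- match.arg(tie)
    stopifnot(length(lists) >= 2)
    ll <- lapply(lists, .lociOf)
    uni <- sort(unique(unlist(ll)))
    rk <- vapply(ll, function(l) {
        r <- match(uni, l); r[is.na(r)] <- length(l) + 1L; r
    }, integer(length(uni)))
    inAll <- vapply(ll, function(l) uni %in% l, logical(length(uni)))
    present <- rowSums(!inAll) == 0
    entry <- ifelse(present, apply(rk, 1, max), NA_integer_)
    ranksum <- rowSums(rk)
    ord <- if (tie == "ranksum")
        order(!present, entry, ranksum, uni)
    else order(!present, entry, uni)
    data.frame(rank = seq_along(uni), locus = uni[ord],
               entry = entry[ord], stringsAsFactors = FALSE)
}

#' Mean robustness/Spearman curves over list pairs
#'
#' Intra-model mode pairs every two folds of the same model (C(M,2)
#' pairs, e.g. 45 for 10 folds); between-model mode pairs the two models
#' on the same fold (one pair per fold). Returns, for each model (or the
#' model pair) and each prefix length in \code{xGrid}, the mean and
#' standard error over pairs.
#'
#' @param rankLists named list: \code{rankLists[[model]][[fold]]} is a
#'   ranked locus list.
#' @param mode \code{"intra"} or \code{"between"} (between requires
#'   exactly two models with aligned folds).
#' @param xGrid prefix lengths to evaluate.
#' @param stat \code{"R"} (robustness) or \code{"spearman"}.
#' @return A \code{data.frame}: \code{model}, \code{x}, \code{mean},
#'   \code{se}, \code{nPairs}.
#' @export
pairwiseSummary <- function(rankLists, mode = c("intra", "between"),
                            xGrid = c(10L, 25L, 50L, 100L),
                            stat = c("R", "spearman")) {
    mode <- match.arg(mode); stat <- match.arg(stat)
    val <- function(a, b, x)
        if (stat == "R") robustnessR(list(a, b), x) else spearmanTop(a, b, x)
    rows <- list()
    if (mode == "intra") {
        for (mod in names(rankLists)) {
            folds <- rankLists[[mod]]
            M <- length(folds)
            if (M < 2) stop("intra mode needs >= 2 folds per model")
            prs <- utils::combn(M, 2)
            for (x in xGrid) {
                v <- apply(prs, 2, function(ij)
                    val(folds[[ij[1]]], folds[[ij[2]]], x))
                rows[[length(rows) + 1L]] <- data.frame(
                    model = mod, x = x, mean = mean(v),
                    se = stats::sd(v) / sqrt(length(v)),
                    nPairs = length(v))
            }
        }
    } else {
        if (length(rankLists) != 2)
            stop("between mode requires exactly two models")
        f1 <- rankLists[[1]]; f2 <- rankLists[[2]]
        if (length(f1) != length(f2))
            stop("between mode requires aligned folds")
        pairName <- paste(names(rankLists), collapse = " vs ")
        for (x in xGrid) {
            v <- vapply(seq_along(f1), function(f)
                val(f1[[f]], f2[[f]], x), numeric(1))
            rows[[length(rows) + 1L]] <- data.frame(
                model = pairName, x = x, mean = mean(v),
                se = stats::sd(v) / sqrt(length(v)), nPairs = length(v))
        }
    }
    do.call(rbind, rows)
}

#' Overlap percentages between two runs or against a reference locus list
#'
#' Compares a run's selected SNPs and loci (all selected, and the top-100
#' by score) with a reference run, reporting the percentage of the run's
#' sets found in the reference's corresponding sets. Against an external
#' reference locus list (e.g. GWAS meta-analysis loci) only loci are
#' compared.
#'
#' @param run list with elements \code{snps}, \code{loci},
#'   \code{topSnps}, \code{topLoci} (character vectors; top sets usually
#'   the 100 highest-scoring).
#' @param reference same structure, or a character vector of reference
#'   locus labels when \code{gwas = TRUE}.
#' @param gwas compare loci only, against an external locus list.
#' @return Named numeric vector of percentages in [0, 100].
#' @export
overlapMetrics <- function(run, reference, gwas = FALSE) {
    pct <- function(a, b) {
        if (length(a) == 0) stop("empty selection in overlap computation")
        100 * length(intersect(a, b)) / length(a)
    }
    if (gwas) {
        ref <- as.character(reference)
        if (length(ref) == 0) stop("empty reference")
        return(c(ILociGWAS = pct(run$loci, ref),
                 ItopLociGWAS = pct(run$topLoci, ref)))
    }
    c(ISnp = pct(run$snps, reference$snps),
      ILoci = pct(run$loci, reference$loci),
      ItopSnp = pct(run$topSnps, reference$topSnps),
      ItopLoci = pct(run$topLoci, reference$topLoci))
}

#' Locus labels of a reference locus list
#'
#' Maps each reference locus (chrom, bp of its best SNP) to the fixed
#' window partition label used by \code{\link{buildPartition}}, so GWAS
#' reference loci can be intersected with locus rankings.
#'
#' @param ref \code{data.frame} from \code{\link{readReferenceLoci}}.
#' @param windowBp,shiftBp partition parameters.
#' @return Character vector of locus labels.
#' @export
referenceLocusLabels <- function(ref, windowBp = 5e5, shiftBp = 0) {
    sprintf("%s:%d", ref$chrom,
            floor((ref$bp - 1 + shiftBp) / windowBp))
}
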