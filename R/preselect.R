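#' Single-SNP association tests
#'
#' Computes, for every SNP, the minor-allele frequency and four chi-squared
#' association p-values: \emph{genotypic} (Pearson test on the 2 class x 3
#' genotype table, 2 df, treating the genotype classes as independent),
#' \emph{dominant} (2 x 2 on AA versus Aa+aa, 1 df), \emph{trend}
#' (Cochran-Armitage trend test with scores 0/1/2, 1 df — the score test
#' of the additive logistic model) and \emph{allelic} (2 x 2 on the
#' 2N allele counts, 1 df). Missing genotypes are dropped per SNP.
#' Degenerate tables (a zero-variance margin, e.g. monomorphic SNPs or a
#' single phenotype class) yield p = 1. No continuity corrections are
#' applied.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @return A \code{data.frame} with columns \code{snp}, \code{maf},
#'   \code{pGenotypic}, \code{pDominant}, \code{pTrend}, \code{pAllelic}.
#' @export
associationTests <- function(ds) {
    g <- genotypes(ds)
    y <- phenotype(ds)
    case <- which(y == 1L); ctrl <- which(y == 0L)
    r <- .genoCounts(g, case)   # cases:   n0 n1 n2 per SNP
    s <- .genoCounts(g, ctrl)   # controls
    R <- rowSums(r); S <- rowSums(s)
    n <- R + S
    nk <- r + s                 # genotype column totals

    q <- (nk[, 2] + 2 * nk[, 3]) / pmax(2 * n, 1L)
    maf <- pmin(q, 1 - q)

    ## genotypic: Pearson on 2x3, df = nonzero genotype columns - 1
    stat <- numeric(nrow(g)); df <- integer(nrow(g))
    ok <- R > 0 & S > 0 & n > 0
    for (k in 1:3) {
        e_r <- R * nk[, k] / pmax(n, 1L)
        e_s <- S * nk[, k] / pmax(n, 1L)
        use <- ok & nk[, k] > 0
        stat[use] <- stat[use] + (r[use, k] - e_r[use])^2 / e_r[use] +
            (s[use, k] - e_s[use])^2 / e_s[use]
        df <- df + as.integer(nk[, k] > 0)
    }
    df <- df - 1L
    pGeno <- ifelse(ok & df >= 1L,
                    stats::pchisq(stat, df = pmax(df, 1L),
                                  lower.tail = FALSE), 1)

    chisq22 <- function(a, b, c, d) {
        N <- a + b + c + d
        den <- (a + b) * (c + d) * (a + c) * (b + d)
        ifelse(den > 0, N * (a * d - b * c)^2 / den, 0)
    }
    ## dominant: AA vs Aa+aa
    pDom <- ifelse(ok, stats::pchisq(
        chisq22(r[, 1], r[, 2] + r[, 3], s[, 1], s[, 2] + s[, 3]),
        df = 1, lower.tail = FALSE), 1)

    ## Cochran-Armitage trend, scores w = (0,1,2), score-test form
    w1 <- nk[, 2]; w2 <- nk[, 3]
    sumWn <- w1 + 2 * w2          # sum w_k n_k
    sumW2n <- w1 + 4 * w2         # sum w_k^2 n_k
    U <- (r[, 2] + 2 * r[, 3]) - R * sumWn / pmax(n, 1L)
    pbar <- R / pmax(n, 1L)
    varU <- pbar * (1 - pbar) * (sumW2n - sumWn^2 / pmax(n, 1L))
    pTrend <- ifelse(ok & varU > 0,
                     stats::pchisq(U^2 / ifelse(varU > 0, varU, 1),
                                   df = 1, lower.tail = FALSE), 1)

    ## allelic: 2x2 on allele counts (2N observations)
    caMin <- r[, 2] + 2 * r[, 3]; caMaj <- 2 * R - caMin
    coMin <- s[, 2] + 2 * s[, 3]; coMaj <- 2 * S - coMin
    pAll <- ifelse(ok, stats::pchisq(
        chisq22(caMin, caMaj, coMin, coMaj), df = 1,
        lower.tail = FALSE), 1)

    data.frame(snp = rownames(g), maf = maf, pGenotypic = pGeno,
               pDominant = pDom, pTrend = pTrend, pAllelic = pAll,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Union-based SNP preselection
#'
#' Applies the MAF screen first (strict \code{maf > mafMin}), then forms
#' one SNP list per association test (\code{p < pMax}, strict, among the
#' MAF survivors) and returns their union — the screening panel — together
#' with their intersection and the per-test lists. Lists are ordered by
#' SNP index, deterministically. Thresholds are screens for dimensionality
#' reduction, not inference, so no multiple-testing adjustment is applied.
#'
#' @param table output of \code{\link{associationTests}}.
#' @param mafMin MAF threshold (default 0.01).
#' @param pMax p-value threshold (default 1e-4).
#' @return A list of class \code{"preselection"} with elements
#'   \code{mafPass}, \code{perTest} (4 character vectors), \code{union},
#'   \code{intersection}, \code{thresholds}.
#' @export
preselectSnps <- function(table, mafMin = 0.01, pMax = 1e-4) {
    stopifnot(is.data.frame(table),
              all(c("snp", "maf", "pGenotypic", "pDominant", "pTrend",
                    "pAllelic") %in% names(table)))
    mafPass <- table$snp[table$maf > mafMin]
    tests <- c("pGenotypic", "pDominant", "pTrend", "pAllelic")
    perTest <- lapply(tests, function(tt)
        table$snp[table$maf > mafMin & table[[tt]] < pMax])
    names(perTest) <- tests
    inUnion <- table$maf > mafMin &
        (table$pGenotypic < pMax | table$pDominant < pMax |
         table$pTrend < pMax | table$pAllelic < pMax)
    inInter <- table$maf > mafMin &
        table$pGenotypic < pMax & table$pDominant < pMax &
        table$pTrend < pMax & table$pAllelic < pMax
    un <- table$snp[inUnion]
    if (length(un) == 0)
        warning("preselection union is empty")
    res <- list(mafPass = mafPass, perTest = perTest, union = un,
                intersection = table$snp[inInter],
                thresholds = c(mafMin = mafMin, pMax = pMax))
    class(res) <- "preselection"
    res
}

#' @export
print.preselection <- function(x, ...) {
    cat("SNP preselection (MAF >", x$thresholds["mafMin"], ", p <",
        x$thresholds["pMax"], ")\n")
    cat("  MAF pass:", length(x$mafPass),
        " union:", length(x$union),
        " intersection:", length(x$intersection), "\n")
    invisible(x)
}
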