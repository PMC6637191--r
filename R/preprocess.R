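#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-squared test of observed genotype counts
#' against the Hardy-Weinberg expectations \eqn{n(1-q)^2, 2nq(1-q), nq^2}
#' implied by the sample allele frequency \eqn{q}. Monomorphic SNPs
#' (allele frequency 0 or 1) return p = 1. All arguments are vectorized.
#'
#' @param n0,n1,n2 genotype counts for 0, 1 and 2 copies of the minor
#'   allele.
#' @return p-value(s) in [0, 1].
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions -> 1
#' hweTest(100, 0, 100)  # no heterozygotes -> ~2.6e-45
#' @export
hweTest <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    if (any(n <= 0)) stop("total genotype count must be positive")
    q <- (n1 + 2 * n2) / (2 * n)
    e0 <- n * (1 - q)^2; e1 <- 2 * n * q * (1 - q); e2 <- n * q^2
    stat <- ifelse(q <= 0 | q >= 1, 0,
                   (n0 - e0)^2 / pmax(e0, .Machine$double.xmin) +
                   (n1 - e1)^2 / pmax(e1, .Machine$double.xmin) +
                   (n2 - e2)^2 / pmax(e2, .Machine$double.xmin))
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

## per-SNP genotype counts (0/1/2) for a subset of samples, missing dropped
.genoCounts <- function(g, cols = seq_len(ncol(g))) {
    gs <- g[, cols, drop = FALSE]
    cbind(n0 = rowSums(gs == 0L, na.rm = TRUE),
          n1 = rowSums(gs == 1L, na.rm = TRUE),
          n2 = rowSums(gs == 2L, na.rm = TRUE))
}

#' Apply quality-control filters
#'
#' Filters in a fixed order: (1) drop samples whose missing-genotype rate
#' exceeds \code{sampleMissMax}; (2) drop SNPs whose missing rate across
#' the surviving samples exceeds \code{snpMissMax}; (3) drop SNPs whose
#' Hardy-Weinberg p-value, computed in surviving \emph{controls} only,
#' falls below \code{hwePMin}. The order matters because each step changes
#' the rates seen by the next; the report tallies every step.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param sampleMissMax,snpMissMax,hwePMin thresholds (defaults 0.05,
#'   0.02, 1e-10).
#' @return A list with elements \code{data} (filtered
#'   \linkS4class{GenotypeData}) and \code{report} (step tallies).
#' @export
applyQC <- function(ds, sampleMissMax = 0.05, snpMissMax = 0.02,
                    hwePMin = 1e-10) {
    stopifnot(sampleMissMax >= 0, sampleMissMax <= 1,
              snpMissMax >= 0, snpMissMax <= 1,
              hwePMin >= 0, hwePMin <= 1)
    g <- genotypes(ds)
    n0samp <- ncol(g); n0snp <- nrow(g)

    sampMiss <- colMeans(is.na(g))
    keepSamp <- sampMiss <= sampleMissMax
    ds <- ds[, keepSamp]
    g <- genotypes(ds)

    snpMiss <- rowMeans(is.na(g))
    keepMiss <- snpMiss <= snpMissMax
    ds <- ds[keepMiss, ]
    g <- genotypes(ds)

    ctl <- which(phenotype(ds) == 0L)
    if (length(ctl)) {
        cc <- .genoCounts(g, ctl)
        tot <- rowSums(cc)
        p <- rep(1, nrow(g))
        p[tot > 0] <- hweTest(cc[tot > 0, 1], cc[tot > 0, 2],
                              cc[tot > 0, 3])
        keepHwe <- p >= hwePMin
    } else keepHwe <- rep(TRUE, nrow(g))
    ds <- ds[keepHwe, ]

    if (nSnps(ds) == 0 || nSamples(ds) == 0)
        stop("QC removed every sample or SNP")
    report <- list(samplesRemoved = sum(!keepSamp),
                   snpsRemovedMissing = sum(!keepMiss),
                   snpsRemovedHwe = sum(!keepHwe),
                   survivors = c(samples = nSamples(ds), snps = nSnps(ds)),
                   inputs = c(samples = n0samp, snps = n0snp),
                   thresholds = c(sampleMissMax = sampleMissMax,
                                  snpMissMax = snpMissMax,
                                  hwePMin = hwePMin))
    list(data = ds, report = report)
}

#' Impute missing genotypes
#'
#' Strategies: \code{Unkw} leaves missing genotypes untouched; \code{Maj}
#' replaces each missing allele with the most common observed allele (so a
#' missing genotype becomes 0 minor alleles whenever the labeled major
#' allele is truly major, and 2 otherwise); \code{HWc} and \code{HWa} draw
#' each missing genotype as Binomial(2, q) with q the minor-allele
#' frequency estimated from observed controls (\code{HWc}) or all observed
#' samples (\code{HWa}) — a random draw consistent with Hardy-Weinberg
#' equilibrium. Random draws use one stream per (seed, SNP), so SNPs are
#' imputed independently and reproducibly.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param strategy one of \code{"Unkw"}, \code{"Maj"}, \code{"HWc"},
#'   \code{"HWa"}.
#' @param seed integer seed (used by HWc/HWa).
#' @return A \linkS4class{GenotypeData}; no \code{NA}s remain except under
#'   \code{Unkw}.
#' @export
imputeGenotypes <- function(ds, strategy = c("Unkw", "Maj", "HWc", "HWa"),
                            seed = 1L) {
    strategy <- match.arg(strategy)
    if (strategy == "Unkw") return(ds)
    g <- genotypes(ds)
    missIdx <- which(is.na(g), arr.ind = TRUE)
    if (nrow(missIdx) == 0) return(ds)
    y <- phenotype(ds)
    useCols <- if (strategy == "HWc") which(y == 0L) else seq_len(ncol(g))
    cc <- .genoCounts(g, useCols)
    tot <- rowSums(cc)
    if (strategy == "HWc" && any(tot[unique(missIdx[, 1])] == 0))
        stop("HWc imputation needs at least one observed control ",
             "genotype per SNP with missing data")
    q <- (cc[, 2] + 2 * cc[, 3]) / (2 * pmax(tot, 1L))

    if (strategy == "Maj") {
        fill <- ifelse(q > 0.5, 2L, 0L)
        g[missIdx] <- fill[missIdx[, 1]]
    } else {
        for (j in unique(missIdx[, 1])) {
            rows <- missIdx[missIdx[, 1] == j, , drop = FALSE]
            set.seed(deriveSeed(seed, paste0("impute", j)))
            g[rows] <- stats::rbinom(nrow(rows), 2L, q[j])
        }
    }
    SummarizedExperiment::assay(ds, "genotype") <- g
    ds
}

#' Encode genotypes as a numeric feature matrix
#'
#' Codings: \code{sum} — one additive column per SNP with values 0/1/2
#' (each extra minor-allele copy adds the same risk); \code{OHE} — three
#' indicator columns per SNP for the genotype classes AA/Aa/aa, dropping
#' the additivity assumption; \code{raw} — two binary columns per SNP, one
#' per (unordered) allele, genotype g mapped to \code{ceiling(g/2)} and
#' \code{floor(g/2)}, giving the same three-class expressiveness with only
#' 2 columns; \code{OHE4} — four indicator columns per SNP for the classes
#' 0-0, 0-1, 1-1 and unknown-unknown, usable on non-imputed data where
#' both alleles of a missing genotype are unknown together.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param coding one of \code{"sum"}, \code{"OHE"}, \code{"raw"},
#'   \code{"OHE4"}.
#' @return A \linkS4class{FeatureMatrix} (samples x features).
#' @examples
#' ds <- simulateGenotypes(simConfig(nCases = 10, nControls = 19,
#'                                   nSnps = 10, nCausal = 0, seed = 3))
#' ncol(featureValues(encodeGenotypes(ds, "OHE")))  # 3 * 10
#' @export
encodeGenotypes <- function(ds, coding = c("sum", "OHE", "raw", "OHE4")) {
    coding <- match.arg(coding)
    G <- t(genotypes(ds))  # samples x SNPs
    m <- ncol(G)
    ids <- colnames(G)
    if (coding != "OHE4" && anyNA(G))
        stop(coding, " coding requires fully imputed genotypes; ",
             "use OHE4 for data with missing values")
    if (coding == "sum") {
        X <- G; storage.mode(X) <- "double"
        colnames(X) <- ids
        fm <- DataFrame(feature = ids, snp = seq_len(m), label = "sum")
    } else if (coding == "OHE") {
        X <- matrix(0, nrow(G), 3L * m)
        lab <- c("AA", "Aa", "aa")
        for (k in 0:2) X[, seq(k + 1L, 3L * m, by = 3L)] <- (G == k) + 0
        colnames(X) <- paste(rep(ids, each = 3L), lab, sep = ".")
        fm <- DataFrame(feature = colnames(X),
                        snp = rep(seq_len(m), each = 3L),
                        label = rep(lab, m))
    } else if (coding == "raw") {
        X <- matrix(0, nrow(G), 2L * m)
        X[, seq(1L, 2L * m, by = 2L)] <- ceiling(G / 2)
        X[, seq(2L, 2L * m, by = 2L)] <- floor(G / 2)
        lab <- c("a1", "a2")
        colnames(X) <- paste(rep(ids, each = 2L), lab, sep = ".")
        fm <- DataFrame(feature = colnames(X),
                        snp = rep(seq_len(m), each = 2L),
                        label = rep(lab, m))
    } else {
        X <- matrix(0, nrow(G), 4L * m)
        lab <- c("AA", "Aa", "aa", "UU")
        for (k in 0:2)
            X[, seq(k + 1L, 4L * m, by = 4L)] <-
                (!is.na(G) & G == k) + 0
        X[, seq(4L, 4L * m, by = 4L)] <- is.na(G) + 0
        colnames(X) <- paste(rep(ids, each = 4L), lab, sep = ".")
        fm <- DataFrame(feature = colnames(X),
                        snp = rep(seq_len(m), each = 4L),
                        label = rep(lab, m))
    }
    new("FeatureMatrix", values = X, featureMap = fm, coding = coding)
}
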