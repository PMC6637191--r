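#' Configuration for the synthetic case-control genotype simulator
#'
#' Builds a validated list of simulation parameters. Defaults emulate a
#' desk-scale version of an Immunochip-style case-control study: a
#' case/control ratio around 0.53, biallelic SNPs with a wide minor-allele
#' frequency (MAF) spectrum, additive log-odds risk concentrated on a small
#' set of causal SNPs with per-SNP odds ratios mostly between 1.1 and 1.5,
#' linkage-disequilibrium (LD) blocks in which nearby SNPs are nearly
#' interchangeable, and marker density enriched around causal loci.
#'
#' @param nCases,nControls sample counts per class (defaults 1733/3267,
#'   i.e. ratio 0.53 at n = 5000).
#' @param nSnps total number of SNPs.
#' @param nCausal number of causal SNPs (must be <= nSnps).
#' @param mafRange MAF range for non-causal SNPs, within (0, 0.5].
#' @param causalMafRange MAF range for causal SNPs; defaults to
#'   [0.05, 0.5] because loci detectable at odds ratios of 1.1-1.5 are
#'   common variants.
#' @param causalOrRange per-SNP odds-ratio range (>= 1); the risk allele
#'   sign is randomized per SNP.
#' @param ldRho first-order allele-copying probability in [0, 1) between
#'   adjacent SNPs inside an LD block.
#' @param blockSize number of consecutive SNPs per LD block.
#' @param densityEnrichment multiplier (>= 1) for SNP density inside the
#'   500 kb windows that contain a causal SNP.
#' @param missRateControls,missRateCases per-entry missingness rates in
#'   [0, 1), applied by class.
#' @param chromLengths bp length of each simulated chromosome.
#' @param rejectCap rejection-sampling budget as a multiple of the
#'   requested sample count.
#' @param seed integer RNG seed; simulation is bit-reproducible under it.
#' @return A list of class \code{"simConfig"}.
#' @export
simConfig <- function(nCases = 1733L, nControls = 3267L, nSnps = 1000L,
                      nCausal = 20L, mafRange = c(0.001, 0.5),
                      causalMafRange = c(0.05, 0.5),
                      causalOrRange = c(1.1, 1.5), ldRho = 0.5,
                      blockSize = 10L, densityEnrichment = 3,
                      missRateControls = 0, missRateCases = 0,
                      chromLengths = rep(5e7, 4), rejectCap = 30,
                      seed = 1L) {
    stopifnot(nCases >= 1, nControls >= 1, nSnps >= 1,
              nCausal >= 0, nCausal <= nSnps,
              length(mafRange) == 2, mafRange[1] > 0, mafRange[2] <= 0.5,
              mafRange[1] <= mafRange[2],
              causalMafRange[1] > 0, causalMafRange[2] <= 0.5,
              all(causalOrRange >= 1), ldRho >= 0, ldRho < 1,
              blockSize >= 1, densityEnrichment >= 1,
              missRateControls >= 0, missRateControls < 1,
              missRateCases >= 0, missRateCases < 1,
              all(chromLengths > 0), rejectCap > 1)
    cfg <- as.list(environment())
    class(cfg) <- "simConfig"
    cfg
}

#' Simulate a case-control genotype dataset
#'
#' Generates genotypes SNP by SNP from Hardy-Weinberg equilibrium at a MAF
#' drawn uniformly from the configured range. Adjacent SNPs within an LD
#' block are coupled by a first-order copying process: each of a sample's
#' two alleles is, with probability \code{ldRho}, copied from the previous
#' SNP on the same haplotype, and otherwise drawn fresh. Case/control
#' labels follow the additive liability model
#' \eqn{P(case | g) = logistic(\beta_0 + \sum_j \beta_j g_j)} with
#' \eqn{\beta_j = \pm\log OR_j} on the causal SNPs; \eqn{\beta_0} is
#' calibrated by bisection so the expected prevalence matches the requested
#' case fraction, and samples are then drawn by rejection until both class
#' quotas are filled. SNP positions are sorted uniform draws per
#' chromosome, with \code{densityEnrichment}-fold density inside the 500 kb
#' windows containing causal SNPs (mimicking arrays enriched near known
#' risk loci). Differential class-wise missingness is applied last.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A \linkS4class{GenotypeData} with truth effects in
#'   \code{rowData()$beta} and the intercept in \code{metadata()$intercept}.
#' @examples
#' ds <- simulateGenotypes(simConfig(nCases = 50, nControls = 94,
#'                                   nSnps = 40, nCausal = 4, seed = 7))
#' ds
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    nC <- length(config$chromLengths)
    winBp <- 5e5

    ## --- SNP placement -----------------------------------------------
    totLen <- sum(config$chromLengths)
    causalChrom <- sample.int(nC, config$nCausal, replace = TRUE,
                              prob = config$chromLengths / totLen)
    causalPos <- floor(stats::runif(config$nCausal) *
                       config$chromLengths[causalChrom]) + 1
    causalWin <- floor((causalPos - 1) / winBp)
    uw <- unique(data.frame(chrom = causalChrom, win = causalWin))
    nOther <- config$nSnps - config$nCausal
    if (nrow(uw) > 0 && config$densityEnrichment > 1 && nOther > 0) {
        f <- min(0.9, nrow(uw) * winBp / totLen)
        E <- config$densityEnrichment
        pEnrich <- E * f / (1 - f + E * f)
    } else pEnrich <- 0
    inWin <- stats::runif(nOther) < pEnrich
    nIn <- sum(inWin)
    otherChrom <- integer(nOther); otherPos <- numeric(nOther)
    if (nIn > 0) {
        pick <- sample.int(nrow(uw), nIn, replace = TRUE)
        otherChrom[inWin] <- uw$chrom[pick]
        otherPos[inWin] <- uw$win[pick] * winBp +
            floor(stats::runif(nIn) * winBp) + 1
    }
    nOut <- nOther - nIn
    if (nOut > 0) {
        oc <- sample.int(nC, nOut, replace = TRUE,
                         prob = config$chromLengths / totLen)
        otherChrom[!inWin] <- oc
        otherPos[!inWin] <- floor(stats::runif(nOut) *
                                  config$chromLengths[oc]) + 1
    }
    chrom <- c(causalChrom, otherChrom)
    pos <- c(causalPos, otherPos)
    isCausal <- c(rep(TRUE, config$nCausal), rep(FALSE, nOther))
    ord <- order(chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]; isCausal <- isCausal[ord]

    ## --- per-SNP MAF and effects -------------------------------------
    maf <- stats::runif(config$nSnps, config$mafRange[1], config$mafRange[2])
    maf[isCausal] <- stats::runif(sum(isCausal), config$causalMafRange[1],
                                  config$causalMafRange[2])
    beta <- numeric(config$nSnps)
    if (config$nCausal > 0) {
        orv <- stats::runif(sum(isCausal), config$causalOrRange[1],
                            config$causalOrRange[2])
        beta[isCausal] <- log(orv) * sample(c(-1, 1), sum(isCausal),
                                            replace = TRUE)
    }

    ## LD blocks: consecutive SNPs within a chromosome, blockSize each
    blockId <- unlist(lapply(split(seq_along(chrom), chrom), function(ix) {
        (seq_along(ix) - 1) %/% config$blockSize
    }), use.names = FALSE)
    blockKey <- paste(chrom, blockId)
    newBlock <- c(TRUE, blockKey[-1] != blockKey[-length(blockKey)])

    genRows <- function(n) {
        h1 <- matrix(0L, n, config$nSnps)
        h2 <- matrix(0L, n, config$nSnps)
        for (j in seq_len(config$nSnps)) {
            f1 <- stats::rbinom(n, 1L, maf[j])
            f2 <- stats::rbinom(n, 1L, maf[j])
            if (newBlock[j] || config$ldRho == 0) {
                h1[, j] <- f1; h2[, j] <- f2
            } else {
                cp1 <- stats::runif(n) < config$ldRho
                cp2 <- stats::runif(n) < config$ldRho
                h1[, j] <- ifelse(cp1, h1[, j - 1L], f1)
                h2[, j] <- ifelse(cp2, h2[, j - 1L], f2)
            }
        }
        h1 + h2
    }

    ## --- intercept calibration by bisection --------------------------
    nTot <- config$nCases + config$nControls
    target <- config$nCases / nTot
    cidx <- which(isCausal)
    if (length(cidx)) {
        ncal <- min(4000L, max(2000L, nTot))
        Gcal <- genRows(ncal)[, cidx, drop = FALSE]
        eta <- drop(Gcal %*% beta[cidx])
        lo <- -30; hi <- 30
        for (it in 1:60) {
            mid <- (lo + hi) / 2
            if (mean(sigmoid(mid + eta)) < target) lo <- mid else hi <- mid
        }
        b0 <- (lo + hi) / 2
        prev <- mean(sigmoid(b0 + eta))
        if (prev < target / 5 || prev > 1 - (1 - target) / 5)
            stop("intercept calibration infeasible for requested case count")
    } else b0 <- stats::qlogis(target)

    ## --- rejection sampling of the two class quotas -------------------
    cases <- NULL; controls <- NULL; drawn <- 0L
    maxDraw <- ceiling(config$rejectCap * nTot)
    while ((is.null(cases) || nrow(cases) < config$nCases) ||
           (is.null(controls) || nrow(controls) < config$nControls)) {
        if (drawn >= maxDraw)
            stop("rejection sampling budget exhausted: requested case ",
                 "count unreachable under the calibrated model")
        b <- min(maxDraw - drawn, max(512L, ceiling(0.6 * nTot)))
        G <- genRows(b); drawn <- drawn + b
        p <- if (length(cidx))
            sigmoid(b0 + drop(G[, cidx, drop = FALSE] %*% beta[cidx]))
        else rep(target, b)
        lab <- stats::rbinom(b, 1L, p)
        cases <- rbind(cases, G[lab == 1L, , drop = FALSE])
        controls <- rbind(controls, G[lab == 0L, , drop = FALSE])
    }
    G <- rbind(cases[seq_len(config$nCases), , drop = FALSE],
               controls[seq_len(config$nControls), , drop = FALSE])
    y <- c(rep(1L, config$nCases), rep(0L, config$nControls))
    perm <- sample.int(nTot)
    G <- G[perm, , drop = FALSE]; y <- y[perm]

    g <- t(G)
    rownames(g) <- sprintf("snp%d", seq_len(config$nSnps))
    colnames(g) <- sprintf("s%d", seq_len(nTot))
    ds <- makeGenotypeData(g, phenotype = y,
                           chrom = as.character(chrom), bp = pos,
                           minor = rep("A", config$nSnps),
                           major = rep("G", config$nSnps),
                           beta = beta, intercept = b0)
    rowData(ds)$mafNominal <- maf
    if (config$missRateControls > 0 || config$missRateCases > 0)
        ds <- injectMissingness(ds, config$missRateControls,
                                config$missRateCases,
                                seed = deriveSeed(config$seed, "miss"))
    ds
}

#' Inject class-differential missingness
#'
#' Sets each (sample, SNP) genotype to missing independently, with a rate
#' that depends on the sample's class. Differential rates mimic residual
#' stratification between case and control genotyping batches; they make
#' the missingness indicator itself phenotype-informative, which is the
#' artifact the unknown-genotype coding can exploit.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param missRateControls,missRateCases per-entry rates in [0, 1).
#' @param seed integer seed.
#' @return The dataset with additional missing entries.
#' @export
injectMissingness <- function(ds, missRateControls, missRateCases, seed) {
    stopifnot(missRateControls >= 0, missRateControls < 1,
              missRateCases >= 0, missRateCases < 1)
    if (missRateControls == 0 && missRateCases == 0) return(ds)
    set.seed(seed)
    g <- genotypes(ds)
    y <- phenotype(ds)
    rate <- ifelse(y == 1L, missRateCases, missRateControls)
    ## column-major draw, one rate per sample column
    miss <- matrix(stats::runif(length(g)), nrow(g), ncol(g)) <
        matrix(rate, nrow(g), ncol(g), byrow = TRUE)
    g[miss] <- NA_integer_
    SummarizedExperiment::assay(ds, "genotype") <- g
    ds
}
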