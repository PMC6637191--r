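#' @rdname GenotypeData-accessors
#' @name GenotypeData-accessors
#' @title Accessors for GenotypeData and FeatureMatrix
#'
#' @description \code{genotypes()} returns the SNP x sample integer matrix
#' (NA = missing); \code{phenotype()} the 0/1 sample vector;
#' \code{snpInfo()} a \code{DataFrame} of per-SNP chromosome, position and
#' alleles; \code{nSnps()}/\code{nSamples()} the dimensions;
#' \code{featureValues()}, \code{featureMap()} and \code{coding()} the
#' pieces of a \linkS4class{FeatureMatrix}.
#'
#' @param x a \linkS4class{GenotypeData} or \linkS4class{FeatureMatrix}.
#' @return See description.
#' @examples
#' ds <- simulateGenotypes(simConfig(nCases = 20, nControls = 30,
#'                                   nSnps = 10, nCausal = 2, seed = 1))
#' dim(genotypes(ds)); table(phenotype(ds))
NULL

#' @rdname GenotypeData-accessors
#' @export
genotypes <- function(x) SummarizedExperiment::assay(x, "genotype")

#' @rdname GenotypeData-accessors
#' @export
phenotype <- function(x) colData(x)$phenotype

#' @rdname GenotypeData-accessors
#' @export
snpInfo <- function(x) {
    rr <- rowRanges(x)
    DataFrame(snp = names(rr),
              chrom = as.character(GenomicRanges::seqnames(rr)),
              bp = GenomicRanges::start(rr),
              S4Vectors::mcols(rr))
}

#' @rdname GenotypeData-accessors
#' @export
nSnps <- function(x) nrow(x)

#' @rdname GenotypeData-accessors
#' @export
nSamples <- function(x) ncol(x)

#' @rdname GenotypeData-accessors
#' @export
featureValues <- function(x) x@values

#' @rdname GenotypeData-accessors
#' @export
featureMap <- function(x) x@featureMap

#' @rdname GenotypeData-accessors
#' @export
coding <- function(x) x@coding

#' @rdname GenotypeData-accessors
#' @export
modelWeights <- function(x) x@weights

#' @rdname GenotypeData-accessors
#' @export
modelGains <- function(x) x@gains

#' @rdname GenotypeData-accessors
#' @export
modelFamily <- function(x) x@family

# Derive a child RNG seed from a base seed and a stage tag; keeps every
# random stage on its own reproducible stream and below 2^31.
deriveSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

sigmoid <- function(z) stats::plogis(z)
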