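#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   rowData<- colData colData<- rowRanges
NULL

#' Container for case-control SNP genotype data
#'
#' \code{GenotypeData} extends
#' \linkS4class{RangedSummarizedExperiment}. Rows are biallelic SNPs
#' (a \code{GRanges} of width-1 positions, with minor/major allele labels in
#' \code{rowData}), columns are samples, and the single \code{"genotype"}
#' assay holds minor-allele counts 0/1/2 with \code{NA} for a missing
#' genotype (both alleles of a missing genotype are unknown together, as on
#' unphased arrays). The binary phenotype lives in
#' \code{colData(x)$phenotype} (0 = control, 1 = case). Simulated datasets
#' may carry per-SNP true log-odds effects in \code{rowData(x)$beta} and the
#' true intercept in \code{metadata(x)$intercept}.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}.
#' @seealso \code{\link{makeGenotypeData}}, \code{\link{simulateGenotypes}}
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

.validGenotypeData <- function(object) {
    msg <- NULL
    if (!"genotype" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'genotype' is required")
    else {
        g <- SummarizedExperiment::assay(object, "genotype")
        bad <- g[!is.na(g)]
        if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
            msg <- c(msg, "genotypes must be in {0,1,2} or NA")
    }
    ph <- colData(object)$phenotype
    if (is.null(ph))
        msg <- c(msg, "colData column 'phenotype' is required")
    else if (!all(ph %in% c(0L, 1L, NA_integer_)))
        msg <- c(msg, "phenotype must be 0 (control), 1 (case) or NA")
    rr <- rowRanges(object)
    if (length(rr)) {
        bych <- split(GenomicRanges::start(rr),
                      as.character(GenomicRanges::seqnames(rr)))
        if (!all(vapply(bych, function(p) !is.unsorted(p), logical(1))))
            msg <- c(msg, "bp positions must be non-decreasing within a chromosome")
        if (any(GenomicRanges::start(rr) < 1L))
            msg <- c(msg, "bp positions must be >= 1")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeData", .validGenotypeData)

#' Construct a GenotypeData object
#'
#' @param genotypes integer matrix, SNPs in rows and samples in columns,
#'   values 0/1/2 minor-allele counts with \code{NA} for missing.
#' @param phenotype integer vector (0 = control, 1 = case, NA = unknown),
#'   one per sample.
#' @param chrom,bp chromosome label and 1-based position per SNP.
#' @param minor,major allele labels per SNP.
#' @param beta optional per-SNP true log-odds effect (simulations).
#' @param intercept optional true intercept stored in \code{metadata()}.
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 2)
#' ds <- makeGenotypeData(g, phenotype = c(1L, 0L, 1L),
#'                        chrom = c("1", "1"), bp = c(100L, 2000L))
#' nSnps(ds); nSamples(ds)
#' @export
makeGenotypeData <- function(genotypes, phenotype, chrom, bp,
                             minor = rep("A", nrow(genotypes)),
                             major = rep("G", nrow(genotypes)),
                             beta = NULL, intercept = NULL) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    if (is.null(rownames(genotypes)))
        rownames(genotypes) <- sprintf("snp%d", seq_len(nrow(genotypes)))
    if (is.null(colnames(genotypes)))
        colnames(genotypes) <- sprintf("s%d", seq_len(ncol(genotypes)))
    rr <- GRanges(seqnames = as.character(chrom),
                  ranges = IRanges(start = as.integer(bp), width = 1L))
    names(rr) <- rownames(genotypes)
    rd <- DataFrame(minor = minor, major = major)
    if (!is.null(beta)) rd$beta <- as.numeric(beta)
    S4Vectors::mcols(rr) <- rd
    cd <- DataFrame(phenotype = as.integer(phenotype),
                    row.names = colnames(genotypes))
    se <- SummarizedExperiment(assays = list(genotype = genotypes),
                               rowRanges = rr, colData = cd)
    obj <- new("GenotypeData", se)
    if (!is.null(intercept)) metadata(obj)$intercept <- intercept
    obj
}

#' Encoded feature matrix derived from genotypes
#'
#' Samples are rows, features columns. \code{featureMap} records, for every
#' feature column, the SNP it came from and a sub-feature label (for
#' multi-column codings). \code{coding} is one of \code{"sum"},
#' \code{"OHE"}, \code{"raw"}, \code{"OHE4"}.
#'
#' @slot values numeric matrix, samples x features.
#' @slot featureMap \code{DataFrame} with columns \code{feature},
#'   \code{snp} (row index into the source \code{GenotypeData}) and
#'   \code{label}.
#' @slot coding character scalar coding tag.
#' @export
setClass("FeatureMatrix",
    representation(values = "matrix", featureMap = "DataFrame",
                   coding = "character"),
    validity = function(object) {
        msg <- NULL
        if (ncol(object@values) != nrow(object@featureMap))
            msg <- c(msg, "featureMap must have one row per feature column")
        if (!object@coding %in% c("sum", "OHE", "raw", "OHE4"))
            msg <- c(msg, "coding must be one of sum/OHE/raw/OHE4")
        if (is.null(msg)) TRUE else msg
    })

#' Fitted classifier adapter
#'
#' Uniform wrapper around the classifier families compared here. Every
#' fitted model can score new samples on the probability scale; linear
#' families and the random-weight null additionally export per-feature
#' weights, tree ensembles export per-feature gains.
#'
#' @slot family one of \code{lr_l1}, \code{lr_l2}, \code{lr_elasticnet},
#'   \code{gbt}, \code{nn_dense}, \code{nn_residual}, \code{random}.
#' @slot coding coding tag of the training features.
#' @slot weights numeric per-feature weights (or length 0).
#' @slot bias numeric intercept (linear/random families).
#' @slot gains numeric per-feature gains (tree families; or length 0).
#' @slot fit underlying fitted object (glmnet, xgboost booster, mlp list).
#' @slot hyper named list of hyper-parameters used.
#' @slot seed integer seed recorded at fit time.
#' @slot cvAUC numeric(2) mean and sd of cross-validated AUC (NA if not run).
#' @export
setClass("FittedModel",
    representation(family = "character", coding = "character",
                   weights = "numeric", bias = "numeric", gains = "numeric",
                   fit = "ANY", hyper = "list", seed = "integer",
                   cvAUC = "numeric"))

setMethod("show", "GenotypeData", function(object) {
    ph <- colData(object)$phenotype
    cat("GenotypeData:", nrow(object), "SNPs x", ncol(object), "samples\n")
    cat("  cases:", sum(ph == 1L, na.rm = TRUE),
        " controls:", sum(ph == 0L, na.rm = TRUE),
        " unphenotyped:", sum(is.na(ph)), "\n")
    g <- SummarizedExperiment::assay(object, "genotype")
    cat(sprintf("  missing genotypes: %.3f%%\n", 100 * mean(is.na(g))))
    if (!is.null(rowData(object)$beta))
        cat("  truth: ", sum(rowData(object)$beta != 0), "causal SNPs\n")
    invisible(NULL)
})

setMethod("show", "FeatureMatrix", function(object) {
    cat("FeatureMatrix:", nrow(object@values), "samples x",
        ncol(object@values), "features, coding =", object@coding, "\n")
    invisible(NULL)
})

setMethod("show", "FittedModel", function(object) {
    cat("FittedModel:", object@family, "on", object@coding, "coding\n")
    if (length(object@weights))
        cat("  nonzero weights:", sum(object@weights != 0), "of",
            length(object@weights), "\n")
    if (!is.na(object@cvAUC[1]))
        cat(sprintf("  cv AUC: %.3f +/- %.3f\n", object@cvAUC[1],
                    object@cvAUC[2]))
    invisible(NULL)
})
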