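#' Read a PLINK 1 bed/bim/fam fileset
#'
#' Reads a SNP-major PLINK 1.9 binary fileset into a
#' \linkS4class{GenotypeData}. Genotypes are counts of the .bim A1 allele
#' (conventionally the minor allele); the PLINK two-bit missing code maps
#' to \code{NA}. Phenotype comes from .fam column 6 (1 = control,
#' 2 = case); samples with any other phenotype code (e.g. -9) are dropped
#' with a message.
#'
#' @param prefix path prefix of the \code{.bed}/\code{.bim}/\code{.fam}
#'   triple.
#' @return A \linkS4class{GenotypeData}.
#' @export
readPlink <- function(prefix) {
    paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
    for (p in paths)
        if (!file.exists(p)) stop("missing PLINK file: ", p)
    bim <- utils::read.table(paths[2], header = FALSE,
                             colClasses = c("character", "character",
                                            "numeric", "integer",
                                            "character", "character"))
    names(bim) <- c("chrom", "id", "cm", "bp", "a1", "a2")
    fam <- utils::read.table(paths[3], header = FALSE,
                             colClasses = "character")
    names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
    nS <- nrow(bim); nI <- nrow(fam)

    raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
    if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
        stop("not a PLINK .bed file (bad magic bytes): ", paths[1])
    if (raw[3] != as.raw(0x01))
        stop("only SNP-major .bed files are supported: ", paths[1])
    bpl <- ceiling(nI / 4)
    if (length(raw) - 3L != nS * bpl)
        stop("PLINK .bed size does not match .bim/.fam dimensions: ",
             paths[1])
    body <- as.integer(raw[-(1:3)])
    ## expand each byte into its four 2-bit codes (little-endian pairs)
    codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                   (body %/% 16L) %% 4L, body %/% 64L)
    ## codes per SNP laid out contiguously
    lut <- c(2L, NA_integer_, 1L, 0L)  # 00,01,10,11 -> minor-allele count
    g <- matrix(lut[codes + 1L], nrow = 4L * bpl)[seq_len(nI), ,
                                                  drop = FALSE]
    g <- t(g)  # SNP x sample
    rownames(g) <- bim$id
    colnames(g) <- fam$iid

    ph <- ifelse(fam$pheno == "2", 1L, ifelse(fam$pheno == "1", 0L,
                                              NA_integer_))
    keep <- !is.na(ph)
    if (any(!keep))
        message(sum(!keep), " unphenotyped sample(s) excluded")
    makeGenotypeData(g[, keep, drop = FALSE], phenotype = ph[keep],
                     chrom = bim$chrom, bp = bim$bp,
                     minor = bim$a1, major = bim$a2)
}

#' Write a PLINK 1 bed/bim/fam fileset
#'
#' Writes a SNP-major \code{.bed} with the standard magic bytes, a
#' \code{.bim} with (chrom, id, 0, bp, minor, major) and a \code{.fam}
#' with phenotype codes 1 (control) / 2 (case). Round-trips losslessly
#' with \code{\link{readPlink}}.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(ds, prefix) {
    g <- genotypes(ds)
    info <- snpInfo(ds)
    nI <- ncol(g); nS <- nrow(g)
    bim <- data.frame(info$chrom, info$snp, 0L, info$bp, info$minor,
                      info$major)
    utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    ph <- phenotype(ds)
    fam <- data.frame(colnames(g), colnames(g), 0L, 0L, 0L,
                      ifelse(is.na(ph), -9L, ph + 1L))
    utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)

    code <- matrix(3L, nrow = nI, ncol = nS)  # 11 = zero minor alleles
    gv <- t(g)                                # sample x SNP
    code[!is.na(gv) & gv == 2L] <- 0L
    code[!is.na(gv) & gv == 1L] <- 2L
    code[is.na(gv)] <- 1L
    bpl <- ceiling(nI / 4)
    if (nI %% 4 != 0)  # pad tail samples with 00 (reads back ignored)
        code <- rbind(code, matrix(0L, 4L * bpl - nI, nS))
    i4 <- seq(1L, 4L * bpl, by = 4L)
    bytes <- code[i4, , drop = FALSE] + 4L * code[i4 + 1L, , drop = FALSE] +
        16L * code[i4 + 2L, , drop = FALSE] + 64L * code[i4 + 3L,
                                                         , drop = FALSE]
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(bytes), con)
    invisible(prefix)
}

#' Read a reference locus list with odds ratios
#'
#' Reads a tab-separated file with header columns \code{chrom}, \code{bp}
#' (position of the locus' best SNP) and \code{or} (odds ratio), as
#' published by GWAS meta-analyses. Each locus is scored by the absolute
#' value of the natural log odds ratio, so risk and protective loci rank
#' by effect magnitude alike.
#'
#' @param path TSV path.
#' @return A \code{data.frame} with columns \code{chrom}, \code{bp},
#'   \code{or}, \code{score}, one row per locus.
#' @export
readReferenceLoci <- function(path) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    need <- c("chrom", "bp", "or")
    if (!all(need %in% names(d)))
        stop("reference locus file must have columns chrom, bp, or")
    if (any(d$or <= 0))
        stop("odds ratios must be positive")
    d <- d[, need]
    d$chrom <- as.character(d$chrom)
    d$score <- abs(log(d$or))
    d
}

#' Write/read the internal plain-text genotype container
#'
#' A portable TSV trio (\code{<prefix>.geno.tsv} SNP x sample matrix with
#' \code{NA} for missing, \code{<prefix>.snps.tsv} SNP metadata including
#' any truth effects, \code{<prefix>.samples.tsv} phenotypes) used where a
#' human-inspectable text serialization is preferable to the PLINK binary.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param prefix path prefix.
#' @return \code{writeGenotypeTsv}: \code{prefix}, invisibly;
#'   \code{readGenotypeTsv}: a \linkS4class{GenotypeData}.
#' @export
writeGenotypeTsv <- function(ds, prefix) {
    utils::write.table(genotypes(ds), paste0(prefix, ".geno.tsv"),
                       sep = "\t", quote = FALSE)
    info <- as.data.frame(snpInfo(ds))
    utils::write.table(info, paste0(prefix, ".snps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    samp <- data.frame(sample = colnames(genotypes(ds)),
                       phenotype = phenotype(ds))
    utils::write.table(samp, paste0(prefix, ".samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(prefix)
}

#' @rdname writeGenotypeTsv
#' @export
readGenotypeTsv <- function(prefix) {
    g <- as.matrix(utils::read.table(paste0(prefix, ".geno.tsv"),
                                     header = TRUE, sep = "\t",
                                     check.names = FALSE))
    storage.mode(g) <- "integer"
    info <- utils::read.table(paste0(prefix, ".snps.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    samp <- utils::read.table(paste0(prefix, ".samples.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    makeGenotypeData(g, phenotype = samp$phenotype,
                     chrom = as.character(info$chrom), bp = info$bp,
                     minor = info$minor, major = info$major,
                     beta = if ("beta" %in% names(info)) info$beta)
}
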