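test_that("HWE chi-squared test matches hand-computed statistics", {
    expect_equal(hweTest(25, 50, 25), 1)           # exact HWE proportions
    expect_equal(hweTest(100, 0, 0), 1)            # monomorphic
    expect_equal(hweTest(0, 0, 50), 1)
    ## (100, 0, 100): q = 0.5, E = (50, 100, 50), X2 = 50+100+50 = 200
    expect_equal(hweTest(100, 0, 100),
                 pchisq(200, df = 1, lower.tail = FALSE))
    expect_equal(hweTest(100, 0, 100), 2.6e-45, tolerance = 0.05)
    ## vectorized and against chisq.test-style manual computation
    set.seed(1)
    for (i in 1:20) {
        n <- sample(50:500, 3)
        q <- (n[2] + 2 * n[3]) / (2 * sum(n))
        e <- sum(n) * c((1 - q)^2, 2 * q * (1 - q), q^2)
        stat <- sum((n - e)^2 / e)
        expect_equal(hweTest(n[1], n[2], n[3]),
                     pchisq(stat, 1, lower.tail = FALSE))
    }
    expect_error(hweTest(0, 0, 0))
})

test_that("QC filters in order and reports every step", {
    ds <- smallSim(nCases = 100, nControls = 189, nSnps = 30,
                   nCausal = 0, seed = 13)
    ## clean data: identity
    res <- applyQC(ds)
    expect_equal(nSnps(res$data), 30)
    expect_equal(res$report$samplesRemoved, 0)
    expect_equal(res$report$snpsRemovedMissing, 0)
    expect_equal(res$report$snpsRemovedHwe, 0)

    ## a sample with 6% missing genotypes is removed at step 1
    g <- genotypes(ds)
    nMiss <- ceiling(0.06 * nrow(g))
    g[seq_len(nMiss), 1] <- NA
    SummarizedExperiment::assay(ds, "genotype") <- g
    res2 <- applyQC(ds)
    expect_equal(res2$report$samplesRemoved, 1)

    ## a SNP violating HWE in controls is removed at step 3
    ds3 <- smallSim(nCases = 100, nControls = 200, nSnps = 10,
                    nCausal = 0, seed = 14)
    g3 <- genotypes(ds3)
    ctl <- which(phenotype(ds3) == 0L)
    g3[5, ctl] <- rep(c(0L, 2L), length.out = length(ctl))  # no hets
    SummarizedExperiment::assay(ds3, "genotype") <- g3
    res3 <- applyQC(ds3)
    expect_equal(res3$report$snpsRemovedHwe, 1)
    expect_false("snp5" %in% rownames(genotypes(res3$data)))

    ## idempotence
    resA <- applyQC(res3$data)
    expect_identical(genotypes(resA$data), genotypes(res3$data))
    expect_equal(resA$report$samplesRemoved +
                 resA$report$snpsRemovedMissing +
                 resA$report$snpsRemovedHwe, 0)
})

test_that("imputation strategies follow their definitions", {
    ds <- smallSim(nCases = 80, nControls = 151, nSnps = 20, nCausal = 0,
                   seed = 15)
    ## identity without missing data, for every strategy
    for (s in c("Unkw", "Maj", "HWc", "HWa"))
        expect_identical(genotypes(imputeGenotypes(ds, s, seed = 1)),
                         genotypes(ds))

    dm <- injectMissingness(ds, 0.1, 0.1, seed = 2)
    expect_true(anyNA(genotypes(imputeGenotypes(dm, "Unkw"))))
    gMaj <- genotypes(imputeGenotypes(dm, "Maj"))
    expect_false(anyNA(gMaj))
    ## Maj: at SNPs where the minor allele is truly minor, fills are 0
    g <- genotypes(dm)
    q <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
    j <- which(q < 0.5)[1]
    miss <- which(is.na(g[j, ]))
    expect_true(all(gMaj[j, miss] == 0L))

    ## HWc with control MAF 0 imputes all zeros at that SNP
    ds0 <- smallSim(nCases = 30, nControls = 57, nSnps = 5, nCausal = 0,
                    seed = 16)
    g0 <- genotypes(ds0)
    g0[2, phenotype(ds0) == 0L] <- 0L
    g0[2, which(phenotype(ds0) == 1L)[1:5]] <- NA
    SummarizedExperiment::assay(ds0, "genotype") <- g0
    gi <- genotypes(imputeGenotypes(ds0, "HWc", seed = 3))
    expect_true(all(gi[2, which(phenotype(ds0) == 1L)[1:5]] == 0L))

    ## determinism under a fixed seed
    expect_identical(genotypes(imputeGenotypes(dm, "HWa", seed = 9)),
                     genotypes(imputeGenotypes(dm, "HWa", seed = 9)))
})

test_that("HWa imputation preserves the minor-allele frequency", {
    ds <- smallSim(nCases = 400, nControls = 755, nSnps = 40,
                   nCausal = 0, seed = 17)
    dm <- injectMissingness(ds, 0.3, 0.3, seed = 4)
    g <- genotypes(dm)
    qObs <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
    gi <- genotypes(imputeGenotypes(dm, "HWa", seed = 5))
    qPost <- rowSums(gi) / (2 * ncol(gi))
    nMiss <- rowSums(is.na(g))
    ## imputed allele count ~ Binomial(2*nMiss, qObs), so qPost deviates
    ## from qObs by at most 3 of its binomial SEs
    se <- sqrt(2 * nMiss * qObs * (1 - qObs)) / (2 * ncol(gi))
    expect_true(all(abs(qPost - qObs) <= 3 * se + 1e-12))
})

test_that("codings produce the documented feature geometry", {
    ds <- smallSim(nCases = 20, nControls = 38, nSnps = 10, nCausal = 0,
                   seed = 18)
    expect_equal(ncol(featureValues(encodeGenotypes(ds, "sum"))), 10)
    expect_equal(ncol(featureValues(encodeGenotypes(ds, "OHE"))), 30)
    expect_equal(ncol(featureValues(encodeGenotypes(ds, "raw"))), 20)
    dm <- injectMissingness(ds, 0.1, 0.1, seed = 6)
    expect_equal(ncol(featureValues(encodeGenotypes(dm, "OHE4"))), 40)

    ## sum equals the (0,1,2)-weighted collapse of OHE, exactly
    Xs <- featureValues(encodeGenotypes(ds, "sum"))
    Xo <- featureValues(encodeGenotypes(ds, "OHE"))
    w <- rep(c(0, 1, 2), 10)
    collapsed <- sapply(1:10, function(j)
        Xo[, (3 * j - 2):(3 * j)] %*% c(0, 1, 2))
    expect_equal(unname(Xs), unname(collapsed))

    ## raw maps genotype g to (ceil(g/2), floor(g/2))
    Xr <- featureValues(encodeGenotypes(ds, "raw"))
    g1 <- t(genotypes(ds))
    expect_equal(unname(Xr[, seq(1, 19, 2)]), unname(ceiling(g1 / 2)))
    expect_equal(unname(Xr[, seq(2, 20, 2)]), unname(floor(g1 / 2)))

    ## OHE4 marks a missing genotype as the fourth class
    X4 <- featureValues(encodeGenotypes(dm, "OHE4"))
    miss <- which(is.na(t(genotypes(dm))), arr.ind = TRUE)
    j <- miss[1, 2]; i <- miss[1, 1]
    expect_equal(unname(X4[i, (4 * j - 3):(4 * j)]), c(0, 0, 0, 1))

    ## non-categorical codings refuse missing data
    expect_error(encodeGenotypes(dm, "sum"), "OHE4")
    expect_error(encodeGenotypes(dm, "raw"), "imputed")
})
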