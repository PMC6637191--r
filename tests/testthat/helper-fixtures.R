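# Small in-code fixtures shared across test files.

# 4-sample, 3-SNP dataset with one missing genotype, built by hand.
tinyDataset <- function() {
    g <- matrix(c(0L, 1L, 2L, 1L,
                  2L, 0L, 1L, 0L,
                  NA, 1L, 0L, 2L), nrow = 3, byrow = TRUE)
    makeGenotypeData(g, phenotype = c(1L, 0L, 1L, 0L),
                     chrom = c("1", "1", "2"),
                     bp = c(100L, 600000L, 250L))
}

# quick simulated dataset with defaults scaled down
smallSim <- function(nCases = 150L, nControls = 283L, nSnps = 60L,
                     nCausal = 5L, seed = 1L, ...) {
    simulateGenotypes(simConfig(nCases = nCases, nControls = nControls,
                                nSnps = nSnps, nCausal = nCausal,
                                seed = seed, ...))
}

# independent counting oracle for the robustness statistic: literal
# tallying with explicit loops, no shared code with robustnessR()
robustnessOracle <- function(lists, x) {
    M <- length(lists)
    counts <- list()
    for (l in lists) {
        ll <- if (is.data.frame(l)) l$locus else l
        for (locus in ll[seq_len(x)]) {
            key <- as.character(locus)
            counts[[key]] <- (if (is.null(counts[[key]])) 0
                              else counts[[key]]) + 1
        }
    }
    cnt <- unlist(counts)
    cnt <- cnt[order(-cnt, names(cnt))]
    sum(cnt[seq_len(min(x, length(cnt)))]) / (M * x)
}
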