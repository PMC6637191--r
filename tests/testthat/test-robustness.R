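test_that("robustness R matches direct counting on worked examples", {
    expect_equal(robustnessR(list(c("A", "B", "C"), c("A", "B", "C")), 3), 1)
    expect_equal(robustnessR(list(c("A", "B"), c("C", "D"), c("E", "F")),
                             2), 1/3)
    ## {A,B,C} vs {A,B,D}: counts A2 B2 then C or D 1 -> 5/6
    expect_equal(robustnessR(list(c("A", "B", "C"), c("A", "B", "D")), 3),
                 5/6)
    expect_error(robustnessR(list(c("A"), c("A", "B")), 2), "length")
})

test_that("robustness R equals the counting oracle over many list sets", {
    loci <- LETTERS[1:6]
    ## exhaustive over all ordered pairs of 2-prefixes from 6 loci
    prefixes <- list()
    for (a in loci) for (b in setdiff(loci, a))
        prefixes[[length(prefixes) + 1]] <- c(a, b)
    for (i in seq_along(prefixes)) for (j in seq_along(prefixes)) {
        ls <- list(prefixes[[i]], prefixes[[j]])
        expect_equal(robustnessR(ls, 2), robustnessOracle(ls, 2))
    }
    ## random sets with M in {2,3}, x in {2,3,4}
    set.seed(11)
    for (rep in 1:300) {
        M <- sample(2:3, 1); x <- sample(2:4, 1)
        ls <- lapply(seq_len(M), function(i) sample(loci, x))
        expect_equal(robustnessR(ls, x), robustnessOracle(ls, x))
        r <- robustnessR(ls, x)
        expect_gte(r, 1 / M); expect_lte(r, 1)
    }
})

test_that("R is invariant to relabeling loci and to list order", {
    set.seed(12)
    ls <- lapply(1:3, function(i) sample(LETTERS[1:6], 4))
    r <- robustnessR(ls, 3)
    expect_equal(robustnessR(rev(ls), 3), r)
    relab <- setNames(letters[1:6], LETTERS[1:6])
    expect_equal(robustnessR(lapply(ls, function(l)
        unname(relab[l])), 3), r)
})

test_that("Spearman on top-x lists uses the x+1 padding convention", {
    expect_equal(spearmanTop(c("A", "B", "C"), c("A", "B", "C"), 3), 1)
    ## reversed common top-x: textbook sum of d^2 oracle
    a <- c("A", "B", "C", "D"); b <- rev(a)
    n <- 4; d2 <- sum((1:4 - 4:1)^2)
    expect_equal(spearmanTop(a, b, 4), 1 - 6 * d2 / (n * (n^2 - 1)))
    ## disjoint prefixes against the same oracle with rank x+1 padding
    a2 <- c("A", "B"); b2 <- c("C", "D")
    ra <- c(1, 2, 3, 3); rb <- c(3, 3, 1, 2)
    expect_equal(spearmanTop(a2, b2, 2),
                 cor(ra, rb, method = "spearman"))
    expect_lt(spearmanTop(a2, b2, 2), 0)
    expect_error(spearmanTop(a, b, 1))
    ## intersection-only variant
    expect_equal(spearmanTop(a, a, 4, intersectionOnly = TRUE), 1)
})

test_that("intersection curves count shared prefixes", {
    ## enumerate prefixes: {L1}vs{L3} empty; {L1,L2}vs{L3,L9} empty;
    ## {L1,L2,L3}vs{L3,L9,L1} shares L1 and L3
    a <- c("L1", "L2", "L3"); b <- c("L3", "L9", "L1")
    expect_equal(intersectionCurve(a, b, 3), c(0L, 0L, 2L))
    expect_equal(intersectionCurve(a, a, 3), 1:3)        # diagonal
    expect_equal(intersectionCurve(a, c("X", "Y", "Z"), 3), rep(0L, 3))
    ## monotone with bounded increments on random lists
    set.seed(13)
    for (i in 1:20) {
        u <- sample(paste0("L", 1:30))
        v <- sample(paste0("L", 1:30))
        cv <- intersectionCurve(u, v, 30)
        expect_true(all(diff(cv) %in% 0:2))
        expect_true(all(cv <= seq_len(30)))
    }
})

test_that("combined rankings follow order of appearance in the intersection", {
    a <- c("A", "B", "C"); b <- c("B", "A", "C")
    comb <- combineRankings(list(a, b))
    ## A and B both enter at x = 2 with equal rank sums; id order applies
    expect_equal(comb$locus, c("A", "B", "C"))
    expect_equal(comb$entry, c(2L, 2L, 3L))

    ## a common locus at positions 1 and 3 enters at x = 3
    l1 <- c("L", "P", "Q"); l2 <- c("R", "S", "L")
    c2 <- combineRankings(list(l1, l2))
    expect_equal(c2$entry[c2$locus == "L"], 3L)
    expect_equal(c2$locus[1], "L")  # only locus in the full intersection

    ## M copies of one list reproduce that list
    c3 <- combineRankings(list(a, a, a))
    expect_equal(c3$locus, a)
    expect_error(combineRankings(list(a)))
})

test_that("pairwise summaries produce C(M,2) intra pairs and per-fold between pairs", {
    mk <- function(seed) { set.seed(seed); sample(paste0("L", 1:20)) }
    tenFolds <- lapply(1:10, mk)
    s <- pairwiseSummary(list(m1 = tenFolds), mode = "intra",
                         xGrid = c(5L))
    expect_equal(s$nPairs, 45)
    s2 <- pairwiseSummary(list(m1 = tenFolds[1:2]), mode = "intra",
                          xGrid = c(5L))
    expect_equal(s2$nPairs, 1)
    ## identical rankings everywhere: mean R 1, SE 0 at every x
    same <- lapply(1:10, function(i) paste0("L", 1:20))
    s3 <- pairwiseSummary(list(m = same), mode = "intra",
                          xGrid = c(2L, 5L, 10L))
    expect_true(all(s3$mean == 1)); expect_true(all(s3$se == 0))
    ## between mode: one pair per fold
    s4 <- pairwiseSummary(list(m1 = tenFolds, m2 = same),
                          mode = "between", xGrid = c(5L))
    expect_equal(s4$nPairs, 10)
    expect_error(pairwiseSummary(list(m1 = tenFolds), mode = "between"))
})

test_that("overlap metrics report percentages of shared selections", {
    run <- list(snps = paste0("s", 1:40), loci = paste0("L", 1:20),
                topSnps = paste0("s", 1:10), topLoci = paste0("L", 1:10))
    self <- overlapMetrics(run, run)
    expect_true(all(self == 100))
    other <- list(snps = paste0("x", 1:40), loci = paste0("Y", 1:20),
                  topSnps = paste0("x", 1:10), topLoci = paste0("Y", 1:10))
    expect_true(all(overlapMetrics(run, other) == 0))
    half <- run; half$topLoci <- c(paste0("L", 1:5), paste0("Z", 1:5))
    expect_equal(unname(overlapMetrics(half, run)["ItopLoci"]), 50)
    ## GWAS reference compares loci only
    g <- overlapMetrics(run, paste0("L", 1:10), gwas = TRUE)
    expect_equal(unname(g["ILociGWAS"]), 50)
    expect_equal(unname(g["ItopLociGWAS"]), 100)
    expect_error(overlapMetrics(run, character(0), gwas = TRUE), "empty")
})

test_that("reference loci map onto partition labels", {
    ref <- data.frame(chrom = c("1", "2"), bp = c(100, 600000),
                      or = c(1.2, 1.3))
    expect_equal(referenceLocusLabels(ref), c("1:0", "2:1"))
})
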