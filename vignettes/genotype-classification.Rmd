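---
title: "Classifying case-control genotypes and measuring locus-ranking stability"
author: "snpML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying case-control genotypes and measuring locus-ranking stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpML)
```

# Scope

`snpML` studies two linked questions on case-control SNP data: how well
different classifier families predict disease status from genotypes, and
how *stable* the genomic loci they flag as important are when the analysis
is repeated on resampled data. Because the genotype archives such analyses
are usually run on are access-restricted, the package ships a synthetic
generator that reproduces the statistical structure the method assumes, and
every downstream stage is specified and tested against it.

# The simulated data-generating model

`simulateGenotypes()` draws data from the model the analysis itself
presumes, which makes it a *positive control*, not a replica of any real
cohort.

**Genotypes.** Each SNP j has a minor-allele frequency (MAF) drawn
uniformly from a configured range (default 0.001–0.5 for null SNPs). A
sample's genotype is the sum of two allele draws, so unlinked SNPs satisfy
Hardy-Weinberg equilibrium (HWE) by construction.

**Linkage disequilibrium.** Consecutive SNPs are grouped into blocks
(default 10 SNPs). Within a block, each of a sample's two alleles is copied
from the same haplotype at the previous SNP with probability `ldRho`
(default 0.5) and drawn fresh otherwise. This first-order copying process
is the simplest mechanism that makes nearby SNPs partially interchangeable
— the property that motivates aggregating SNP scores to loci — while
leaving HWE intact. It does not reproduce empirical human LD maps, decay
with physical distance, or recombination hot spots.

**Phenotype.** Case probability follows the additive liability model
`P(case|g) = sigmoid(β₀ + Σ βⱼ gⱼ)` with `βⱼ = ±log ORⱼ` on `nCausal`
SNPs, odds ratios uniform in a configured range (default 1.1–1.5, the
effect sizes typical of common-variant risk loci). Causal SNPs draw their
MAF from 0.05–0.5: loci detectable at such odds ratios in cohorts of this
size are common variants, and giving causal status to a 0.1% variant would
make it undetectable by any method, which is not a useful test condition.
`β₀` is calibrated by bisection so the expected prevalence matches the
requested case fraction; exact class quotas are then filled by rejection
sampling, with an explicit error if the budget (default 30x the requested
sample count) is exhausted.

**Marker density.** Genotyping arrays designed around known risk loci
carry more markers near them. The generator mimics this by placing extra
null SNPs inside the 500 kb windows that contain a causal SNP
(`densityEnrichment`, default 3x). This non-uniform density is what makes
the random-model locus overlap exceed naive chance expectations — an
artifact the robustness analyses must be able to expose.

**Missingness.** Genotypes go missing at a per-entry Bernoulli rate that
may differ between cases and controls, emulating residual batch or
stratification differences between case and control genotyping. On arrays,
the two alleles of a genotype call fail together, so missingness is a
genotype-level state. The differential-rate mechanism is a stand-in for an
unknown real mechanism, not a claim about any particular cohort.

**What is not emulated**: population structure and admixture, relatedness,
sex chromosomes, genotyping error that is not missingness, and phased
haplotypes. Tests passing on this generator therefore certify the
pipeline's statistical machinery, not its behaviour under confounding.

# Pre-processing

**QC** (`applyQC()`) filters in a fixed order — samples with > 5% missing
genotypes, then SNPs with > 2% missing rate, then SNPs with an HWE
p-value < 1e-10 computed in surviving controls only. The order matters
because each step changes the rates the next one sees; the report tallies
each step. The HWE test is the 1-df chi-squared goodness-of-fit test
against the proportions implied by the sample allele frequency, the
conventional choice behind thresholds as extreme as 1e-10 at biobank
sample sizes; monomorphic SNPs return p = 1.

**Imputation** (`imputeGenotypes()`). `Unkw` keeps missing values (for the
categorical coding below); `Maj` replaces each missing allele with the most
common observed allele; `HWc`/`HWa` draw a missing genotype as
Binomial(2, q̂) with q̂ estimated from observed controls or from all
observed samples. The Binomial(2, q̂) draw is our canonical reading of "a
random draw consistent with HWE"; an alternative would be to resample from
the observed genotype-class frequencies, which differs only at SNPs out of
HWE. Each SNP uses its own seeded stream, so imputation at one SNP is
unaffected by how many other SNPs have missing entries.

**Coding** (`encodeGenotypes()`). `sum` is the additive 0/1/2 coding (one
column per SNP); `OHE` uses three indicator columns per SNP, dropping
additivity; `raw` uses two per-allele binary columns (`ceil(g/2)`,
`floor(g/2)`), which spans the same three genotype classes with fewer
columns; `OHE4` adds an unknown-genotype indicator and is the only coding
defined on non-imputed data. `sum` is exactly the (0,1,2)-weighted collapse
of `OHE` — a linear identity the tests assert.

A warning this structure makes visible: when missingness differs by class,
the `OHE4` unknown-indicator columns are themselves predictive, and a
classifier will exploit them. The acceptance suite reproduces this
inflation (AUC far above 0.5 on *null* SNPs) and shows HWE-based
imputation removes it. High AUC under `Unkw`-style codings on real data is
therefore not evidence of genetic signal.

# SNP preselection

`associationTests()` computes four single-SNP chi-squared tests: genotypic
(2x3 table, 2 df), dominant (AA vs Aa+aa), Cochran-Armitage trend with
scores 0/1/2 (the score test of the additive logistic model), and allelic
(2x2 on 2N allele counts). "Combined alleles counting" contingency tables
are read as the standard allelic test, and "independent classes" as the
2-df genotypic test. Degenerate tables — monomorphic SNPs, an absent
genotype class reducing the table, or a single phenotype class — return
p = 1 rather than erroring, and no continuity corrections are applied.
The implementation is vectorized over SNPs from the genotype-count tables
(a 10,000-SNP screen takes ~1 s); the test suite checks it against
`chisq.test()` and `prop.trend.test()` on random tables.

`preselectSnps()` applies the MAF screen first (strict >), then keeps the
union of the four per-test lists at p < `pMax` (strict <). The union, not
the intersection, is kept so that the panel is as agnostic as possible
about the genetic model. Thresholds are screens, not inference, so no
multiple-testing correction is applied anywhere.

By default experiments preselect on each refold's *training split only*.
Screening on the full dataset before splitting — as published protocols
sometimes do — leaks test-label information into feature selection; the
effect is visible even on null data, where full-data screening at p < 0.05
biases the random model's held-out AUC a few percent away from 0.5.
`experimentConfig(screenFullData = TRUE)` reproduces the full-data variant for
comparison.

# Model families

`fitModel()` exposes seven families behind one adapter: Lasso, Ridge and
elastic-net logistic regression (via `glmnet`; weights exported, and
scores are exactly `sigmoid(Xw + b)` from the exported weights), gradient
boosted trees (via `xgboost`, single-threaded for reproducibility; gain
importances exported), dense and pre-activation residual multilayer
perceptrons, and the random-weight null model.

The networks are implemented natively in matrix algebra: ReLU stacks of 64
neurons per hidden layer (residual variant: an input projection plus
two-layer pre-activation blocks, requiring an odd hidden-layer count),
trained by mini-batch Adam on the logistic loss with AUC-based early
stopping on a 10% validation split. At desk scale this is faster than a
deep-learning runtime would be, and keeps fits bit-reproducible under a
seed. Published hyper-parameter grids for such comparisons are usually in
supplementary material; here the defaults are standard practice (penalty
grid 1e-4–1e2, elastic-net mixing {0.1, 0.5, 0.9}, ≤ 500 trees, early
stopping) and every value is configuration, not code.
`selectHyperparameters()` picks grid points by 10-fold stratified
cross-validated AUC, breaking ties toward the stronger regularization.
Class imbalance is left unweighted — all controls are kept.

The random model draws i.i.d. standard-normal weights over the preselected
features and never trains. Its held-out AUC is ~0.5 on any fold, which
anchors the AUC scale; its locus rankings calibrate how much ranked-list
overlap marker density alone produces.

`aucScore()` is the Mann-Whitney AUC with ties counted one half;
`ensembleAverage()` is the unweighted mean of member probabilities.

# Feature and locus importance

Three criteria, chosen per family: permutation feature importance (PFI;
mean AUC drop on the test set over 10 permutations of one feature column —
model-agnostic), |weight| for linear families, and gain for tree
ensembles. PFI keeps negative scores (permutation that *improves* AUC is
informative noise) ranked below zero; ties everywhere break by ascending
feature index so that rankings are deterministic, which the robustness
statistics require.

Loci are fixed 500 kb windows: window = `floor((bp - 1 + shift)/500kb)`
per chromosome, with a second "bis" partition shifted by 250 kb to smooth
boundary effects (shift direction is irrelevant to that purpose). A fixed
partition, rather than windows centred on each list's own best SNPs, is
what makes *different* rankings comparable. Multi-column codings collapse
to their SNP's best sub-feature score; a locus scores the maximum over its
member SNPs.

# Robustness and overlap

For M ranked lists and prefix length x, `robustnessR()` counts each
locus's appearances among the M top-x prefixes and sums the x largest
counts, normalized by Mx — R runs from 1/M (disjoint prefixes) to 1
(perfect agreement). Ties at the count cut are resolved by locus id,
deterministically. `spearmanTop()` supplements R with a Spearman
coefficient over the union of the two top-x sets, assigning rank x+1 to a
locus absent from one list (an intersection-only mode is available);
`intersectionCurve()` reports |top-x ∩ top-x| as a function of x.
`combineRankings()` merges model rankings by order of appearance in the
running intersection — a locus enters at the smallest x at which every
list ranks it in its top x, with rank-sum then id tie-breaks.
`pairwiseSummary()` aggregates either all C(M,2) fold pairs within a model
(45 pairs for 10 refolds) or the per-fold pairs between two models, as
mean ± standard error per x.

# Pipeline and problem sizes

`runExperiment()` chains the stages in a fixed order (simulate/load →
optional control subsampling → QC → imputation → stratified refolds →
train-split preselection → coding → optional hyper-parameter CV → fit →
test AUC → importance → locus rankings on both partitions → robustness),
deriving every stage seed from the global seed, so reports rerun
byte-identically. Stratified splitting allocates `round(frac·n_cases)`
cases to the training set and fills the remainder with controls, making
class ratios match to within one sample (a 51,951-sample cohort at 2/3
splits exactly 34,634/17,317).

The test and acceptance suites run at desk scale — 5,000 samples and
1,000–2,000 SNPs for calibration and recovery checks, a 10,000-SNP null
screen for test calibration, and a 600-sample end-to-end rerun check —
sizes chosen so the whole suite completes in a few minutes while leaving
every asymptotic approximation it relies on (chi-squared calibration at
MAF ≥ 0.1, 3-SE binomial bands over independent SNPs) valid.

# Known limitations

Simulated LD is block-wise and first-order, so LD-aware clumping is out of
scope (and unnecessary: windows are fixed). No stratification correction
or genomic control is implemented; on confounded real data the
preselection screen will admit confounded SNPs. The allelic test assumes
HWE-like independence of the 2N alleles. Reference-panel imputation is
deliberately not provided — the HWE draw is the designed comparison point
for studying pre-processing effects, not a state-of-the-art imputer.
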