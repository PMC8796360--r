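# Shared fixture builders; everything is generated in code at test time.

# Small hand-sized cohort from an explicit matrix.
makeCohort <- function(values, labels = NULL, platform = NULL, dataset = NULL) {
    ExpressionCohort(values, labels = labels, platform = platform,
                     dataset = dataset)
}

# Random labeled cohort (pure noise unless classes differ by construction).
# Sample ids carry the seed so cohorts from different seeds can be combined.
randomCohort <- function(nGenes = 20, nSamples = 12, nClasses = 2, seed = 1) {
    set.seed(seed)
    m <- matrix(stats::rnorm(nGenes * nSamples, mean = 5), nGenes, nSamples,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("s%d_%03d", seed, seq_len(nSamples))))
    makeCohort(m, labels = rep_len(paste0("c", seq_len(nClasses)), nSamples))
}

# Default small simulated cohort used across tests; informative and stromal
# set sizes are scaled down to fit desk-sized gene counts.
smallSim <- function(nClasses = 3, nGenes = 100, nPer = 12, seed = 1,
                     nInformativePerClass = 10L, nStromal = 10L, ...) {
    simulateCohort(syntheticConfig(nClasses = nClasses, nGenes = nGenes,
                                   nSamplesPerClassPerPlatform = nPer,
                                   nInformativePerClass = nInformativePerClass,
                                   nStromal = nStromal, seed = seed, ...))
}

# Per-sample strictly increasing transforms (expression here is >= 0).
# The affine map varies by sample on purpose: invariance must hold per
# sample, not just globally.
monotoneTransforms <- list(
    log1p = function(m) apply(m, 2L, log1p),
    cube = function(m) m^3,
    affine = function(m) sweep(sweep(m, 2L, seq_len(ncol(m)) + 1, "*"),
                               2L, seq_len(ncol(m)), "+"))

transformCohort <- function(cohort, f) {
    v <- f(exprValues(cohort))
    dimnames(v) <- dimnames(exprValues(cohort))
    ExpressionCohort(v, labels = classLabels(cohort),
                     platform = platformLabels(cohort),
                     dataset = datasetLabels(cohort))
}

# Ground-truth informative genes as a flat vector.
informativeGenes <- function(truth) {
    unique(unlist(lapply(truth@informative, function(d) d$gene)))
}
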