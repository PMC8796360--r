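# Shared small RF config keeps the forest scale test-sized; the pipeline
# structure (3 stages, OOB bookkeeping) is identical at any tree count.
testRfConfig <- function(nTreesSelection = 300L, nTreesFinal = 300L,
                         borutaTrees = 200L, ...)
    rfConfig(nTreesSelection = nTreesSelection, nTreesFinal = nTreesFinal,
             borutaTrees = borutaTrees, ...)

test_that("stage-1 one-vs-rest models rescue markers of a rare class", {
    set.seed(1)
    lab <- c(rep("A", 20), rep("B", 20), rep("C", 6))
    n <- length(lab)
    m <- matrix(rnorm(20 * n, 5, 1), 20, n,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n)))
    for (g in paste0("g0", 1:4))   # strong A-vs-B splitters
        m[g, ] <- m[g, ] + ifelse(lab == "A", 4, 0)
    for (g in paste0("g0", 5:8))
        m[g, ] <- m[g, ] + ifelse(lab == "B", 4, 0)
    m["g20", ] <- m["g20", ] + ifelse(lab == "C", 6, 0)   # rare-class marker
    co <- makeCohort(m, labels = lab)
    s1 <- stage1SelectGenes(co, testRfConfig(genesPerModel = 2L))
    expect_false("g20" %in% s1$perModelTop$all)
    expect_true("g20" %in% s1$perModelTop$C)
    expect_true("g20" %in% s1$genes)
    expect_lte(length(s1$genes), (3 + 1) * 2)
})

test_that("stage-1 with G = gene count returns all genes", {
    co <- randomCohort(nGenes = 8, nSamples = 12, nClasses = 2, seed = 2)
    expect_warning(s1 <- stage1SelectGenes(co, testRfConfig(genesPerModel = 50L)),
                   "all genes")
    expect_setequal(s1$genes, rownames(co))
})

test_that("stage-2 enumerates all pairs and yields non-negative importances", {
    sim <- smallSim(nClasses = 3, nGenes = 60, nPer = 10, seed = 3)
    genes <- rownames(sim$cohort)[1:20]
    s2 <- stage2RankRules(sim$cohort, genes, testRfConfig())
    expect_equal(nrow(s2$rules), 190L)
    expect_true(all(s2$importance >= 0))
})

test_that("informative up/down pairs outrank pairs of uninformative genes", {
    sim <- smallSim(nClasses = 3, nGenes = 60, nPer = 15, seed = 4)
    tr <- sim$truth
    inf1 <- tr@informative$class1
    genes <- c(inf1$gene[1:4],
               setdiff(rownames(sim$cohort),
                       c(informativeGenes(tr), tr@stromalGenes))[1:4])
    s2 <- stage2RankRules(sim$cohort, genes, testRfConfig())
    isInf <- s2$rules$geneA %in% inf1$gene & s2$rules$geneB %in% inf1$gene
    isNoise <- !(s2$rules$geneA %in% inf1$gene) & !(s2$rules$geneB %in% inf1$gene)
    expect_gt(mean(s2$importance[isInf, "all"]), mean(s2$importance[isNoise, "all"]))
})

test_that("the diversification filter enforces per-gene budgets per ranking", {
    rules <- data.frame(geneA = c("A", "A", "D"), geneB = c("B", "C", "E"))
    imp <- matrix(c(0.9, 0.8, 0.7), 3, 1, dimnames = list(NULL, "all"))
    kept <- diversifyRules(imp, rules, geneRepetition = 1L)
    expect_equal(kept$all, c(1L, 3L))          # (A,C) dropped: A already used
    keptInf <- diversifyRules(imp, rules, geneRepetition = Inf)
    expect_equal(sort(keptInf$all), 1:3)       # identity filter
    # property over random importances
    set.seed(5)
    for (rep in 1:5) {
        genes <- paste0("g", 1:8)
        rr <- enumerateRules(genes)
        im <- matrix(runif(nrow(rr)), ncol = 1, dimnames = list(NULL, "m"))
        k <- diversifyRules(im, rr, 1L)$m
        expect_lte(length(k), nrow(rr))
        dropped <- setdiff(seq_len(nrow(rr)), k)
        for (d in dropped) {
            sharing <- k[rr$geneA[k] %in% c(rr$geneA[d], rr$geneB[d]) |
                         rr$geneB[k] %in% c(rr$geneA[d], rr$geneB[d])]
            expect_true(any(im[sharing, 1] >= im[d, 1]))
        }
    }
})

test_that("the final forest leaves ~ 1/e of samples out of bag and emits probabilities", {
    sim <- smallSim(nClasses = 3, nGenes = 80, nPer = 20, seed = 6)
    model <- trainRFRules(sim$cohort, testRfConfig(genesPerModel = 8L,
                                                   rulesPerModel = 10L))
    inbag <- do.call(cbind, model@forest$inbag.counts)
    oobFrac <- mean(colMeans(inbag == 0))
    expect_lt(abs(oobFrac - exp(-1)), 0.02)
    pr <- predictSamples(model, sim$cohort)
    expect_equal(unname(rowSums(scores(pr))), rep(1, ncol(sim$cohort)),
                 tolerance = 1e-9)
    expect_gte(model@oobAccuracy, 0.95)   # separable synthetic data
})

test_that("training is deterministic given the seed", {
    sim <- smallSim(nClasses = 3, nGenes = 60, nPer = 10, seed = 7)
    cfg <- testRfConfig(genesPerModel = 6L, rulesPerModel = 8L, seed = 17L)
    m1 <- trainRFRules(sim$cohort, cfg)
    m2 <- trainRFRules(sim$cohort, cfg)
    expect_identical(m1@rules, m2@rules)
    expect_identical(m1@oobScores, m2@oobScores)
    expect_identical(scores(predictSamples(m1, sim$cohort)),
                     scores(predictSamples(m2, sim$cohort)))
})

test_that("predictions are invariant to per-sample monotone transforms", {
    sim <- smallSim(nClasses = 3, nGenes = 60, nPer = 10, seed = 8)
    model <- trainRFRules(sim$cohort, testRfConfig(genesPerModel = 6L,
                                                   rulesPerModel = 8L))
    base <- predictSamples(model, sim$cohort)
    for (f in monotoneTransforms) {
        pr <- predictSamples(model, transformCohort(sim$cohort, f))
        expect_identical(predictedClass(pr), predictedClass(base))
        expect_identical(scores(pr), scores(base))
    }
})

test_that("OOB accuracy estimates held-out accuracy", {
    cfg <- syntheticConfig(nClasses = 3, nGenes = 100, nInformativePerClass = 12,
                           effectSize = 1, noiseSD = 0.8,
                           nSamplesPerClassPerPlatform = 30, seed = 9)
    sim <- simulateCohort(cfg)
    model <- trainRFRules(sim$cohort, testRfConfig(genesPerModel = 8L,
                                                   rulesPerModel = 10L,
                                                   nTreesFinal = 1000L))
    held <- simulateCohort(cfg, nPerClassPerPlatform = 40, sampleSeed = 71)$cohort
    pr <- predictSamples(model, held)
    heldAcc <- mean(predictedClass(pr) == classLabels(held))
    expect_lt(abs(model@oobAccuracy - heldAcc), 0.05)
})

test_that("shadow-feature pruning rejects planted noise and keeps perfect rules", {
    sim <- smallSim(nClasses = 3, nGenes = 90, nPer = 20, seed = 10)
    tr <- sim$truth
    lab <- classLabels(sim$cohort)
    # candidate up-vs-down pairs per class, kept only when empirically
    # near-perfect (delta >= 0.95): the baseline gap of an arbitrary pair can
    # swamp the class effect, which is not the case being planted here
    cand <- do.call(rbind, lapply(names(tr@informative), function(cl) {
        d <- tr@informative[[cl]]
        g <- expand.grid(geneA = d$gene[d$direction == "up"],
                         geneB = d$gene[d$direction == "down"],
                         stringsAsFactors = FALSE)
        g$class <- cl
        g
    }))
    vals <- ruleValues(binarizeRules(sim$cohort, cand))
    cand$delta <- vapply(seq_len(nrow(cand)), function(i)
        tspScore(vals[i, ], lab, cand$class[i])[["delta"]], numeric(1))
    infRules <- head(cand[cand$delta >= 0.95, c("geneA", "geneB")], 12)
    noiseGenes <- setdiff(rownames(sim$cohort),
                          c(informativeGenes(tr), tr@stromalGenes))
    noiseRules <- data.frame(geneA = noiseGenes[1:10], geneB = noiseGenes[11:20])
    rules <- rbind(infRules, noiseRules)
    model <- trainFinalForest(sim$cohort, rules, testRfConfig())
    pruned <- borutaPrune(model, maxIter = 30L, seed = 12)
    isNoise <- c(rep(FALSE, nrow(infRules)), rep(TRUE, nrow(noiseRules)))
    expect_gte(mean(pruned$result@status[isNoise] == "rejected"), 0.9)
    expect_gte(mean(pruned$result@status[!isNoise] == "confirmed"), 0.9)
})

test_that("kNN rule imputation copies consistent neighbours and tolerates masked genes", {
    sim <- smallSim(nClasses = 3, nGenes = 80, nPer = 15, seed = 11)
    model <- trainRFRules(sim$cohort, testRfConfig(genesPerModel = 8L,
                                                   rulesPerModel = 10L))
    v <- model@trainRuleValues
    # a sample identical to a training sample on the shared rules
    probe <- v[, 3, drop = FALSE]
    probe[1:3, ] <- NA
    filled <- imputeMissingRules(probe, model, k = 1L)   # nearest-neighbour copy
    expect_equal(unname(filled[, 1]), as.numeric(v[, 3]))
    filled5 <- imputeMissingRules(probe, model, k = 5L)
    expect_equal(unname(filled5[1:3, 1]), as.numeric(v[1:3, 3]))
    # masking 10% of genes rarely flips high-margin predictions
    full <- predictSamples(model, sim$cohort)
    set.seed(13)
    drop <- sample(rownames(sim$cohort), ceiling(0.1 * nrow(sim$cohort)))
    masked <- exprValues(sim$cohort)[setdiff(rownames(sim$cohort), drop), ]
    prM <- predictSamples(model, masked)
    hi <- scoreMargin(full) > 0.3
    if (any(hi))
        expect_lte(mean(predictedClass(prM)[hi] != predictedClass(full)[hi]), 0.05)
    # refusal when too many rules are unevaluable
    few <- exprValues(sim$cohort)[unique(c(model@rules$geneA[1], model@rules$geneB[1])), ]
    expect_error(predictSamples(model, few), "refusing")
})

test_that("the OOB proximity matrix is symmetric, bounded, and separates classes", {
    sim <- smallSim(nClasses = 2, nGenes = 60, nPer = 10, seed = 14)
    co <- sim$cohort
    # add exact duplicates of the first sample
    v <- cbind(exprValues(co), dup1 = exprValues(co)[, 1], dup2 = exprValues(co)[, 1])
    lab <- c(classLabels(co), classLabels(co)[1], classLabels(co)[1])
    co2 <- makeCohort(v, labels = unname(lab))
    model <- suppressWarnings(   # small gene pool yields < 8 filtered rules
        trainRFRules(co2, testRfConfig(genesPerModel = 6L, rulesPerModel = 8L,
                                       nTreesFinal = 1000L)))
    prox <- extractProximity(model)
    expect_equal(prox, t(prox))
    expect_true(all(prox >= 0 & prox <= 1, na.rm = TRUE))
    expect_true(all(diag(prox) == 1))
    expect_gte(prox["dup1", "dup2"], 0.8)
    labs <- classLabels(co2)
    cross <- prox[labs == "class1", labs == "class2"]
    expect_lte(mean(cross, na.rm = TRUE), 0.2)
})
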