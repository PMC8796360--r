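test_that("Wilcoxon gene selection ranks clean markers on top", {
    set.seed(1)
    n <- 24
    lab <- rep(c("T", "R"), each = n / 2)
    m <- matrix(rnorm(10 * n, 5, 1), 10, n,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:n)))
    m["g1", lab == "T"] <- m["g1", lab == "T"] + 10   # strictly higher in T
    m["g2", lab == "T"] <- m["g2", lab == "T"] - 10
    sel <- selectGenesWilcoxon(makeCohort(m, labels = lab), "T", n = 2)
    expect_equal(sel$up[1], "g1")
    expect_equal(sel$down[1], "g2")
    expect_error(selectGenesWilcoxon(makeCohort(m, labels = lab), "Z", 2), "absent")
})

test_that("platform-wise gene selection excludes genes discriminative on one platform only", {
    set.seed(2)
    n <- 40
    lab <- rep(rep(c("T", "R"), each = 10), 2)
    plat <- rep(c("p1", "p2"), each = 20)
    m <- matrix(rnorm(8 * n, 5, 1), 8, n,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:n)))
    m["g1", lab == "T"] <- m["g1", lab == "T"] + 8          # both platforms
    sel1only <- lab == "T" & plat == "p1"
    m["g2", sel1only] <- m["g2", sel1only] + 8              # platform 1 only
    co <- makeCohort(m, labels = lab, platform = plat)
    sel <- selectGenesWilcoxon(co, "T", n = 1, platformWise = TRUE)
    expect_equal(sel$up[1], "g1")
    selNaive <- selectGenesWilcoxon(co, "T", n = 2, platformWise = FALSE)
    expect_true("g2" %in% selNaive$up)   # without the flag it sneaks in
})

test_that("pivot genes allow a non-differential gene to anchor the best rule", {
    n <- 20
    lab <- rep(c("T", "R"), each = n / 2)
    m <- rbind(A1 = ifelse(lab == "T", 10, 8),
               A2 = ifelse(lab == "T", 10.2, 8.2),
               D1 = ifelse(lab == "T", 0, 2),
               D2 = ifelse(lab == "T", 0.1, 2.1),
               P = rep(9, n))                      # constant pivot between 8 and 10
    m <- m + matrix(seq(0, 0.009, length.out = 5 * n), 5, n)  # break exact ties
    colnames(m) <- paste0("s", 1:n)
    co <- makeCohort(m, labels = c(lab))
    base <- trainKTSP(co, ktspConfig(nGenesPerDirection = 2, fixedK = 1,
                                     pivotGenes = FALSE))
    expect_lt(base@rules$T$delta[1], 1)            # no in-pool pair crosses over
    piv <- trainKTSP(co, ktspConfig(nGenesPerDirection = 2, fixedK = 1,
                                    pivotGenes = TRUE))
    expect_equal(piv@rules$T$delta[1], 1)
    expect_true("P" %in% c(piv@rules$T$geneA, piv@rules$T$geneB))
})

test_that("trained voters use gene-disjoint rules and fixed k is honoured", {
    sim <- smallSim(nClasses = 3, nGenes = 100, nPer = 15, seed = 3)
    model <- trainKTSP(sim$cohort, ktspConfig(nGenesPerDirection = 10, fixedK = 3))
    expect_true(methods::validObject(model))
    expect_equal(unname(model@k), rep(3L, 3))
    for (cl in model@classes) {
        genes <- c(model@rules[[cl]]$geneA, model@rules[[cl]]$geneB)
        expect_equal(anyDuplicated(genes), 0L)
        expect_true(all(diff(model@rules[[cl]]$delta) <= 1e-12))
    }
})

test_that("variance optimization picks k within the range and per-class k may differ", {
    sim <- smallSim(nClasses = 3, nGenes = 120, nPer = 20, seed = 4)
    model <- trainKTSP(sim$cohort, ktspConfig(nGenesPerDirection = 8, kRange = 2:6))
    expect_true(all(model@k >= 2 & model@k <= 6))
})

test_that("k-TSP scores are vote fractions with exact tie flags", {
    rules <- list(
        X = data.frame(geneA = "g1", geneB = "g2", delta = 1, gamma = 1),
        Y = data.frame(geneA = "g3", geneB = "g4", delta = 1, gamma = 1))
    model <- methods::new("KTSPModel", classes = c("X", "Y"), rules = rules,
                          k = c(X = 1L, Y = 1L), config = ktspConfig())
    m <- cbind(s1 = c(g1 = 2, g2 = 1, g3 = 2, g4 = 1),   # both rules TRUE -> tie
               s2 = c(g1 = 2, g2 = 1, g3 = 1, g4 = 2))   # only X TRUE
    pr <- predictSamples(model, m)
    expect_true(tieFlag(pr)[["s1"]])
    expect_equal(unname(predictedClass(pr)[["s1"]]), "X")  # lexicographic winner
    expect_equal(unname(scoreMargin(pr)[["s1"]]), 0)
    expect_false(tieFlag(pr)[["s2"]])
    expect_equal(unname(scoreMargin(pr)[["s2"]]), 1)
    # scores live on the vote grid
    sim <- smallSim(nClasses = 3, nGenes = 80, nPer = 10, seed = 5)
    km <- trainKTSP(sim$cohort, ktspConfig(nGenesPerDirection = 6, fixedK = 4))
    sc <- scores(predictSamples(km, sim$cohort))
    expect_true(all(abs(sc * 4 - round(sc * 4)) < 1e-12))
})

test_that("k-TSP predictions are invariant to per-sample monotone transforms", {
    sim <- smallSim(nClasses = 3, nGenes = 80, nPer = 10, seed = 6)
    model <- trainKTSP(sim$cohort, ktspConfig(nGenesPerDirection = 6, fixedK = 3))
    base <- predictSamples(model, sim$cohort)
    for (f in monotoneTransforms) {
        tr <- transformCohort(sim$cohort, f)
        pr <- predictSamples(model, tr)
        expect_identical(predictedClass(pr), predictedClass(base))
        expect_identical(scores(pr), scores(base))
    }
})

test_that("one-vs-one and platform-wise variants reduce to the default in degenerate settings", {
    sim <- smallSim(nClasses = 2, nGenes = 80, nPer = 15, seed = 7)
    cfgA <- ktspConfig(nGenesPerDirection = 6, fixedK = 3)
    cfgB <- ktspConfig(nGenesPerDirection = 6, fixedK = 3,
                       geneSelectionMode = "one_vs_one",
                       ruleScoringMode = "one_vs_one")
    a <- trainKTSP(sim$cohort, cfgA); b <- trainKTSP(sim$cohort, cfgB)
    expect_identical(a@rules, b@rules)
    cfgC <- ktspConfig(nGenesPerDirection = 6, fixedK = 3, platformWise = TRUE)
    c <- trainKTSP(sim$cohort, cfgC)   # single platform
    expect_identical(a@rules, c@rules)
})

test_that("a single binary voter with odd k cannot produce an ambiguous majority", {
    sim <- smallSim(nClasses = 2, nGenes = 80, nPer = 12, seed = 8)
    model <- trainKTSP(sim$cohort, ktspConfig(nGenesPerDirection = 6, fixedK = 3))
    sc <- scores(predictSamples(model, sim$cohort))
    expect_true(all(abs(sc - 0.5) > 1e-9))   # odd k: vote fraction never 1/2
})

test_that("tie prevalence declines as the fixed rule count grows", {
    sim <- smallSim(nClasses = 5, nGenes = 150, nPer = 12, seed = 9,
                    effectSize = 1, noiseSD = 0.8)
    tab <- suppressWarnings(
        tieSweep(sim$cohort, kValues = c(2L, 20L), reps = 2L,
                 config = ktspConfig(nGenesPerDirection = 8), seed = 21))
    expect_gt(tab$tieRate[tab$k == 2], 0)
    expect_lte(tab$tieRate[tab$k == 20], tab$tieRate[tab$k == 2])
})
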