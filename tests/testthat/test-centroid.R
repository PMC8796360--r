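test_that("gene selection takes strong markers and honours the AUC gate", {
    # one massively upregulated gene with m = 1
    set.seed(1)
    n <- 20
    lab <- rep(c("T", "R"), each = n / 2)
    m <- matrix(rnorm(6 * n, 5, 0.3), 6, n,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:n)))
    m["g1", lab == "T"] <- m["g1", lab == "T"] + 5
    m["g2", lab == "T"] <- m["g2", lab == "T"] - 5
    sel <- selectCentroidGenes(makeCohort(m, labels = lab), m = 1)
    expect_equal(sel$genes$T$up, "g1")
    expect_equal(sel$genes$T$down, "g2")
})

test_that("a significant but weakly discriminative gene is excluded by the AUC gate", {
    # 600 + 600 samples; gate gene: P(v=1|T) = 0.6 vs 0.5 -> folded AUC 0.55,
    # moderated-t p well below 0.05 at this n
    set.seed(2)
    nT <- nR <- 600
    lab <- rep(c("T", "R"), c(nT, nR))
    gate <- c(rep(1, 0.6 * nT), rep(0, 0.4 * nT), rep(1, 0.5 * nR), rep(0, 0.5 * nR))
    good <- ifelse(lab == "T", 8, 4) + rnorm(nT + nR, 0, 0.5)
    bad2 <- ifelse(lab == "T", 4, 8) + rnorm(nT + nR, 0, 0.5)
    m <- rbind(gGate = gate, gUp = good, gDown = bad2)
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    co <- makeCohort(m, labels = lab)
    sel <- suppressWarnings(selectCentroidGenes(co, m = 2))
    stT <- sel$stats$T
    expect_lt(stT$p[stT$gene == "gGate"], 0.05)
    expect_lt(max(stT$auc[stT$gene == "gGate"], 1 - stT$auc[stT$gene == "gGate"]), 0.6)
    expect_false("gGate" %in% unlist(sel$genes$T))
})

test_that("selection recovers ground-truth informative genes on synthetic data", {
    sim <- smallSim(nClasses = 3, nGenes = 120, nPer = 25, seed = 5,
                    effectSize = 2, noiseSD = 0.5)
    sel <- suppressWarnings(selectCentroidGenes(sim$cohort, m = 8))
    picked <- unique(unlist(sel$genes))
    expect_gte(mean(picked %in% informativeGenes(sim$truth)), 0.9)
})

test_that("centroid construction identities hold", {
    set.seed(3)
    m <- matrix(rnorm(30, 5), 10, 3,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
    lab <- c("a", "b", "c")
    gl <- list(a = list(up = "g1", down = "g2"), b = list(up = "g3", down = "g4"),
               c = list(up = "g5", down = "g6"))
    co1 <- makeCohort(m, labels = lab)
    raw <- buildCentroids(co1, gl, mode = "raw")
    # one sample per class: centroid equals that sample
    for (i in 1:3)
        expect_equal(unname(raw@centroids[, lab[i]]), unname(m[raw@unionGenes, i]))
    # larger cohort: centered centroids average to zero with class weights
    co <- randomCohort(nGenes = 12, nSamples = 18, nClasses = 3, seed = 4)
    gl2 <- list(c1 = list(up = "g001", down = "g002"),
                c2 = list(up = "g003", down = "g004"),
                c3 = list(up = "g005", down = "g006"))
    rawM <- buildCentroids(co, gl2, mode = "raw")
    cenM <- buildCentroids(co, gl2, mode = "centered")
    w <- table(classLabels(co))[colnames(cenM@centroids)]
    expect_equal(unname(cenM@centroids %*% as.numeric(w) / sum(w)),
                 matrix(0, length(cenM@unionGenes), 1), tolerance = 1e-12)
    # raw and centered differ by exactly the per-gene training means
    expect_equal(rawM@centroids - cenM@centroids,
                 matrix(cenM@rowMeansTrain, length(cenM@unionGenes),
                        3, dimnames = dimnames(rawM@centroids)))
})

test_that("nearest-centroid prediction follows Pearson correlation", {
    co <- randomCohort(nGenes = 15, nSamples = 12, nClasses = 3, seed = 6)
    gl <- list(c1 = list(up = c("g001", "g007"), down = "g002"),
               c2 = list(up = "g003", down = c("g004", "g008")),
               c3 = list(up = "g005", down = "g006"))
    model <- buildCentroids(co, gl, mode = "raw")
    # a sample equal to a centroid correlates 1 with it
    probe <- matrix(model@centroids[, "c2"], ncol = 1,
                    dimnames = list(model@unionGenes, "probe"))
    pr <- predictSamples(model, probe)
    expect_equal(unname(scores(pr)[1, "c2"]), 1.0)
    expect_equal(unname(predictedClass(pr)), "c2")
    # positive-affine transforms leave the prediction identical
    pr2 <- predictSamples(model, probe * 3.7 + 11)
    expect_equal(scores(pr2), scores(pr), tolerance = 1e-12)
    # zero-variance sample is refused
    flat <- matrix(5, length(model@unionGenes), 1,
                   dimnames = list(model@unionGenes, "flat"))
    expect_error(predictSamples(model, flat), "variance")
})

test_that("prediction is perfect on noise-free synthetic data", {
    sim <- smallSim(nClasses = 3, nGenes = 80, nPer = 8, seed = 7, noiseSD = 0)
    model <- suppressWarnings(trainCentroid(sim$cohort, m = 5, mode = "raw"))
    pr <- predictSamples(model, sim$cohort)
    expect_equal(mean(predictedClass(pr) == classLabels(sim$cohort)), 1.0)
})

test_that("centered-mode prediction depends only on stored training means, not the batch", {
    sim <- smallSim(nClasses = 3, nGenes = 100, nPer = 15, seed = 8)
    model <- suppressWarnings(trainCentroid(sim$cohort, m = 6, mode = "centered"))
    te <- simulateCohort(syntheticConfig(nClasses = 3, nGenes = 100,
                                         nSamplesPerClassPerPlatform = 15, seed = 8),
                         nPerClassPerPlatform = 6, sampleSeed = 55)$cohort
    full <- predictSamples(model, te)
    solo <- predictSamples(model, te[, 1])
    expect_equal(scores(solo)[1, ], scores(full)[1, ])
})

test_that("raw-mode correlations exceed centered-mode correlations on average", {
    sim <- smallSim(nClasses = 3, nGenes = 100, nPer = 15, seed = 9)
    sel <- suppressWarnings(selectCentroidGenes(sim$cohort, m = 6))
    raw <- buildCentroids(sim$cohort, sel$genes, mode = "raw")
    cen <- buildCentroids(sim$cohort, sel$genes, mode = "centered")
    expect_gt(mean(scores(predictSamples(raw, sim$cohort))),
              mean(scores(predictSamples(cen, sim$cohort))))
})

test_that("missing centroid genes are tolerated up to the threshold", {
    sim <- smallSim(nClasses = 3, nGenes = 100, nPer = 10, seed = 10)
    model <- suppressWarnings(trainCentroid(sim$cohort, m = 6, mode = "raw"))
    v <- exprValues(sim$cohort)
    dropFew <- v[setdiff(rownames(v), model@unionGenes[1]), , drop = FALSE]
    expect_warning(predictSamples(model, dropFew), "dropping")
    dropMost <- v[setdiff(rownames(v),
                          model@unionGenes[seq_len(ceiling(0.5 * length(model@unionGenes)))]),
                  , drop = FALSE]
    expect_error(predictSamples(model, dropMost), "missing")
})

test_that("the size sweep produces nested models with non-decreasing unions", {
    sim <- smallSim(nClasses = 3, nGenes = 150, nInformativePerClass = 30,
                    nPer = 15, seed = 11, effectDecay = 0.9)
    sweep <- suppressWarnings(
        centroidSizeSweep(sim$cohort, mValues = c(5L, 10L, 20L), mode = "raw"))
    expect_equal(nrow(sweep), 3L)
    expect_true(all(diff(sweep$unionSize) >= 0))
    expect_length(attr(sweep, "models"), 3L)
})
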