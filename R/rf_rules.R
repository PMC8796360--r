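#' @include AllClasses.R pair_rules.R
NULL

#' Rule-based Random Forest configuration
#'
#' Defaults follow the published pipeline settings: 5000 trees for both the
#' selection and final forests, node size 1, mtry of 10% of features during
#' gene/rule selection and the square root of the rule count in the final
#' probability forest, impurity (Gini) variable importance, and at most one
#' retained rule per gene within each importance ranking.
#'
#' @param genesPerModel top genes kept per stage-1 forest (G).
#' @param rulesPerModel top filtered rules kept per stage-2 model (R).
#' @param nTreesSelection trees for the stage-1/stage-2 selection forests.
#' @param nTreesFinal trees for the final probability forest.
#' @param nodeSize minimum terminal node size.
#' @param mtryFraction fraction of features tried per split during
#'   selection.
#' @param geneRepetition max retained rules per gene within one importance
#'   ranking (diversification filter).
#' @param borutaTrees trees per shadow-pruning iteration.
#' @param seed forest seed; the pipeline is deterministic given it.
#' @return config list for [trainRFRules()].
#' @export
rfConfig <- function(genesPerModel = 50L, rulesPerModel = 50L,
                     nTreesSelection = 5000L, nTreesFinal = 5000L,
                     nodeSize = 1L, mtryFraction = 0.10,
                     geneRepetition = 1L, borutaTrees = 500L, seed = 1L) {
    stopifnot(genesPerModel >= 1L, rulesPerModel >= 1L,
              mtryFraction > 0, mtryFraction <= 1)
    list(genesPerModel = as.integer(genesPerModel),
         rulesPerModel = as.integer(rulesPerModel),
         nTreesSelection = as.integer(nTreesSelection),
         nTreesFinal = as.integer(nTreesFinal),
         nodeSize = as.integer(nodeSize), mtryFraction = mtryFraction,
         geneRepetition = as.integer(geneRepetition),
         borutaTrees = as.integer(borutaTrees), seed = as.integer(seed))
}

# One selection forest; returns named impurity importances.
selectionForestImportance <- function(x, y, config, seed) {
    rf <- ranger::ranger(x = x, y = y,
                         num.trees = config$nTreesSelection,
                         mtry = max(1L, floor(config$mtryFraction * ncol(x))),
                         min.node.size = config$nodeSize,
                         importance = "impurity", seed = seed,
                         num.threads = 1L, verbose = FALSE)
    rf$variable.importance
}

#' Stage 1: gene importance ranking and selection
#'
#' Trains one all-classes forest and one one-vs-rest forest per class on
#' within-sample-ranked raw data and keeps the top `genesPerModel` genes of
#' each by impurity importance. The one-vs-rest supplementation exists
#' because genes identifying smaller classes may not reach the very top of
#' the all-classes ranking. The union is deduplicated with provenance
#' (all-classes model first, then per-class models).
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param config an [rfConfig()].
#' @return list with `genes` (character union), `importance` (long
#'   data.frame: model, gene, importance, rank) and `perModelTop`.
#' @export
stage1SelectGenes <- function(cohort, config = rfConfig()) {
    lab <- requireLabels(cohort)
    classes <- sort(unique(lab))
    G <- min(config$genesPerModel, nrow(cohort))
    if (config$genesPerModel > nrow(cohort))
        warning("genesPerModel exceeds gene count; using all genes")
    x <- t(rankTransform(exprValues(cohort)))
    models <- c("all", classes)
    impRows <- perModelTop <- list()
    for (i in seq_along(models)) {
        mod <- models[i]
        y <- if (mod == "all") factor(lab)
             else factor(ifelse(lab == mod, mod, ".rest"))
        imp <- selectionForestImportance(x, y, config, seed = config$seed + i)
        top <- names(sort(imp, decreasing = TRUE))[seq_len(G)]
        perModelTop[[mod]] <- top
        impRows[[mod]] <- data.frame(model = mod, gene = names(imp),
                                     importance = unname(imp),
                                     rank = rank(-imp, ties.method = "first"),
                                     stringsAsFactors = FALSE)
    }
    list(genes = unique(unlist(perModelTop, use.names = FALSE)),
         importance = do.call(rbind, impRows), perModelTop = perModelTop)
}

#' Stage 2: rule importance ranking
#'
#' Enumerates all unordered pairs of the stage-1 gene union, binarizes
#' them, and repeats the all-classes + one-vs-rest forest training with the
#' rules as features, recording per-rule impurity importance per model.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param genes stage-1 gene union.
#' @param config an [rfConfig()].
#' @return list with `rules` (data.frame geneA/geneB), `ruleMat`
#'   ([RuleMatrix-class]) and `importance` (rules-by-models matrix).
#' @export
stage2RankRules <- function(cohort, genes, config = rfConfig()) {
    lab <- requireLabels(cohort)
    classes <- sort(unique(lab))
    rules <- enumerateRules(genes)
    ruleMat <- binarizeRules(cohort, rules)
    x <- t(ruleValues(ruleMat))
    colnames(x) <- sprintf("r%05d", seq_len(nrow(rules)))
    models <- c("all", classes)
    imp <- matrix(NA_real_, nrow(rules), length(models),
                  dimnames = list(rownames(ruleValues(ruleMat)), models))
    for (i in seq_along(models)) {
        mod <- models[i]
        y <- if (mod == "all") factor(lab)
             else factor(ifelse(lab == mod, mod, ".rest"))
        imp[, mod] <- selectionForestImportance(x, y, config,
                                                seed = config$seed + 100L + i)
    }
    list(rules = rules, ruleMat = ruleMat, importance = imp)
}

#' Per-gene rule diversification filter
#'
#' Within each model's descending importance ranking, a rule is kept only
#' while neither of its genes has already been kept `geneRepetition` times
#' in that ranking, avoiding reliance on many rules sharing one informative
#' partner gene.
#'
#' @param importance rules-by-models importance matrix.
#' @param rules data.frame (geneA, geneB) aligned with `importance` rows.
#' @param geneRepetition max kept rules per gene per ranking (Inf =
#'   identity filter).
#' @return list per model of kept rule indices in importance order.
#' @export
diversifyRules <- function(importance, rules, geneRepetition = 1L) {
    lapply(stats::setNames(colnames(importance), colnames(importance)),
           function(mod) {
        ord <- order(-importance[, mod])
        cnt <- new.env(parent = emptyenv())
        keep <- integer(0)
        for (i in ord) {
            a <- rules$geneA[i]; b <- rules$geneB[i]
            ca <- get0(a, cnt, ifnotfound = 0L); cb <- get0(b, cnt, ifnotfound = 0L)
            if (ca < geneRepetition && cb < geneRepetition) {
                keep <- c(keep, i)
                assign(a, ca + 1L, cnt); assign(b, cb + 1L, cnt)
            }
        }
        keep
    })
}

# Fit the final probability forest on a rules x samples 0/1 matrix.
finalForestFit <- function(ruleVals, lab, config) {
    x <- as.data.frame(t(ruleVals))
    colnames(x) <- sprintf("r%05d", seq_len(nrow(ruleVals)))
    y <- factor(lab)
    rf <- ranger::ranger(x = x, y = y, probability = TRUE,
                         num.trees = config$nTreesFinal,
                         mtry = max(1L, floor(sqrt(nrow(ruleVals)))),
                         min.node.size = config$nodeSize,
                         importance = "impurity", keep.inbag = TRUE,
                         seed = config$seed + 999L, num.threads = 1L,
                         verbose = FALSE)
    oob <- rf$predictions    # OOB class probabilities; NaN if never OOB
    rownames(oob) <- colnames(ruleVals)
    ok <- stats::complete.cases(oob) & !apply(oob, 1L, function(r) any(is.nan(r)))
    pred <- colnames(oob)[max.col(oob[ok, , drop = FALSE], ties.method = "first")]
    list(forest = rf, oobScores = oob, oobAccuracy = mean(pred == lab[ok]))
}

#' Stage 3: train the final probability forest
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param rules data.frame (geneA, geneB) of the retained rules.
#' @param config an [rfConfig()].
#' @return an [RFRulesModel-class] (stage-1/stage-2 slots empty; use
#'   [trainRFRules()] for the full pipeline).
#' @export
trainFinalForest <- function(cohort, rules, config = rfConfig()) {
    lab <- requireLabels(cohort)
    ruleMat <- binarizeRules(cohort, rules)
    fit <- finalForestFit(ruleValues(ruleMat), lab, config)
    methods::new("RFRulesModel", classes = sort(unique(lab)),
                 stage1 = list(), stage2 = list(),
                 rules = ruleInfo(ruleMat), forest = fit$forest,
                 trainRuleValues = ruleValues(ruleMat),
                 trainLabels = unname(lab), oobScores = fit$oobScores,
                 oobAccuracy = fit$oobAccuracy, config = config)
}

#' Train the complete three-stage rule-based Random Forest pipeline
#'
#' (i) gene importance ranking and selection on ranked raw data
#' ([stage1SelectGenes()]); (ii) rule importance ranking on the binarized
#' pairs of the gene union ([stage2RankRules()]); (iii) per-gene
#' diversification filtering ([diversifyRules()]), selection of the top
#' `rulesPerModel` filtered rules from each model, and training of a final
#' probability forest whose out-of-bag votes give training scores. During
#' training roughly 37% of samples are left out of each tree's bootstrap,
#' so with 5000 trees each sample is out-of-bag for about 1850 of them.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param config an [rfConfig()].
#' @return an [RFRulesModel-class].
#' @export
trainRFRules <- function(cohort, config = rfConfig()) {
    s1 <- stage1SelectGenes(cohort, config)
    s2 <- stage2RankRules(cohort, s1$genes, config)
    filt <- diversifyRules(s2$importance, s2$rules, config$geneRepetition)
    selIdx <- unique(unlist(lapply(filt, function(k)
        utils::head(k, config$rulesPerModel)), use.names = FALSE))
    if (any(vapply(filt, length, 1L) < config$rulesPerModel))
        warning("fewer than rulesPerModel filtered rules for some model; using all")
    rules <- s2$rules[selIdx, , drop = FALSE]
    rownames(rules) <- NULL
    model <- trainFinalForest(cohort, rules, config)
    model@stage1 <- s1
    model@stage2 <- list(importance = s2$importance, filtered = filt)
    model
}

# Rule values for new data given a model; rules whose genes are absent
# become NA rows (to be imputed).
ruleValuesForData <- function(m, rules) {
    present <- rules$geneA %in% rownames(m) & rules$geneB %in% rownames(m)
    v <- matrix(NA_real_, nrow(rules), ncol(m),
                dimnames = list(paste0(rules$geneA, ">", rules$geneB),
                                colnames(m)))
    if (any(present)) {
        sub <- rules[present, , drop = FALSE]
        v[present, ] <- (m[sub$geneA, , drop = FALSE] >
                         m[sub$geneB, , drop = FALSE]) * 1
    }
    v
}

#' Impute missing rule values by k-nearest training neighbours
#'
#' For each sample, Hamming similarity to the retained training samples is
#' computed over the evaluable rules only (pairwise-complete; genes are
#' never imputed, rules are). Each missing rule is filled with the modal
#' value among the `k` most similar training samples, mode ties broken by
#' the single most similar neighbour's value.
#'
#' @param ruleVals rules-by-samples matrix with NA for unevaluable rules.
#' @param model an [RFRulesModel-class] (supplies the training matrix).
#' @param k neighbours (default 5; `k = 1` is a nearest-neighbour copy).
#' @return completed 0/1 matrix.
#' @export
imputeMissingRules <- function(ruleVals, model, k = 5L) {
    tr <- model@trainRuleValues
    k <- min(k, ncol(tr))
    for (j in seq_len(ncol(ruleVals))) {
        miss <- is.na(ruleVals[, j])
        if (!any(miss)) next
        ev <- which(!miss)
        if (!length(ev)) stop("sample ", colnames(ruleVals)[j],
                              " has no evaluable rules")
        sim <- colMeans(tr[ev, , drop = FALSE] == ruleVals[ev, j])
        nb <- order(-sim)[seq_len(k)]
        frac <- rowMeans(tr[miss, nb, drop = FALSE])
        fill <- ifelse(frac > 0.5, 1, ifelse(frac < 0.5, 0, tr[miss, nb[1L]]))
        ruleVals[miss, j] <- fill
    }
    ruleVals
}

#' @describeIn predictSamples Rule-based Random Forest prediction: scores
#'   are forest-averaged class probabilities (summing to 1). Rules whose
#'   genes are missing from `x` are imputed via [imputeMissingRules()];
#'   more than `maxMissingRules` unevaluable rules is refused.
#' @param imputeK neighbours for missing-rule imputation (RF method).
#' @param maxMissingRules maximum tolerated fraction of unevaluable rules
#'   (RF method; default 0.5).
#' @export
setMethod("predictSamples", "RFRulesModel", function(object, x, imputeK = 5L,
                                                     maxMissingRules = 0.5, ...) {
    m <- asExprMatrix(x)
    v <- ruleValuesForData(m, object@rules)
    missFrac <- mean(is.na(v[, 1L]))
    if (missFrac > maxMissingRules)
        stop(round(missFrac * 100), "% of rules unevaluable (limit ",
             maxMissingRules * 100, "%); refusing to predict")
    if (missFrac > 0) v <- imputeMissingRules(v, object, k = imputeK)
    newdat <- as.data.frame(t(v))
    colnames(newdat) <- sprintf("r%05d", seq_len(nrow(v)))
    sc <- stats::predict(object@forest, data = newdat,
                         num.threads = 1L)$predictions
    rownames(sc) <- colnames(m)
    newPredictionResult(sc, method = "rf-rules")
})

#' Shadow-feature pruning of a rule forest
#'
#' Iteratively augments the rule matrix with per-column permuted "shadow"
#' copies, retrains a forest, and counts for each rule the iterations in
#' which its importance beats the best shadow. A two-sided binomial test at
#' `alpha` labels rules confirmed (significantly more hits than chance),
#' rejected (significantly fewer; removed from subsequent iterations) or
#' tentative (undecided at `maxIter`). The final forest is rebuilt on the
#' confirmed (plus, optionally, tentative) rules.
#'
#' @param model a trained [RFRulesModel-class].
#' @param maxIter maximum iterations (default 50).
#' @param alpha significance level of the binomial test (default 0.01).
#' @param includeTentative keep tentative rules in the rebuilt model.
#' @param seed permutation seed.
#' @return list with `result` ([BorutaResult-class]) and `model` (pruned
#'   [RFRulesModel-class]).
#' @export
borutaPrune <- function(model, maxIter = 50L, alpha = 0.01,
                        includeTentative = TRUE, seed = 1L) {
    v <- model@trainRuleValues
    lab <- model@trainLabels
    config <- model@config
    nR <- nrow(v)
    status <- rep("tentative", nR)
    hits <- iters <- integer(nR)
    withSeed(seed, {
        for (it in seq_len(maxIter)) {
            undec <- which(status == "tentative")
            if (!length(undec)) break
            live <- which(status != "rejected")
            x <- t(v[live, , drop = FALSE])
            shadow <- apply(x, 2L, sample)
            xs <- cbind(x, shadow)
            colnames(xs) <- c(sprintf("f%05d", live),
                              sprintf("s%05d", seq_along(live)))
            rf <- ranger::ranger(x = xs, y = factor(lab),
                                 num.trees = config$borutaTrees,
                                 mtry = max(1L, floor(sqrt(ncol(xs)))),
                                 min.node.size = config$nodeSize,
                                 importance = "impurity",
                                 seed = config$seed + 2000L + it,
                                 num.threads = 1L, verbose = FALSE)
            imp <- rf$variable.importance
            shadowMax <- max(imp[grepl("^s", names(imp))])
            realImp <- imp[sprintf("f%05d", undec)]
            hit <- realImp > shadowMax
            hits[undec] <- hits[undec] + hit
            iters[undec] <- iters[undec] + 1L
            if (it >= 5L) {
                for (r in undec) {
                    pHigh <- stats::pbinom(hits[r] - 1L, iters[r], 0.5,
                                           lower.tail = FALSE)
                    pLow <- stats::pbinom(hits[r], iters[r], 0.5)
                    if (pHigh < alpha / 2) status[r] <- "confirmed"
                    else if (pLow < alpha / 2) status[r] <- "rejected"
                }
            }
        }
    })
    result <- methods::new("BorutaResult",
        status = factor(status, levels = c("confirmed", "tentative", "rejected")),
        hits = hits, iterations = iters)
    keep <- status == "confirmed" | (includeTentative & status == "tentative")
    if (!any(keep)) { warning("no rules retained; keeping the best-hit rule")
                      keep[which.max(hits)] <- TRUE }
    fit <- finalForestFit(v[keep, , drop = FALSE], lab, config)
    pruned <- methods::new("RFRulesModel", classes = model@classes,
                           stage1 = model@stage1, stage2 = model@stage2,
                           rules = model@rules[keep, , drop = FALSE],
                           forest = fit$forest,
                           trainRuleValues = v[keep, , drop = FALSE],
                           trainLabels = lab, oobScores = fit$oobScores,
                           oobAccuracy = fit$oobAccuracy, config = config)
    list(result = result, model = pruned)
}

#' Extract the out-of-bag proximity matrix of a rule forest
#'
#' Entry (i, j) is the fraction of trees, among those where both samples
#' are out-of-bag, in which the two samples land in the same terminal
#' node; the diagonal is 1 by convention. Pairs never jointly out-of-bag
#' are NA. High proximity indicates samples the forest treats as
#' interchangeable, flagging reference-label cohesiveness and candidate
#' mislabeled samples.
#'
#' @param model a trained [RFRulesModel-class].
#' @return symmetric samples-by-samples matrix in [0, 1] (NA = undefined).
#' @export
extractProximity <- function(model) {
    v <- model@trainRuleValues
    x <- as.data.frame(t(v))
    colnames(x) <- sprintf("r%05d", seq_len(nrow(v)))
    term <- stats::predict(model@forest, data = x, type = "terminalNodes",
                           num.threads = 1L)$predictions
    inbag <- do.call(cbind, model@forest$inbag.counts)   # samples x trees
    oob <- inbag == 0L
    n <- ncol(v)
    bothOOB <- oob %*% t(oob)
    same <- matrix(0, n, n)
    for (t in seq_len(ncol(term))) {
        idx <- which(oob[, t])
        if (length(idx) < 2L) next
        byNode <- split(idx, term[idx, t])
        for (grp in byNode) if (length(grp) > 1L)
            same[grp, grp] <- same[grp, grp] + 1
    }
    prox <- same / bothOOB
    prox[bothOOB == 0] <- NA_real_
    diag(prox) <- 1
    dimnames(prox) <- list(colnames(v), colnames(v))
    prox
}
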