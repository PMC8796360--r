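#' @include AllClasses.R pair_rules.R
NULL

#' k-TSP configuration
#'
#' Defaults follow the classic multiclass k-TSP setup: the top 50 up- and
#' 50 downregulated genes per class by one-vs-rest Wilcoxon statistic, and
#' the number of rules chosen in 2..10 by variance optimization. Expanded
#' budgets (500 genes, k up to 50), pivot genes, one-vs-one selection or
#' scoring and platform-wise selection/scoring are opted in per flag.
#'
#' @param nGenesPerDirection genes per direction entering the pair pool.
#' @param kRange candidate rule counts for variance optimization.
#' @param fixedK fixed rule count overriding `kRange` (NULL = optimize).
#' @param pivotGenes also pair pool genes with all remaining training genes,
#'   letting a non-differential gene act as a pivot point.
#' @param geneSelectionMode `"one_vs_rest"` or `"one_vs_one"` Wilcoxon
#'   gene ranking.
#' @param ruleScoringMode `"one_vs_rest"` or `"one_vs_one"` (worst-case
#'   aggregation across opposing classes) rule scoring.
#' @param platformWise perform gene selection and rule scoring per platform,
#'   keeping genes/scores that hold on every platform (worst-case).
#' @return list of class-free config values for [trainKTSP()].
#' @export
ktspConfig <- function(nGenesPerDirection = 50L, kRange = 2:10, fixedK = NULL,
                       pivotGenes = FALSE,
                       geneSelectionMode = c("one_vs_rest", "one_vs_one"),
                       ruleScoringMode = c("one_vs_rest", "one_vs_one"),
                       platformWise = FALSE) {
    stopifnot(min(kRange) >= 1L)
    list(nGenesPerDirection = as.integer(nGenesPerDirection),
         kRange = as.integer(kRange),
         fixedK = if (!is.null(fixedK)) as.integer(fixedK),
         pivotGenes = isTRUE(pivotGenes),
         geneSelectionMode = match.arg(geneSelectionMode),
         ruleScoringMode = match.arg(ruleScoringMode),
         platformWise = isTRUE(platformWise))
}

# Standardized Wilcoxon rank-sum z per gene for target-vs-comparison
# samples (rows = genes). Positive z = upregulated in the target group.
wilcoxZ <- function(expr, inT, inC) {
    sub <- expr[, c(which(inT), which(inC)), drop = FALSE]
    ranks <- t(apply(sub, 1L, rank, ties.method = "average"))
    n1 <- sum(inT); n0 <- sum(inC); n <- n1 + n0
    W <- rowSums(ranks[, seq_len(n1), drop = FALSE])
    (W - n1 * (n + 1) / 2) / sqrt(n1 * n0 * (n + 1) / 12)
}

#' Wilcoxon gene selection for one k-TSP voter
#'
#' Ranks genes by a one-vs-rest Wilcoxon rank-sum statistic (or, in
#' one-vs-one mode, by the worst-case statistic across all opposing
#' classes) and returns the top `n` up- and downregulated genes. In
#' platform-wise mode the statistic is computed within each platform and
#' aggregated by its worst case across platforms, so only genes
#' differential on every platform rank highly.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param target target class.
#' @param n genes per direction.
#' @param mode `"one_vs_rest"` or `"one_vs_one"`.
#' @param platformWise aggregate per-platform statistics by worst case.
#' @return list with `up`, `down` (character) and `stat` (named numeric,
#'   the aggregated signed statistic).
#' @export
selectGenesWilcoxon <- function(cohort, target, n = 50L,
                                mode = c("one_vs_rest", "one_vs_one"),
                                platformWise = FALSE) {
    mode <- match.arg(mode)
    stopifnot(n >= 1L)
    lab <- requireLabels(cohort)
    if (!target %in% lab) stop("target class '", target, "' absent")
    expr <- exprValues(cohort)
    plats <- if (platformWise) platformLabels(cohort) else NULL
    platSet <- if (is.null(plats)) list(rep(TRUE, length(lab)))
               else lapply(unique(plats), function(p) plats == p)
    parts <- list()
    for (sel in platSet) {
        inT <- sel & lab == target
        others <- if (mode == "one_vs_rest") list(sel & lab != target)
                  else lapply(setdiff(unique(lab), target),
                              function(o) sel & lab == o)
        for (inC in others) {
            if (!any(inT) || !any(inC)) next
            parts[[length(parts) + 1L]] <- wilcoxZ(expr, inT, inC)
        }
    }
    if (!length(parts)) stop("no usable comparison groups")
    zmat <- do.call(cbind, parts)
    upScore <- apply(zmat, 1L, min)    # worst case across comparisons
    dnScore <- apply(zmat, 1L, max)
    stat <- ifelse(abs(upScore) >= abs(dnScore), upScore, dnScore)
    names(stat) <- rownames(expr)
    up <- rownames(expr)[order(upScore, decreasing = TRUE)][seq_len(min(n, nrow(expr)))]
    down <- rownames(expr)[order(dnScore)][seq_len(min(n, nrow(expr)))]
    list(up = up, down = setdiff(down, up)[seq_len(min(n, length(setdiff(down, up))))],
         stat = stat)
}

# Signed delta of every rule aggregated worst-case over the comparison
# units implied by the scoring mode / platform-wise flag. Positive values
# mean the rule (as oriented) favors the target class in *every* unit.
aggregateSignedDelta <- function(ruleMat, lab, target, mode, platformWise, plats) {
    platSet <- if (platformWise && !is.null(plats))
        lapply(unique(plats), function(p) plats == p) else list(rep(TRUE, length(lab)))
    parts <- list()
    for (sel in platSet) {
        others <- if (mode == "one_vs_rest") list("rest")
                  else as.list(setdiff(unique(lab), target))
        for (o in others) {
            inT <- sel & lab == target
            inC <- if (identical(o, "rest")) sel & lab != target else sel & lab == o
            if (!any(inT) || !any(inC)) next
            v <- ruleValues(ruleMat)
            parts[[length(parts) + 1L]] <-
                rowMeans(v[, inT, drop = FALSE]) - rowMeans(v[, inC, drop = FALSE])
        }
    }
    pm <- do.call(cbind, parts)
    sPlus <- apply(pm, 1L, min)
    sMinus <- apply(-pm, 1L, min)
    ifelse(sPlus >= sMinus, pmax(sPlus, 0), -pmax(sMinus, 0))
}

# Build one binary (one-vs-rest) k-TSP voter. Returns list(rules, k).
buildBinaryKTSP <- function(cohort, target, config, rankedExpr) {
    lab <- classLabels(cohort)
    plats <- platformLabels(cohort)
    pool <- selectGenesWilcoxon(cohort, target, config$nGenesPerDirection,
                                mode = config$geneSelectionMode,
                                platformWise = config$platformWise)
    poolGenes <- unique(c(pool$up, pool$down))
    cand <- enumerateRules(poolGenes)
    if (config$pivotGenes) {
        rest <- setdiff(rownames(cohort), poolGenes)
        if (length(rest))
            cand <- unique(rbind(cand, enumerateRules(poolGenes, rest)))
    }
    rm <- binarizeRules(cohort, cand)
    signed <- aggregateSignedDelta(rm, lab, target, config$ruleScoringMode,
                                   config$platformWise, plats)
    gammaDf <- scoreRulesForClass(rm, lab, target, rankedExpr = rankedExpr)
    cand$delta <- abs(signed)
    cand$gamma <- gammaDf$gamma
    # orient so TRUE indicates the target class
    flip <- signed < 0
    tmp <- cand$geneA[flip]; cand$geneA[flip] <- cand$geneB[flip]; cand$geneB[flip] <- tmp
    ord <- order(-cand$delta, -cand$gamma, cand$geneA, cand$geneB)
    cand <- cand[ord, , drop = FALSE]
    maxK <- config$fixedK %||% max(config$kRange)
    used <- character(0); keep <- integer(0)
    for (i in seq_len(nrow(cand))) {
        if (length(keep) >= maxK) break
        g <- c(cand$geneA[i], cand$geneB[i])
        if (!any(g %in% used)) { keep <- c(keep, i); used <- c(used, g) }
    }
    rules <- cand[keep, c("geneA", "geneB", "delta", "gamma"), drop = FALSE]
    rownames(rules) <- NULL
    if (!is.null(config$fixedK)) {
        if (nrow(rules) < config$fixedK)
            warning("class ", target, ": only ", nrow(rules), " disjoint rules for k = ",
                    config$fixedK)
        return(list(rules = rules, k = nrow(rules)))
    }
    # variance optimization: standardized separation of the vote sums
    rv <- ruleValues(binarizeRules(cohort, rules))
    inT <- lab == target
    kGrid <- config$kRange[config$kRange <= nrow(rules)]
    if (!length(kGrid)) kGrid <- nrow(rules)
    crit <- vapply(kGrid, function(k) {
        votes <- colSums(rv[seq_len(k), , drop = FALSE])
        d <- abs(mean(votes[inT]) - mean(votes[!inT]))
        n1 <- sum(inT); n0 <- sum(!inT)
        sp <- sqrt(((n1 - 1) * stats::var(votes[inT]) +
                    (n0 - 1) * stats::var(votes[!inT])) / (n1 + n0 - 2))
        if (sp == 0) ifelse(d > 0, Inf, 0) else d / sp
    }, numeric(1))
    k <- kGrid[which.max(crit)]
    list(rules = rules[seq_len(k), , drop = FALSE], k = k)
}

#' Train a multiclass one-vs-rest k-TSP predictor
#'
#' One binary k-TSP voter per class: Wilcoxon gene selection, TSP scoring
#' of all candidate pairs (delta primary, rank-difference gamma breaking
#' delta ties), greedy selection of top pairs with disjoint genes, and rule
#' count chosen by variance optimization (standardized separation of the
#' training vote sums over `kRange`) unless `fixedK` is set. The chosen k
#' may differ across classes.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param config a [ktspConfig()].
#' @return a [KTSPModel-class].
#' @export
trainKTSP <- function(cohort, config = ktspConfig()) {
    lab <- requireLabels(cohort)
    classes <- sort(unique(lab))
    rankedExpr <- colRanks(exprValues(cohort))
    voters <- lapply(classes, function(cl)
        buildBinaryKTSP(cohort, cl, config, rankedExpr))
    names(voters) <- classes
    methods::new("KTSPModel", classes = classes,
                 rules = lapply(voters, `[[`, "rules"),
                 k = vapply(voters, function(v) as.integer(v$k), integer(1)),
                 config = config)
}

#' @describeIn predictSamples k-TSP prediction: each class voter scores a
#'   sample as the fraction of its rules that are TRUE; the highest vote
#'   fraction decides the call. Scores live on the grid 0, 1/k, ..., 1, so
#'   exact ties can occur and are flagged. Missing genes are an error (this
#'   predictor family does no imputation).
#' @export
setMethod("predictSamples", "KTSPModel", function(object, x, ...) {
    m <- asExprMatrix(x)
    sc <- vapply(object@classes, function(cl) {
        rv <- ruleValues(binarizeRules(m, object@rules[[cl]]))
        colMeans(rv)
    }, numeric(ncol(m)))
    sc <- matrix(sc, ncol = length(object@classes),
                 dimnames = list(colnames(m), object@classes))
    newPredictionResult(sc, method = "ktsp")
})

# Truncate a trained voter set to a smaller fixed k (greedy lists are
# prefix-stable, so this equals retraining with fixedK = k).
truncateKTSP <- function(model, k) {
    rules <- lapply(model@rules, function(r)
        r[seq_len(min(k, nrow(r))), , drop = FALSE])
    methods::new("KTSPModel", classes = model@classes, rules = rules,
                 k = vapply(rules, nrow, 1L), config = model@config)
}

#' Tied-score prevalence across fixed rule counts
#'
#' Forces every class voter to a fixed number of rules k over a grid,
#' predicts a held-out split and reports the fraction of samples whose top
#' score is tied. Vote-fraction ties are prevalent at small k and decline
#' as k grows.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param kValues fixed rule counts to examine.
#' @param reps repetitions (fresh stratified splits) averaged per k.
#' @param trainFraction train proportion per split.
#' @param config base [ktspConfig()]; `fixedK` is overridden.
#' @param seed split seed base.
#' @return data.frame (k, tieRate, accuracy).
#' @export
tieSweep <- function(cohort, kValues = c(2L, 5L, 10L, 25L, 50L), reps = 1L,
                     trainFraction = 0.8, config = ktspConfig(), seed = 1L) {
    kValues <- sort(unique(as.integer(kValues)))
    acc <- tie <- matrix(NA_real_, length(kValues), reps)
    for (r in seq_len(reps)) {
        sp <- stratifiedSplit(cohort, trainFraction, seed = seed + r - 1L)
        cfg <- config; cfg$fixedK <- max(kValues)
        full <- suppressWarnings(trainKTSP(sp$train, cfg))
        lab <- classLabels(sp$test)
        for (i in seq_along(kValues)) {
            pr <- predictSamples(truncateKTSP(full, kValues[i]), sp$test)
            tie[i, r] <- mean(tieFlag(pr))
            acc[i, r] <- mean(predictedClass(pr) == lab)
        }
    }
    data.frame(k = kValues, tieRate = rowMeans(tie), accuracy = rowMeans(acc))
}
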