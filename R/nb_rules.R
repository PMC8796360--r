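#' @include AllClasses.R pair_rules.R
NULL

#' Naive-Bayes-on-rules configuration
#'
#' @param kRange candidate per-class rule counts (default 1..50).
#' @param cvFolds stratified cross-validation folds for choosing k
#'   (default 20).
#' @param datasetWeights optional named positive weights per training
#'   dataset; rule deltas are then computed per dataset and averaged with
#'   these weights, damping the influence of large datasets.
#' @param candidateGeneCap guard on exhaustive pair enumeration: above this
#'   gene count the input is pre-filtered to the cap by one-vs-rest
#'   Wilcoxon statistics (logged).
#' @param alpha additive (Laplace) smoothing on the Bernoulli conditionals.
#' @param seed fold-assignment seed.
#' @return config list for [trainNBRules()].
#' @export
nbRulesConfig <- function(kRange = 1:50, cvFolds = 20L, datasetWeights = NULL,
                          candidateGeneCap = 300L, alpha = 1, seed = 1L) {
    stopifnot(cvFolds >= 2L, is.null(datasetWeights) || all(datasetWeights > 0))
    list(kRange = as.integer(kRange), cvFolds = as.integer(cvFolds),
         datasetWeights = datasetWeights,
         candidateGeneCap = as.integer(candidateGeneCap),
         alpha = alpha, seed = as.integer(seed))
}

# Per-class rule ranking on a training subset: returns for each class an
# integer vector ordering candidate rules by (delta desc, list order), plus
# the signed deltas (for orientation).
rankRulesPerClass <- function(ruleMat, lab, classes, datasets, weights) {
    lapply(stats::setNames(classes, classes), function(cl) {
        sc <- scoreRulesForClass(ruleMat, lab, cl,
                                 groups = if (!is.null(weights)) datasets,
                                 weights = weights)
        list(order = order(-sc$delta), signed = sc$signed)
    })
}

nbFit <- function(ruleVals, lab, classes, alpha) {
    priors <- table(factor(lab, levels = classes)) / length(lab)
    cond <- vapply(classes, function(cl) {
        sel <- lab == cl
        (rowSums(ruleVals[, sel, drop = FALSE]) + alpha) / (sum(sel) + 2 * alpha)
    }, numeric(nrow(ruleVals)))
    cond <- matrix(cond, nrow = nrow(ruleVals),
                   dimnames = list(rownames(ruleVals), classes))
    list(priors = as.numeric(priors), cond = cond)
}

nbPosterior <- function(fit, ruleVals, classes) {
    lp <- vapply(seq_along(classes), function(j) {
        p <- fit$cond[, j]
        log(fit$priors[j]) +
            colSums(ruleVals * log(p) + (1 - ruleVals) * log(1 - p))
    }, numeric(ncol(ruleVals)))
    lp <- matrix(lp, ncol = length(classes),
                 dimnames = list(colnames(ruleVals), classes))
    post <- exp(lp - apply(lp, 1L, max))
    post / rowSums(post)
}

#' Train a Naive-Bayes-on-rules predictor
#'
#' All gene pairs are enumerated (pre-filtered above `candidateGeneCap`
#' genes) and scored per class by one-vs-rest delta (per-dataset weighted
#' average when `datasetWeights` is given). The per-class rule count k —
#' the *same* k for every class — is chosen at the peak mean overall
#' accuracy of a stratified `cvFolds`-fold cross-validation over `kRange`
#' (smallest k on exact ties), after which the model is refit on all data:
#' class-proportion priors and Laplace-smoothed Bernoulli conditionals for
#' the top-k rules of every class.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param config an [nbRulesConfig()].
#' @return an [NBRulesModel-class].
#' @export
trainNBRules <- function(cohort, config = nbRulesConfig()) {
    lab <- requireLabels(cohort)
    classes <- sort(unique(lab))
    datasets <- datasetLabels(cohort)
    weights <- config$datasetWeights
    if (!is.null(weights) && is.null(datasets))
        stop("datasetWeights given but cohort has no dataset labels")
    genes <- rownames(cohort)
    if (length(genes) > config$candidateGeneCap) {
        message("trainNBRules: pre-filtering ", length(genes), " genes to ",
                config$candidateGeneCap, " by one-vs-rest Wilcoxon statistic")
        per <- ceiling(config$candidateGeneCap / (2L * length(classes)))
        keep <- unique(unlist(lapply(classes, function(cl) {
            s <- selectGenesWilcoxon(cohort, cl, per)
            c(s$up, s$down)
        })))
        genes <- utils::head(keep, config$candidateGeneCap)
    }
    rules <- enumerateRules(genes)
    ruleMat <- binarizeRules(cohort, rules)
    v <- ruleValues(ruleMat)
    nFolds <- min(config$cvFolds, ncol(v))
    folds <- withSeed(config$seed, {
        f <- integer(length(lab))
        for (cl in classes) {
            idx <- sample(which(lab == cl))
            f[idx] <- rep_len(seq_len(nFolds), length(idx))
        }
        f
    })
    kGrid <- config$kRange[config$kRange <= nrow(rules)]
    if (!length(kGrid)) { warning("kRange exceeds rule count; truncating")
                          kGrid <- nrow(rules) }
    accSum <- accN <- stats::setNames(numeric(length(kGrid)), kGrid)
    for (f in seq_len(nFolds)) {
        tr <- folds != f; te <- !tr
        if (!any(te) || length(unique(lab[tr])) < length(classes)) next
        trMat <- methods::new("RuleMatrix", rules = rules,
                              values = v[, tr, drop = FALSE])
        ranking <- rankRulesPerClass(trMat, lab[tr], classes, datasets[tr], weights)
        for (j in seq_along(kGrid)) {
            sel <- unique(unlist(lapply(ranking, function(r)
                r$order[seq_len(kGrid[j])])))
            fit <- nbFit(v[sel, tr, drop = FALSE], lab[tr], classes, config$alpha)
            post <- nbPosterior(fit, v[sel, te, drop = FALSE], classes)
            pred <- classes[max.col(post, ties.method = "first")]
            accSum[j] <- accSum[j] + sum(pred == lab[te])
            accN[j] <- accN[j] + sum(te)
        }
    }
    cvCurve <- data.frame(k = kGrid, accuracy = accSum / accN)
    bestK <- kGrid[which.max(cvCurve$accuracy)]   # smallest k on exact ties
    ranking <- rankRulesPerClass(ruleMat, lab, classes, datasets, weights)
    selRows <- lapply(classes, function(cl) ranking[[cl]]$order[seq_len(bestK)])
    selIdx <- unique(unlist(selRows))
    selRules <- rules[selIdx, , drop = FALSE]
    selRules$targetClass <- vapply(selIdx, function(i)
        classes[which(vapply(selRows, function(s) i %in% s, logical(1)))[1L]],
        character(1))
    selRules$delta <- NA_real_
    for (cl in classes) {
        hit <- selIdx %in% ranking[[cl]]$order[seq_len(bestK)] &
               selRules$targetClass == cl
        selRules$delta[hit] <- abs(ranking[[cl]]$signed[selIdx[hit]])
    }
    # orient rules TRUE -> target class (complement symmetry of the NB)
    selVals <- v[selIdx, , drop = FALSE]
    for (i in seq_along(selIdx)) {
        s <- ranking[[selRules$targetClass[i]]]$signed[selIdx[i]]
        if (!is.na(s) && s < 0) {
            tmp <- selRules$geneA[i]
            selRules$geneA[i] <- selRules$geneB[i]; selRules$geneB[i] <- tmp
            selVals[i, ] <- 1L - selVals[i, ]
        }
    }
    rownames(selRules) <- rownames(selVals) <- paste0(selRules$geneA, ">",
                                                      selRules$geneB)
    fit <- nbFit(selVals, lab, classes, config$alpha)
    methods::new("NBRulesModel", classes = classes, rules = selRules,
                 k = as.integer(bestK),
                 priors = stats::setNames(fit$priors, classes),
                 condProb = fit$cond, cvCurve = cvCurve, config = config)
}

#' @describeIn predictSamples Naive-Bayes-on-rules prediction: scores are
#'   the normalized posterior probabilities (class-proportion priors times
#'   the product of Bernoulli conditionals of the selected rule values);
#'   posteriors sum to 1 per sample and tend to extremes even for
#'   out-of-distribution samples.
#' @export
setMethod("predictSamples", "NBRulesModel", function(object, x, ...) {
    m <- asExprMatrix(x)
    rv <- ruleValues(binarizeRules(m, object@rules))
    post <- nbPosterior(list(priors = object@priors, cond = object@condProb),
                        rv, object@classes)
    newPredictionResult(post, method = "nb-rules")
})
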