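#' @include AllClasses.R
NULL

#' Evaluate predictions against reference labels
#'
#' Reports overall accuracy, per-class recall, the reference-by-predicted
#' confusion matrix, the tie count, the mean top-versus-second margin and
#' (when platforms are supplied) per-platform accuracy. A tied sample
#' counts as correct only when the reference class is the reported
#' (lexicographically first) winner — a conservative convention stated here
#' so the report is auditable.
#'
#' @param pred a [PredictionResult-class].
#' @param reference named (or cohort-ordered) character vector of reference
#'   class labels, or a labeled [ExpressionCohort-class].
#' @param platforms optional per-sample platform labels.
#' @return an [EvalReport-class].
#' @export
evaluatePredictions <- function(pred, reference, platforms = NULL) {
    if (methods::is(reference, "ExpressionCohort")) {
        platforms <- platforms %||% platformLabels(reference)
        reference <- classLabels(reference)
    }
    predLab <- predictedClass(pred)
    if (!is.null(names(reference))) {
        missing <- setdiff(names(predLab), names(reference))
        if (length(missing))
            stop("reference labels missing for sample(s): ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        reference <- reference[names(predLab)]
    } else if (length(reference) != length(predLab)) {
        stop("reference label length does not match predictions")
    }
    levs <- sort(union(reference, predLab))
    conf <- table(reference = factor(reference, levs),
                  predicted = factor(predLab, levs))
    conf <- unclass(conf)
    acc <- sum(diag(conf)) / sum(conf)
    recall <- diag(conf) / rowSums(conf)
    perPlat <- NULL
    if (!is.null(platforms)) {
        perPlat <- vapply(split(seq_along(reference), platforms),
                          function(i) mean(predLab[i] == reference[i]),
                          numeric(1))
        perPlat <- data.frame(platform = names(perPlat), accuracy = unname(perPlat))
    }
    methods::new("EvalReport", accuracy = acc, recall = recall,
                 confusion = conf, tieCount = sum(tieFlag(pred)),
                 meanMargin = mean(scoreMargin(pred)), perPlatform = perPlat)
}

#' Margin summary of a prediction set
#'
#' @param pred a [PredictionResult-class].
#' @return data.frame with one row per predicted class plus an `overall`
#'   row: n, mean and median top-versus-second margin, tie count.
#' @export
marginProfile <- function(pred) {
    m <- scoreMargin(pred); p <- predictedClass(pred); tf <- tieFlag(pred)
    rows <- lapply(split(seq_along(m), p), function(i)
        data.frame(class = p[i][1L], n = length(i), meanMargin = mean(m[i]),
                   medianMargin = stats::median(m[i]), ties = sum(tf[i]),
                   stringsAsFactors = FALSE))
    out <- do.call(rbind, c(rows, list(
        data.frame(class = "overall", n = length(m), meanMargin = mean(m),
                   medianMargin = stats::median(m), ties = sum(tf),
                   stringsAsFactors = FALSE))))
    rownames(out) <- NULL
    out
}

#' Purity-sensitivity curve of a trained predictor
#'
#' For each purity level, a fresh test set is generated from the same
#' synthetic gene universe as the training cohort (same config seed, new
#' sample stream) with every sample fixed at that purity; accuracy and mean
#' margin are recorded. Rule-based predictors, whose features are
#' within-sample comparisons largely internal to the tumor profile, degrade
#' more slowly in low-purity samples than raw-data centroids, whose
#' correlations drift toward the stromal background profile.
#'
#' @param model a trained model accepted by [predictSamples()].
#' @param config the [SyntheticConfig-class] the training cohort came from.
#' @param purityGrid purity levels in (0, 1].
#' @param nPerClassPerPlatform test samples per class per platform.
#' @param sampleSeed sample-stream seed for the test draws.
#' @return data.frame (purity, accuracy, meanMargin).
#' @export
puritySensitivity <- function(model, config, purityGrid = c(1, 0.8, 0.6, 0.5),
                              nPerClassPerPlatform = 10L, sampleSeed = 424242L) {
    out <- lapply(purityGrid, function(pu) {
        sim <- simulateCohort(config, nPerClassPerPlatform = nPerClassPerPlatform,
                              sampleSeed = sampleSeed, fixedPurity = pu)
        pr <- predictSamples(model, sim$cohort)
        data.frame(purity = pu,
                   accuracy = mean(predictedClass(pr) == classLabels(sim$cohort)),
                   meanMargin = mean(scoreMargin(pr)))
    })
    do.call(rbind, out)
}
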