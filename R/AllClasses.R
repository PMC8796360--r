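#' @include AllGenerics.R
NULL

#' ExpressionCohort: genes-by-samples expression data with sample metadata
#'
#' The single input currency of the package: a
#' [SummarizedExperiment::SummarizedExperiment] carrying one assay named
#' `"exprs"` of raw-scale (non-cohort-normalized, typically log2(TPM+1) or
#' log2 array intensity) expression values with genes in rows and samples in
#' columns. Optional per-sample metadata columns `class` (reference label),
#' `platform` and `dataset` live in `colData`. Validity requires unique gene
#' and sample identifiers and all-finite values.
#'
#' A cohort is "labeled" when every sample carries a class label; training
#' functions additionally require at least two samples per class.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @seealso [ExpressionCohort()], [readExpression()], [simulateCohort()]
#' @aliases exprValues classLabels platformLabels datasetLabels
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(v)) msg <- c(msg, "'exprs' must be numeric")
        else if (!all(is.finite(v))) msg <- c(msg, "all expression values must be finite")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if ("class" %in% names(SummarizedExperiment::colData(object))) {
        cl <- SummarizedExperiment::colData(object)$class
        if (anyNA(cl)) msg <- c(msg, "every labeled sample must have exactly one class")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionCohort
#'
#' @param values numeric genes-by-samples matrix with rownames (gene ids)
#'   and colnames (sample ids).
#' @param labels optional per-sample class labels (character/factor,
#'   length = number of samples).
#' @param platform optional per-sample platform labels.
#' @param dataset optional per-sample dataset-of-origin labels.
#' @return an [ExpressionCohort-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ExpressionCohort(m, labels = rep(c("A", "B"), 2))
#' @export
ExpressionCohort <- function(values, labels = NULL, platform = NULL, dataset = NULL) {
    values <- as.matrix(values)
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    if (!is.null(labels))   cd$class    <- as.character(labels)
    if (!is.null(platform)) cd$platform <- as.character(platform)
    if (!is.null(dataset))  cd$dataset  <- as.character(dataset)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd)
    methods::new("ExpressionCohort", se)
}

#' @rdname ExpressionCohort-class
#' @export
setMethod("exprValues", "ExpressionCohort", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExpressionCohort-class
#' @export
setMethod("classLabels", "ExpressionCohort", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"class" %in% names(cd)) return(NULL)
    stats::setNames(as.character(cd$class), colnames(x))
})

#' @rdname ExpressionCohort-class
#' @export
setMethod("platformLabels", "ExpressionCohort", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"platform" %in% names(cd)) return(NULL)
    stats::setNames(as.character(cd$platform), colnames(x))
})

#' @rdname ExpressionCohort-class
#' @export
setMethod("datasetLabels", "ExpressionCohort", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"dataset" %in% names(cd)) return(NULL)
    stats::setNames(as.character(cd$dataset), colnames(x))
})

setMethod("show", "ExpressionCohort", function(object) {
    cat("ExpressionCohort:", nrow(object), "genes x", ncol(object), "samples\n")
    cl <- classLabels(object)
    if (!is.null(cl)) {
        tb <- table(cl)
        cat("  classes:", paste0(names(tb), " (", tb, ")", collapse = ", "), "\n")
    }
    pl <- platformLabels(object)
    if (!is.null(pl)) cat("  platforms:", paste(unique(pl), collapse = ", "), "\n")
    ds <- datasetLabels(object)
    if (!is.null(ds)) cat("  datasets:", paste(unique(ds), collapse = ", "), "\n")
})

#' RuleMatrix: binarized gene-pair rules over samples
#'
#' A gene-pair rule is the binary feature "expression of gene A exceeds
#' expression of gene B within one sample". A `RuleMatrix` holds a rule
#' table (`geneA`, `geneB`, `targetClass`, and where computed the primary
#' TSP score `delta`, the secondary rank-difference score `gamma` and a
#' forest `importance`) together with a rules-by-samples 0/1 value matrix.
#' Exact expression ties evaluate to 0 (strict inequality). Rule values are
#' invariant under per-sample strictly increasing transforms of expression.
#'
#' @slot rules data.frame of rule descriptions.
#' @slot values integer 0/1 matrix, rules in rows, samples in columns.
#' @aliases ruleInfo ruleValues
#' @seealso [binarizeRules()], [enumerateRules()]
#' @export
setClass("RuleMatrix",
    representation(rules = "data.frame", values = "matrix"))

setValidity("RuleMatrix", function(object) {
    msg <- NULL
    r <- object@rules
    if (!all(c("geneA", "geneB") %in% names(r)))
        msg <- c(msg, "rules must have geneA and geneB columns")
    else if (any(r$geneA == r$geneB))
        msg <- c(msg, "geneA and geneB must differ in every rule")
    if (nrow(r) != nrow(object@values))
        msg <- c(msg, "rule table and value matrix disagree in rule count")
    if (length(object@values) && !all(object@values %in% c(0L, 1L)))
        msg <- c(msg, "rule values must be 0/1")
    if ("delta" %in% names(r) && any(!is.na(r$delta) & (r$delta < 0 | r$delta > 1)))
        msg <- c(msg, "delta must lie in [0,1]")
    if (is.null(msg)) TRUE else msg
})

#' @rdname RuleMatrix-class
#' @export
setMethod("ruleInfo", "RuleMatrix", function(x) x@rules)

#' @rdname RuleMatrix-class
#' @export
setMethod("ruleValues", "RuleMatrix", function(x) x@values)

setMethod("show", "RuleMatrix", function(object) {
    cat("RuleMatrix:", nrow(object@rules), "rules x", ncol(object@values), "samples\n")
    if ("targetClass" %in% names(object@rules))
        cat("  target classes:", paste(unique(object@rules$targetClass), collapse = ", "), "\n")
})

#' PredictionResult: per-sample class scores and calls
#'
#' Scores are on each predictor's native scale (Pearson correlation for
#' centroids, vote fractions for k-TSP, posterior probabilities for the
#' Naive Bayes and Random Forest predictors). The predicted class attains
#' the maximum score; `margin` is top minus second-best score (0 under a
#' tie); `tie` is TRUE iff at least two classes share the exact top score,
#' in which case the lexicographically first top class is reported.
#'
#' @slot scores numeric samples-by-classes matrix.
#' @slot predicted character vector of winning labels.
#' @slot margin numeric top-minus-second score differences.
#' @slot tie logical tie flags.
#' @slot method character, the predictor family that produced the result.
#' @aliases scores predictedClass scoreMargin tieFlag
#' @export
setClass("PredictionResult",
    representation(scores = "matrix", predicted = "character",
                   margin = "numeric", tie = "logical", method = "character"))

setValidity("PredictionResult", function(object) {
    msg <- NULL
    n <- nrow(object@scores)
    if (length(object@predicted) != n || length(object@margin) != n ||
        length(object@tie) != n)
        msg <- c(msg, "per-sample vectors must match score matrix rows")
    if (any(object@margin < 0)) msg <- c(msg, "margins must be non-negative")
    if (is.null(msg)) TRUE else msg
})

# Internal constructor: derives call, margin and tie flag from a score matrix.
newPredictionResult <- function(scoreMat, method = "unknown") {
    classes <- sort(colnames(scoreMat))
    scoreMat <- scoreMat[, classes, drop = FALSE]
    top <- apply(scoreMat, 1L, max)
    tie <- vapply(seq_len(nrow(scoreMat)), function(i)
        sum(scoreMat[i, ] == top[i]) >= 2L, logical(1))
    predicted <- vapply(seq_len(nrow(scoreMat)), function(i)
        classes[which(scoreMat[i, ] == top[i])[1L]], character(1))
    second <- vapply(seq_len(nrow(scoreMat)), function(i) {
        s <- sort(scoreMat[i, ], decreasing = TRUE)
        if (length(s) >= 2L) s[2L] else s[1L]
    }, numeric(1))
    methods::new("PredictionResult", scores = scoreMat, predicted = predicted,
                 margin = top - second, tie = tie, method = method)
}

#' @rdname PredictionResult-class
#' @export
setMethod("scores", "PredictionResult", function(x) x@scores)

#' @rdname PredictionResult-class
#' @export
setMethod("predictedClass", "PredictionResult", function(x)
    stats::setNames(x@predicted, rownames(x@scores)))

#' @rdname PredictionResult-class
#' @export
setMethod("scoreMargin", "PredictionResult", function(x)
    stats::setNames(x@margin, rownames(x@scores)))

#' @rdname PredictionResult-class
#' @export
setMethod("tieFlag", "PredictionResult", function(x)
    stats::setNames(x@tie, rownames(x@scores)))

#' @describeIn PredictionResult-class flatten to a data.frame
#'   (sample_id, predicted_class, tie_flag, margin, one score column per class).
#' @param row.names,optional,... passed through for S3 compatibility.
#' @export
as.data.frame.PredictionResult <- function(x, row.names = NULL, optional = FALSE, ...) {
    out <- data.frame(sample_id = rownames(x@scores),
                      predicted_class = x@predicted,
                      tie_flag = x@tie, margin = x@margin,
                      stringsAsFactors = FALSE)
    sc <- x@scores
    colnames(sc) <- paste0("score_", colnames(sc))
    cbind(out, as.data.frame(sc, row.names = NULL))
}

setMethod("show", "PredictionResult", function(object) {
    cat("PredictionResult (", object@method, "): ", nrow(object@scores),
        " samples, ", ncol(object@scores), " classes\n", sep = "")
    cat("  ties:", sum(object@tie), " mean margin:",
        signif(mean(object@margin), 4), "\n")
    print(table(predicted = object@predicted))
})

#' CentroidModel: nearest-centroid predictor (raw or centered)
#'
#' In `raw` mode ("single-sample centroid") class centroids are mean raw
#' expression profiles and samples are scored by Pearson correlation to each
#' centroid on the union gene set; a sample can be predicted in isolation.
#' In `centered` mode the centroids are means of per-gene row-centered
#' training data and new samples are centered with the *stored training row
#' means*, never with the batch they arrive in.
#'
#' @slot mode "raw" or "centered".
#' @slot m genes per class per direction used for selection.
#' @slot classes class labels.
#' @slot geneLists per-class list with `up` and `down` gene vectors.
#' @slot unionGenes deduplicated union of selected genes.
#' @slot centroids union-genes-by-classes matrix of class means.
#' @slot rowMeansTrain per-gene training means (centered mode; empty in raw).
#' @seealso [buildCentroids()], [predictSamples()]
#' @export
setClass("CentroidModel",
    representation(mode = "character", m = "integer", classes = "character",
                   geneLists = "list", unionGenes = "character",
                   centroids = "matrix", rowMeansTrain = "numeric"))

setValidity("CentroidModel", function(object) {
    msg <- NULL
    if (!object@mode %in% c("raw", "centered")) msg <- c(msg, "mode must be raw or centered")
    if (anyNA(object@centroids)) msg <- c(msg, "centroid matrix must have no missing values")
    sel <- unique(unlist(object@geneLists))
    if (!all(sel %in% object@unionGenes))
        msg <- c(msg, "every selected gene must appear in the union list")
    if (length(object@unionGenes) > 2L * object@m * length(object@classes))
        msg <- c(msg, "union gene list larger than 2*m*C")
    if (object@mode == "centered" && length(object@rowMeansTrain) != length(object@unionGenes))
        msg <- c(msg, "centered mode requires stored training row means")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CentroidModel", function(object) {
    cat("CentroidModel (", object@mode, " mode): ", length(object@classes),
        " classes, m = ", object@m, ", union of ", length(object@unionGenes),
        " genes\n", sep = "")
})

#' KTSPModel: one-vs-rest multiclass k-Top-Scoring-Pairs predictor
#'
#' One binary k-TSP voter per class; each voter scores a sample as the
#' fraction of its k rules that are TRUE (rules oriented so TRUE indicates
#' the target class) and the highest vote fraction decides the call. Within
#' one class's rule list no gene appears twice; k may differ across classes.
#'
#' @slot classes class labels.
#' @slot rules per-class data.frame (geneA, geneB, delta, gamma).
#' @slot k chosen number of rules per class.
#' @slot config snapshot of the [ktspConfig()] used.
#' @export
setClass("KTSPModel",
    representation(classes = "character", rules = "list", k = "integer",
                   config = "list"))

setValidity("KTSPModel", function(object) {
    msg <- NULL
    for (cl in object@classes) {
        r <- object@rules[[cl]]
        g <- c(r$geneA, r$geneB)
        if (anyDuplicated(g))
            msg <- c(msg, sprintf("class %s rule list reuses a gene", cl))
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "KTSPModel", function(object) {
    cat("KTSPModel:", length(object@classes), "one-vs-rest voters\n")
    cat("  k per class:", paste0(object@classes, "=", object@k, collapse = ", "), "\n")
})

#' NBRulesModel: Naive Bayes over selected gene-pair rules
#'
#' Exhaustively scored gene-pair rules; the same number k of top rules per
#' class (chosen at the peak of a stratified cross-validation accuracy
#' curve) feed a multiclass Bernoulli Naive Bayes with class-proportion
#' priors and additive smoothing.
#'
#' @slot classes class labels.
#' @slot rules data.frame of selected rules (geneA, geneB, targetClass, delta).
#' @slot k chosen rules per class.
#' @slot priors class prior probabilities (sum to 1).
#' @slot condProb rules-by-classes matrix of smoothed P(rule = 1 | class).
#' @slot cvCurve data.frame (k, accuracy) of the cross-validation sweep.
#' @slot config snapshot of the [nbRulesConfig()] used.
#' @export
setClass("NBRulesModel",
    representation(classes = "character", rules = "data.frame", k = "integer",
                   priors = "numeric", condProb = "matrix", cvCurve = "data.frame",
                   config = "list"))

setValidity("NBRulesModel", function(object) {
    msg <- NULL
    if (abs(sum(object@priors) - 1) > 1e-8) msg <- c(msg, "priors must sum to 1")
    if (length(object@condProb) &&
        (any(object@condProb <= 0) || any(object@condProb >= 1)))
        msg <- c(msg, "smoothed conditionals must lie strictly in (0,1)")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "NBRulesModel", function(object) {
    cat("NBRulesModel:", length(object@classes), "classes, k =", object@k,
        "rules per class (", nrow(object@rules), "rules )\n")
})

#' RFRulesModel: three-stage rule-based Random Forest predictor
#'
#' Stage 1 ranks genes by impurity importance of forests trained on ranked
#' raw data (one all-classes model plus one one-vs-rest model per class) and
#' keeps the top genes of each. Stage 2 repeats the forest training on the
#' binarized gene-pair rules of the gene union. After a per-gene
#' diversification filter, the top rules per model train a final probability
#' forest whose out-of-bag votes provide training scores, and which supports
#' proximity extraction, shadow-feature pruning and kNN rule imputation for
#' missing genes.
#'
#' @slot classes class labels.
#' @slot stage1 list: per-model gene importances and the selected gene union.
#' @slot stage2 list: candidate rules and per-model rule importances.
#' @slot rules data.frame of rules used by the final forest.
#' @slot forest the fitted probability forest (with stored in-bag counts).
#' @slot trainRuleValues retained rules-by-training-samples 0/1 matrix.
#' @slot trainLabels training class labels.
#' @slot oobScores samples-by-classes out-of-bag score matrix.
#' @slot oobAccuracy out-of-bag training accuracy.
#' @slot config snapshot of the [rfConfig()] used.
#' @seealso [trainRFRules()], [borutaPrune()], [extractProximity()]
#' @export
setClass("RFRulesModel",
    representation(classes = "character", stage1 = "list", stage2 = "list",
                   rules = "data.frame", forest = "ANY",
                   trainRuleValues = "matrix", trainLabels = "character",
                   oobScores = "matrix", oobAccuracy = "numeric",
                   config = "list"))

setMethod("show", "RFRulesModel", function(object) {
    cat("RFRulesModel:", length(object@classes), "classes,",
        nrow(object@rules), "rules,",
        object@config$nTreesFinal, "trees\n")
    cat("  OOB accuracy:", signif(object@oobAccuracy, 4), "\n")
})

#' BorutaResult: shadow-feature pruning outcome
#'
#' Each rule is compared over iterations against the maximum importance of
#' permuted "shadow" copies of all rules and labeled confirmed, tentative or
#' rejected by a binomial test on the hit counts.
#'
#' @slot status factor per rule: confirmed / tentative / rejected.
#' @slot hits number of iterations each rule beat the best shadow.
#' @slot iterations iterations each rule was tested in.
#' @export
setClass("BorutaResult",
    representation(status = "factor", hits = "integer", iterations = "integer"))

setMethod("show", "BorutaResult", function(object) {
    print(table(object@status))
})

#' SyntheticConfig: generative parameters for simulated cohorts
#'
#' Parameters of the synthetic multi-class, multi-platform, variable-purity
#' cohort generator; see [simulateCohort()] for the generative model. All
#' expression-shift parameters (`effectSize`, `stromalEffectSize`,
#' `baselineRange`, `noiseSD`) are on the natural-log abundance scale used
#' internally; the emitted matrix is log2(abundance + 1).
#'
#' @slot nClasses number of tumor classes (>= 2).
#' @slot nGenes total genes.
#' @slot nInformativePerClass class-specific differentially expressed genes.
#' @slot effectSize mean log-scale shift of informative genes.
#' @slot noiseSD per-gene Gaussian noise SD.
#' @slot platforms list of lists (name, compression, offsetSD): per-platform
#'   power-law dynamic-range compression exponent and per-gene lognormal
#'   offset SD.
#' @slot purityAlpha,purityBeta Beta parameters of the tumor-purity
#'   distribution (NA = purity fixed at 1). Length-nClasses vectors give
#'   class-specific purity distributions, emulating tumor categories partly
#'   defined by high infiltration.
#' @slot stromalEffectSize shift defining the stromal/immune background
#'   profile on the designated stromal gene set.
#' @slot nStromal number of stromal-program genes.
#' @slot nSamplesPerClassPerPlatform samples per class on each platform.
#' @slot baselineRange Uniform range of baseline log-scale gene means.
#' @slot overlapFraction fraction of each class's informative set shared
#'   with the next class (0 = disjoint, the default).
#' @slot effectDecay geometric decay of informative-gene effects within a
#'   class (gene j shifts by `effectSize * effectDecay^(j-1)`); 1 (default)
#'   gives constant effects, values below 1 give the rank-ordered
#'   effect-size continuum seen in real marker lists.
#' @slot stromalOverlapClass index of a class whose upregulated program is
#'   shared by the stromal profile (NA = none), emulating tumor classes
#'   that resemble stromal/immune-rich tissue.
#' @slot seed master seed; gene-level and sample-level draws use separate
#'   streams derived from it so regenerating samples keeps the gene universe.
#' @seealso [syntheticConfig()], [simulateCohort()]
#' @export
setClass("SyntheticConfig",
    representation(nClasses = "integer", nGenes = "integer",
                   nInformativePerClass = "integer", effectSize = "numeric",
                   noiseSD = "numeric", platforms = "list",
                   purityAlpha = "numeric", purityBeta = "numeric",
                   stromalEffectSize = "numeric", nStromal = "integer",
                   nSamplesPerClassPerPlatform = "integer",
                   baselineRange = "numeric", overlapFraction = "numeric",
                   effectDecay = "numeric", stromalOverlapClass = "integer",
                   seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- NULL
    if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
    need <- object@nInformativePerClass * object@nClasses
    if (object@overlapFraction == 0 && need > object@nGenes)
        msg <- c(msg, "nInformativePerClass * nClasses must not exceed nGenes")
    for (p in object@platforms) {
        if (!all(c("name", "compression", "offsetSD") %in% names(p)))
            msg <- c(msg, "each platform needs name, compression, offsetSD")
        else if (p$compression <= 0) msg <- c(msg, "compression exponent must be > 0")
    }
    if (!length(object@purityAlpha) %in% c(1L, object@nClasses) ||
        length(object@purityBeta) != length(object@purityAlpha))
        msg <- c(msg, "purity parameters must have length 1 or nClasses")
    if (!all(is.na(object@purityAlpha)) &&
        (any(object@purityAlpha <= 0, na.rm = TRUE) ||
         any(object@purityBeta <= 0, na.rm = TRUE)))
        msg <- c(msg, "purity Beta parameters must be positive")
    if (object@overlapFraction < 0 || object@overlapFraction >= 1)
        msg <- c(msg, "overlapFraction must be in [0,1)")
    if (object@effectDecay <= 0 || object@effectDecay > 1)
        msg <- c(msg, "effectDecay must be in (0,1]")
    if (!is.na(object@stromalOverlapClass) &&
        (object@stromalOverlapClass < 1L || object@stromalOverlapClass > object@nClasses))
        msg <- c(msg, "stromalOverlapClass out of range")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SyntheticConfig
#'
#' Defaults emulate a five-class tumor cohort with strong subtype markers
#' (log-scale effect 2 against per-gene noise SD 0.5), a 30-gene
#' stromal/immune program, purity fixed at 1 and a single undistorted
#' platform. Platform distortion and sub-unit purity are opted into
#' explicitly, e.g. `platforms = list(list(name = "rnaseq", compression = 1,
#' offsetSD = 0), list(name = "array", compression = 0.5, offsetSD = 0.4))`
#' and `purityAlpha = 8, purityBeta = 2`.
#'
#' @param nClasses,nGenes,nInformativePerClass,effectSize,noiseSD,platforms
#'   see [SyntheticConfig-class].
#' @param purityAlpha,purityBeta,stromalEffectSize,nStromal see
#'   [SyntheticConfig-class].
#' @param nSamplesPerClassPerPlatform,baselineRange,overlapFraction,seed see
#'   [SyntheticConfig-class].
#' @param effectDecay,stromalOverlapClass see [SyntheticConfig-class].
#' @return a validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nClasses = 5L, nGenes = 300L,
                            nInformativePerClass = 20L,
                            effectSize = 2, noiseSD = 0.5,
                            platforms = list(list(name = "platform1",
                                                  compression = 1, offsetSD = 0)),
                            purityAlpha = NA_real_, purityBeta = NA_real_,
                            stromalEffectSize = 2, nStromal = 30L,
                            nSamplesPerClassPerPlatform = 20L,
                            baselineRange = c(1, 7), overlapFraction = 0,
                            effectDecay = 1, stromalOverlapClass = NA_integer_,
                            seed = 1L) {
    methods::new("SyntheticConfig",
        nClasses = as.integer(nClasses), nGenes = as.integer(nGenes),
        nInformativePerClass = as.integer(nInformativePerClass),
        effectSize = effectSize, noiseSD = noiseSD, platforms = platforms,
        purityAlpha = as.numeric(purityAlpha), purityBeta = as.numeric(purityBeta),
        stromalEffectSize = stromalEffectSize, nStromal = as.integer(nStromal),
        nSamplesPerClassPerPlatform = as.integer(nSamplesPerClassPerPlatform),
        baselineRange = baselineRange, overlapFraction = overlapFraction,
        effectDecay = effectDecay,
        stromalOverlapClass = as.integer(stromalOverlapClass),
        seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nClasses, "classes,", object@nGenes, "genes,",
        object@nSamplesPerClassPerPlatform, "samples/class/platform,",
        length(object@platforms), "platform(s)\n")
    cat("  effect", object@effectSize, "noise", object@noiseSD,
        "purity", if (is.na(object@purityAlpha)) "1 (fixed)" else
            paste0("Beta(", object@purityAlpha, ",", object@purityBeta, ")"), "\n")
})

#' GroundTruth: record of the generative state of a simulated cohort
#'
#' @slot informative per-class data.frame (gene, direction) of informative
#'   genes, exactly as generated.
#' @slot stromalGenes genes carrying the stromal/immune background program.
#' @slot purity per-sample tumor purity in (0, 1].
#' @slot baselineMeans per-gene baseline log-scale means.
#' @slot classMeans genes-by-classes matrix of tumor-profile means.
#' @slot injectedPairs data.frame of platform-specific pairs added by
#'   [injectPlatformSpecificPairs()] (empty otherwise).
#' @export
setClass("GroundTruth",
    representation(informative = "list", stromalGenes = "character",
                   purity = "numeric", baselineMeans = "numeric",
                   classMeans = "matrix", injectedPairs = "data.frame"))

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@informative), "classes,",
        sum(vapply(object@informative, nrow, 1L)), "informative genes,",
        length(object@stromalGenes), "stromal genes,",
        nrow(object@injectedPairs), "injected platform-specific pairs\n")
})

#' EvalReport: evaluation summary for a set of predictions
#'
#' @slot accuracy overall accuracy (trace of the confusion matrix / total).
#'   A tied sample counts as correct only when the reference class is the
#'   reported (lexicographically first) winner.
#' @slot recall per-reference-class recall.
#' @slot confusion reference-by-predicted confusion matrix.
#' @slot tieCount number of tied top scores.
#' @slot meanMargin mean top-versus-second score margin.
#' @slot perPlatform per-platform accuracy (NULL when no platforms given).
#' @export
setClass("EvalReport",
    representation(accuracy = "numeric", recall = "numeric",
                   confusion = "matrix", tieCount = "integer",
                   meanMargin = "numeric", perPlatform = "ANY"))

setMethod("show", "EvalReport", function(object) {
    cat("EvalReport: accuracy", signif(object@accuracy, 4),
        "| ties", object@tieCount,
        "| mean margin", signif(object@meanMargin, 4), "\n")
    print(object@confusion)
    if (!is.null(object@perPlatform)) {
        cat("per-platform accuracy:\n")
        print(object@perPlatform)
    }
})
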