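#' Predict class labels for new samples
#'
#' Common prediction contract for all trained predictor families. Every
#' method returns a [PredictionResult-class] with one score per class per
#' sample, the winning label, the top-versus-second score margin and a tie
#' flag. Ties (exact equality of the top score) are resolved to the
#' lexicographically first class and flagged.
#'
#' @param object a trained model (`CentroidModel`, `KTSPModel`,
#'   `NBRulesModel` or `RFRulesModel`).
#' @param x an [ExpressionCohort-class] or a numeric genes-by-samples matrix
#'   on the raw (non-cohort-normalized) scale used at training time.
#' @param ... method-specific arguments.
#' @return a [PredictionResult-class].
#' @export
setGeneric("predictSamples", function(object, x, ...) standardGeneric("predictSamples"))

#' Within-sample rank transform
#'
#' Replaces each sample's expression values by their within-sample ranks
#' (average ranks on ties). The result is invariant under any strictly
#' increasing per-sample transform of the input, which is the property that
#' makes rank- and rule-based predictors single-sample predictors.
#'
#' @param x an [ExpressionCohort-class] or a numeric genes-by-samples matrix.
#' @return an object of the same class as `x` with ranked values.
#' @export
setGeneric("rankTransform", function(x) standardGeneric("rankTransform"))

#' @rdname ExpressionCohort-class
#' @param x an `ExpressionCohort`.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionCohort-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ExpressionCohort-class
#' @export
setGeneric("platformLabels", function(x) standardGeneric("platformLabels"))

#' @rdname ExpressionCohort-class
#' @export
setGeneric("datasetLabels", function(x) standardGeneric("datasetLabels"))

#' @rdname PredictionResult-class
#' @param object,x a `PredictionResult`.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname PredictionResult-class
#' @export
setGeneric("predictedClass", function(x) standardGeneric("predictedClass"))

#' @rdname PredictionResult-class
#' @export
setGeneric("scoreMargin", function(x) standardGeneric("scoreMargin"))

#' @rdname PredictionResult-class
#' @export
setGeneric("tieFlag", function(x) standardGeneric("tieFlag"))

#' @rdname RuleMatrix-class
#' @param x a `RuleMatrix`.
#' @export
setGeneric("ruleInfo", function(x) standardGeneric("ruleInfo"))

#' @rdname RuleMatrix-class
#' @export
setGeneric("ruleValues", function(x) standardGeneric("ruleValues"))
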