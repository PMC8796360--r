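#' @include AllClasses.R
NULL

#' Rule table of a trained rule-based model
#'
#' Returns one row per gene-pair rule with a `targetClass` column, suitable
#' for [binarizeRules()] and [platformSpecificity()]. For k-TSP models the
#' target is the owning class voter; for Naive-Bayes models it is the class
#' whose ranking selected the rule; for Random Forest models — whose rules
#' are not class-owned — each rule is attributed to the class with the
#' largest one-vs-rest delta on the retained training rule values.
#'
#' @param model a [KTSPModel-class], [NBRulesModel-class] or
#'   [RFRulesModel-class].
#' @return data.frame with columns `geneA`, `geneB`, `targetClass`.
#' @export
modelRuleTable <- function(model) {
    if (methods::is(model, "KTSPModel")) {
        out <- do.call(rbind, lapply(model@classes, function(cl)
            cbind(model@rules[[cl]][, c("geneA", "geneB"), drop = FALSE],
                  targetClass = cl, stringsAsFactors = FALSE)))
        rownames(out) <- NULL
        return(out)
    }
    if (methods::is(model, "NBRulesModel"))
        return(model@rules[, c("geneA", "geneB", "targetClass"), drop = FALSE])
    if (methods::is(model, "RFRulesModel")) {
        v <- model@trainRuleValues
        lab <- model@trainLabels
        deltas <- vapply(sort(unique(lab)), function(cl)
            abs(rowMeans(v[, lab == cl, drop = FALSE]) -
                rowMeans(v[, lab != cl, drop = FALSE])),
            numeric(nrow(v)))
        deltas <- matrix(deltas, nrow = nrow(v),
                         dimnames = list(NULL, sort(unique(lab))))
        out <- model@rules[, c("geneA", "geneB"), drop = FALSE]
        out$targetClass <- colnames(deltas)[max.col(deltas, ties.method = "first")]
        rownames(out) <- NULL
        return(out)
    }
    stop("no rule table for models of class ", class(model))
}
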