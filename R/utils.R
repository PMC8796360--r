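`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a local RNG state; the caller's stream is untouched.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Accept either an ExpressionCohort or a bare genes x samples matrix.
asExprMatrix <- function(x) {
    if (methods::is(x, "ExpressionCohort")) return(exprValues(x))
    if (is.matrix(x) && is.numeric(x)) {
        if (is.null(rownames(x)) || is.null(colnames(x)))
            stop("expression matrix needs gene rownames and sample colnames")
        return(x)
    }
    stop("expected an ExpressionCohort or a numeric genes x samples matrix")
}

requireLabels <- function(cohort, minPerClass = 2L) {
    lab <- classLabels(cohort)
    if (is.null(lab)) stop("cohort carries no class labels")
    tb <- table(lab)
    if (any(tb < minPerClass))
        stop("every class needs at least ", minPerClass, " samples; offending: ",
             paste(names(tb)[tb < minPerClass], collapse = ", "))
    lab
}

# Column-wise average ranks of a genes x samples matrix.
colRanks <- function(m) {
    r <- apply(m, 2L, rank, ties.method = "average")
    dimnames(r) <- dimnames(m)
    r
}

# Rank-form AUC of numeric scores against a logical positive indicator
# (Mann-Whitney with average ranks, so binary scores are handled exactly).
rankAUC <- function(score, positive) {
    n1 <- sum(positive); n0 <- sum(!positive)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(score, ties.method = "average")
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
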