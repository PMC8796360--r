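#' @include AllClasses.R
NULL

#' Enumerate candidate gene-pair rules
#'
#' With a single gene list (or `right` identical to `left`) all
#' `n*(n-1)/2` unordered pairs are emitted with orientation canonicalized
#' lexicographically (the TSP score delta is symmetric under orientation
#' flip with the rule value complemented). With two distinct lists, all
#' ordered pairs `(a, b)` with `a != b` are emitted.
#'
#' @param genesLeft,genesRight non-empty character vectors of gene ids.
#' @return data.frame with columns `geneA`, `geneB`.
#' @export
enumerateRules <- function(genesLeft, genesRight = genesLeft) {
    stopifnot(length(genesLeft) > 0L, length(genesRight) > 0L)
    if (setequal(genesLeft, genesRight)) {
        g <- sort(unique(genesLeft))
        if (length(g) < 2L) return(data.frame(geneA = character(),
                                              geneB = character()))
        cb <- utils::combn(g, 2L)
        return(data.frame(geneA = cb[1L, ], geneB = cb[2L, ],
                          stringsAsFactors = FALSE))
    }
    grid <- expand.grid(geneA = genesLeft, geneB = genesRight,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[grid$geneA != grid$geneB, , drop = FALSE]
    rownames(grid) <- NULL
    grid
}

#' Binarize expression into gene-pair rule values
#'
#' Entry (r, i) is 1 iff `expr(geneA_r, i) > expr(geneB_r, i)`, with exact
#' ties evaluating to 0 (strict inequality). Because only within-sample
#' comparisons are used, the result is invariant to any per-sample strictly
#' increasing transform of the expression values — the defining
#' single-sample-predictor property.
#'
#' @param x an [ExpressionCohort-class] or genes-by-samples matrix.
#' @param rules data.frame with `geneA`, `geneB` (extra columns are kept).
#' @return a [RuleMatrix-class].
#' @export
binarizeRules <- function(x, rules) {
    m <- asExprMatrix(x)
    missing <- setdiff(unique(c(rules$geneA, rules$geneB)), rownames(m))
    if (length(missing)) {
        hit <- which(rules$geneA %in% missing | rules$geneB %in% missing)[1L]
        stop("gene(s) absent from expression data: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             " (first affected rule: ", rules$geneA[hit], ">", rules$geneB[hit], ")")
    }
    vals <- (m[rules$geneA, , drop = FALSE] > m[rules$geneB, , drop = FALSE]) * 1L
    rownames(vals) <- paste0(rules$geneA, ">", rules$geneB)
    if (!"targetClass" %in% names(rules)) rules$targetClass <- "all"
    methods::new("RuleMatrix", rules = rules, values = vals)
}

#' TSP score of a single rule
#'
#' The primary score delta is the absolute difference in the empirical
#' frequency of the rule being TRUE between the target class and the
#' comparison group (all non-target samples in `one_vs_rest` mode, class
#' `other` in `one_vs_one` mode). The secondary score gamma — used only to
#' order rules of equal delta — is the absolute difference in the mean
#' within-sample rank difference of the pair between the two groups, and is
#' returned when `rankDiff` (per-sample rank(A) - rank(B)) is supplied.
#'
#' @param ruleValues 0/1 vector of rule values per sample.
#' @param labels class labels per sample.
#' @param target the target class.
#' @param mode `"one_vs_rest"` or `"one_vs_one"`.
#' @param other comparison class (one_vs_one mode).
#' @param rankDiff optional numeric vector of within-sample rank differences.
#' @return named numeric `c(delta =, gamma =)` (gamma NA without rankDiff).
#' @export
tspScore <- function(ruleValues, labels, target,
                     mode = c("one_vs_rest", "one_vs_one"), other = NULL,
                     rankDiff = NULL) {
    mode <- match.arg(mode)
    inT <- labels == target
    comp <- if (mode == "one_vs_rest") !inT else labels == other
    if (!any(inT)) stop("no samples of target class '", target, "'")
    if (!any(comp)) stop("empty comparison group")
    delta <- abs(mean(ruleValues[inT]) - mean(ruleValues[comp]))
    gamma <- if (is.null(rankDiff)) NA_real_
             else abs(mean(rankDiff[inT]) - mean(rankDiff[comp]))
    c(delta = delta, gamma = gamma)
}

# Vectorized signed TSP scoring over all rules of a RuleMatrix.
# Returns data.frame(delta = |signed|, signed, gamma). signed > 0 means the
# rule as oriented is TRUE more often in the target class.
scoreRulesForClass <- function(ruleMat, labels, target,
                               mode = c("one_vs_rest", "one_vs_one"),
                               other = NULL, rankedExpr = NULL,
                               weights = NULL, groups = NULL) {
    mode <- match.arg(mode)
    v <- ruleValues(ruleMat)
    inT <- labels == target
    comp <- if (mode == "one_vs_rest") !inT else labels == other
    if (!any(inT) || !any(comp)) stop("empty class group in rule scoring")
    signedOne <- function(keepT, keepC)
        rowMeans(v[, keepT, drop = FALSE]) - rowMeans(v[, keepC, drop = FALSE])
    if (is.null(groups)) {
        signed <- signedOne(inT, comp)
    } else {
        # per-group (e.g. per-dataset) signed deltas averaged with weights
        gs <- unique(groups)
        w <- (weights %||% stats::setNames(rep(1, length(gs)), gs))[gs]
        parts <- vapply(gs, function(g) {
            kT <- inT & groups == g; kC <- comp & groups == g
            if (!any(kT) || !any(kC)) return(rep(NA_real_, nrow(v)))
            signedOne(kT, kC)
        }, numeric(nrow(v)))
        parts <- matrix(parts, nrow = nrow(v))
        ok <- !is.na(parts[1L, ])
        signed <- as.numeric(parts[, ok, drop = FALSE] %*%
                             (w[ok] / sum(w[ok])))
    }
    gamma <- rep(NA_real_, nrow(v))
    if (!is.null(rankedExpr)) {
        r <- ruleInfo(ruleMat)
        rd <- rankedExpr[r$geneA, , drop = FALSE] - rankedExpr[r$geneB, , drop = FALSE]
        gamma <- abs(rowMeans(rd[, inT, drop = FALSE]) -
                     rowMeans(rd[, comp, drop = FALSE]))
    }
    data.frame(delta = abs(signed), signed = signed, gamma = gamma)
}

#' Per-rule platform-specificity diagnostics
#'
#' For every rule and platform, reports the AUC of the binary rule value
#' against target-class membership within that platform (Mann-Whitney rank
#' form, folded to [0.5, 1] so orientation does not matter) and the
#' constancy fraction (max of the fraction TRUE and fraction FALSE). A rule
#' is flagged platform-specific when it discriminates on some platform
#' (AUC >= `aucHigh`) while being near-uninformative (AUC <= `aucLow`) or
#' near-constant (constancy >= `constancyHigh`) on another. Platforms
#' without target-class samples yield NA AUC and are excluded from
#' flagging. The thresholds are tool defaults, not estimated quantities.
#'
#' @param ruleMat a [RuleMatrix-class] whose rules carry a `targetClass`.
#' @param labels per-sample class labels.
#' @param platforms per-sample platform labels (>= 2 platforms).
#' @param aucHigh,aucLow,constancyHigh flagging thresholds.
#' @return list with `table` (long data.frame: rule, targetClass, platform,
#'   auc, constancy) and `flagged` (logical per rule).
#' @export
platformSpecificity <- function(ruleMat, labels, platforms,
                                aucHigh = 0.7, aucLow = 0.55,
                                constancyHigh = 0.95) {
    plats <- unique(platforms)
    if (length(plats) < 2L) stop("platform specificity needs >= 2 platforms")
    v <- ruleValues(ruleMat)
    info <- ruleInfo(ruleMat)
    if (!"targetClass" %in% names(info) || any(info$targetClass == "all"))
        stop("every rule needs an explicit targetClass")
    rows <- vector("list", nrow(info) * length(plats)); k <- 0L
    flagged <- logical(nrow(info))
    for (r in seq_len(nrow(info))) {
        auc <- con <- stats::setNames(rep(NA_real_, length(plats)), plats)
        for (p in plats) {
            sel <- platforms == p
            pos <- labels[sel] == info$targetClass[r]
            a <- rankAUC(v[r, sel], pos)
            auc[p] <- if (is.na(a)) NA_real_ else max(a, 1 - a)
            f <- mean(v[r, sel])
            con[p] <- max(f, 1 - f)
            k <- k + 1L
            rows[[k]] <- data.frame(rule = rownames(v)[r],
                                    targetClass = info$targetClass[r],
                                    platform = p, auc = auc[p],
                                    constancy = con[p],
                                    stringsAsFactors = FALSE)
        }
        ok <- !is.na(auc)
        disc <- ok & auc >= aucHigh
        dead <- ok & (auc <= aucLow | con >= constancyHigh)
        flagged[r] <- any(disc) && any(dead & !disc)
    }
    list(table = do.call(rbind, rows[seq_len(k)]), flagged = flagged)
}
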