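#' @include AllClasses.R
NULL

# Per-class one-vs-rest gene statistics: moderated-t p-value (limma
# empirical-Bayes variance shrinkage) or plain Welch t, one-vs-rest AUC and
# mean log-scale fold change.
centroidGeneStats <- function(expr, labels, target, test = c("moderated", "welch")) {
    test <- match.arg(test)
    inT <- labels == target
    if (test == "moderated") {
        design <- stats::model.matrix(~ inT)
        fit <- limma::eBayes(limma::lmFit(expr, design))
        p <- fit$p.value[, 2L]
    } else {
        p <- apply(expr, 1L, function(v)
            stats::t.test(v[inT], v[!inT])$p.value)
    }
    ranks <- t(apply(expr, 1L, rank, ties.method = "average"))
    n1 <- sum(inT); n0 <- sum(!inT)
    auc <- (rowSums(ranks[, inT, drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    fc <- rowMeans(expr[, inT, drop = FALSE]) - rowMeans(expr[, !inT, drop = FALSE])
    data.frame(gene = rownames(expr), p = p, auc = auc, foldChange = fc,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Select centroid genes per class
#'
#' Per class (one-vs-rest): retain genes passing the moderated-t gate
#' (p < 0.05) AND a Subtype-vs-Rest AUC strictly above 0.6, rank the
#' survivors by mean fold change (difference of mean log expression), and
#' take the top `m` upregulated and top `m` downregulated genes. Classes
#' with fewer than `m` qualifying genes in a direction contribute all they
#' have, with a warning.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param m genes per class per direction.
#' @param test `"moderated"` (limma empirical-Bayes, default) or `"welch"`.
#' @param pCutoff,aucCutoff selection gates.
#' @return list with `stats` (per-class data.frames of gene, p, auc,
#'   foldChange) and `genes` (per-class lists with `up`, `down`).
#' @export
selectCentroidGenes <- function(cohort, m, test = c("moderated", "welch"),
                                pCutoff = 0.05, aucCutoff = 0.6) {
    stopifnot(m >= 1L)
    test <- match.arg(test)
    lab <- requireLabels(cohort)
    expr <- exprValues(cohort)
    classes <- sort(unique(lab))
    stats <- genes <- list()
    for (cl in classes) {
        st <- centroidGeneStats(expr, lab, cl, test)
        # discrimination gate is direction-free: a downregulated marker has
        # oriented AUC below 0.5 but the same discriminative power
        keep <- st[st$p < pCutoff & pmax(st$auc, 1 - st$auc) > aucCutoff, , drop = FALSE]
        up <- keep[keep$foldChange > 0, , drop = FALSE]
        dn <- keep[keep$foldChange < 0, , drop = FALSE]
        up <- up$gene[order(up$foldChange, decreasing = TRUE)]
        dn <- dn$gene[order(dn$foldChange)]
        if (length(up) < m || length(dn) < m)
            warning("class ", cl, ": only ", length(up), " up / ", length(dn),
                    " down qualifying genes for m = ", m)
        stats[[cl]] <- st
        genes[[cl]] <- list(up = utils::head(up, m), down = utils::head(dn, m))
    }
    list(stats = stats, genes = genes)
}

#' Build a nearest-centroid model
#'
#' Centroids are class means over the deduplicated union of all selected
#' genes (a common vector is required to correlate samples against every
#' centroid). Raw mode averages the raw values ("single-sample centroid");
#' centered mode averages per-gene mean-centered values and stores the
#' training row means for application to new samples. Raw and centered
#' centroids therefore differ by exactly the per-gene training means.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param geneLists per-class `list(up =, down =)` from
#'   [selectCentroidGenes()].
#' @param mode `"raw"` or `"centered"`.
#' @param m the selection size (stored for bookkeeping).
#' @return a [CentroidModel-class].
#' @export
buildCentroids <- function(cohort, geneLists, mode = c("raw", "centered"),
                           m = max(lengths(unlist(geneLists, recursive = FALSE)))) {
    mode <- match.arg(mode)
    lab <- requireLabels(cohort, minPerClass = 1L)  # a 1-sample class is a valid centroid
    classes <- sort(names(geneLists))
    union <- unique(unlist(geneLists, use.names = FALSE))
    expr <- exprValues(cohort)[union, , drop = FALSE]
    rowMeansTrain <- rowMeans(expr)
    work <- if (mode == "centered") expr - rowMeansTrain else expr
    centroids <- vapply(classes, function(cl)
        rowMeans(work[, lab == cl, drop = FALSE]), numeric(length(union)))
    dimnames(centroids) <- list(union, classes)
    methods::new("CentroidModel", mode = mode, m = as.integer(m),
                 classes = classes, geneLists = geneLists, unionGenes = union,
                 centroids = centroids,
                 rowMeansTrain = if (mode == "centered") rowMeansTrain else numeric(0))
}

#' Train a nearest-centroid predictor end to end
#'
#' Convenience wrapper: [selectCentroidGenes()] then [buildCentroids()].
#'
#' @inheritParams selectCentroidGenes
#' @inheritParams buildCentroids
#' @return a [CentroidModel-class].
#' @export
trainCentroid <- function(cohort, m = 10L, mode = c("raw", "centered"),
                          test = c("moderated", "welch")) {
    mode <- match.arg(mode)
    sel <- selectCentroidGenes(cohort, m, test = match.arg(test))
    buildCentroids(cohort, sel$genes, mode = mode, m = m)
}

#' @describeIn predictSamples Nearest-centroid prediction. The score is the
#'   Pearson correlation between the sample's values on the union gene set
#'   (centered mode: minus the stored training row means) and each class
#'   centroid. Samples are scored independently; the batch composition
#'   never enters. Centroid genes absent from `x` are dropped from both
#'   sides with a warning; more than `maxMissing` missing is refused.
#' @param maxMissing maximum tolerated fraction of missing centroid genes
#'   (centroid method; default 0.2).
#' @export
setMethod("predictSamples", "CentroidModel", function(object, x, maxMissing = 0.2, ...) {
    m <- asExprMatrix(x)
    genes <- object@unionGenes
    present <- genes %in% rownames(m)
    if (mean(!present) > maxMissing)
        stop(sum(!present), " of ", length(genes),
             " centroid genes missing (> ", maxMissing * 100, "%)")
    if (any(!present))
        warning("dropping ", sum(!present), " centroid genes absent from input")
    genes <- genes[present]
    vals <- m[genes, , drop = FALSE]
    if (object@mode == "centered")
        vals <- vals - object@rowMeansTrain[genes]
    cent <- object@centroids[genes, , drop = FALSE]
    sds <- apply(vals, 2L, stats::sd)
    if (any(sds == 0))
        stop("zero variance over centroid genes; correlation undefined for: ",
             paste(colnames(vals)[sds == 0], collapse = ", "))
    sc <- stats::cor(vals, cent)
    newPredictionResult(sc, method = paste0(object@mode, "-centroid"))
})

#' Centroid size sweep
#'
#' Trains one centroid model per selection size `m`, reporting the union
#' gene count, training accuracy (direct reapplication to the training
#' data) and mean top-versus-second score margin. Gene statistics are
#' computed once; size grids are nested slices of the same ranking.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param mValues ascending vector of selection sizes.
#' @param mode `"raw"` or `"centered"`.
#' @param test selection test, see [selectCentroidGenes()].
#' @return data.frame (m, unionSize, accuracy, meanMargin), with the fitted
#'   models in `attr(, "models")`.
#' @export
centroidSizeSweep <- function(cohort, mValues = c(10L, 25L, 50L, 75L, 100L, 125L),
                              mode = c("raw", "centered"),
                              test = c("moderated", "welch")) {
    mode <- match.arg(mode)
    stopifnot(!is.unsorted(mValues))
    sel <- suppressWarnings(
        selectCentroidGenes(cohort, max(mValues), test = match.arg(test)))
    lab <- classLabels(cohort)
    models <- list(); out <- vector("list", length(mValues))
    for (i in seq_along(mValues)) {
        mm <- mValues[i]
        gl <- lapply(sel$genes, function(g)
            list(up = utils::head(g$up, mm), down = utils::head(g$down, mm)))
        mod <- buildCentroids(cohort, gl, mode = mode, m = mm)
        pr <- predictSamples(mod, cohort)
        models[[as.character(mm)]] <- mod
        out[[i]] <- data.frame(m = mm, unionSize = length(mod@unionGenes),
                               accuracy = mean(predictedClass(pr) == lab),
                               meanMargin = mean(scoreMargin(pr)))
    }
    res <- do.call(rbind, out)
    attr(res, "models") <- models
    res
}
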