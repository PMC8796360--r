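#' @include AllClasses.R
NULL

#' Read an expression matrix from TSV/CSV
#'
#' Expects gene identifiers in the first column and one column per sample
#' (header row of sample ids), genes in rows. Values must be on a raw
#' non-cohort-normalized scale (e.g. log2(TPM+1) or array signal
#' intensities).
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated (override with `sep`).
#' @param duplicates what to do with duplicated gene rows: `"reject"`
#'   (default, error) or `"median"` (median-merge, as is common when probes
#'   are summarized to gene symbols).
#' @param annotation optional path to a sample annotation table with columns
#'   `sample_id`, `class`, and optionally `platform` and `dataset`.
#' @param sep field separator; `NULL` = infer from the extension.
#' @return an [ExpressionCohort-class].
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, duplicates = c("reject", "median"),
                           annotation = NULL, sep = NULL) {
    duplicates <- match.arg(duplicates)
    sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "\"", comment.char = "", stringsAsFactors = FALSE),
        error = function(e) stop("malformed expression file '", path, "': ",
                                 conditionMessage(e)))
    if (ncol(df) < 2L) stop("expression file needs a gene column plus >= 1 sample")
    genes <- as.character(df[[1L]])
    vals <- df[, -1L, drop = FALSE]
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad)) {
        for (j in which(bad)) {
            nn <- suppressWarnings(as.numeric(vals[[j]]))
            if (anyNA(nn) && !anyNA(vals[[j]]))
                stop("non-numeric value in sample column '", names(vals)[j],
                     "' (first at data line ",
                     which(is.na(nn) & !is.na(vals[[j]]))[1L], ")")
            vals[[j]] <- nn
        }
    }
    m <- as.matrix(vals)
    rownames(m) <- genes
    if (anyDuplicated(genes)) {
        if (duplicates == "reject")
            stop("duplicated gene identifier(s): ",
                 paste(unique(genes[duplicated(genes)])[1:5], collapse = ", "),
                 " (use duplicates = 'median' to merge)")
        m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i)
            apply(m[i, , drop = FALSE], 2L, stats::median)))
        m <- m[unique(genes), , drop = FALSE]
    }
    cohort <- ExpressionCohort(m)
    if (!is.null(annotation)) cohort <- attachAnnotation(cohort, readAnnotation(annotation))
    cohort
}

#' Read a sample annotation table
#'
#' @param path TSV/CSV with columns `sample_id`, `class` and optionally
#'   `platform`, `dataset`.
#' @param sep field separator; `NULL` = infer from the extension.
#' @return a data.frame.
#' @export
readAnnotation <- function(path, sep = NULL) {
    sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    ann <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(ann)) stop("annotation needs a sample_id column")
    ann
}

#' Attach sample annotation to a cohort
#'
#' @param cohort an [ExpressionCohort-class].
#' @param ann data.frame as returned by [readAnnotation()].
#' @return the annotated cohort; samples missing from `ann` raise an error.
#' @export
attachAnnotation <- function(cohort, ann) {
    idx <- match(colnames(cohort), ann$sample_id)
    if (anyNA(idx))
        stop("annotation missing sample(s): ",
             paste(colnames(cohort)[is.na(idx)][1:5], collapse = ", "))
    ExpressionCohort(exprValues(cohort),
                     labels = if ("class" %in% names(ann)) ann$class[idx],
                     platform = if ("platform" %in% names(ann)) ann$platform[idx],
                     dataset = if ("dataset" %in% names(ann)) ann$dataset[idx])
}

#' Write an expression matrix (and optionally its annotation) to TSV
#'
#' Full numeric precision is preserved, so write-then-read round-trips.
#'
#' @param cohort an [ExpressionCohort-class] or genes-by-samples matrix.
#' @param path output TSV path for the expression matrix.
#' @param annotationPath optional path for the sample annotation TSV.
#' @export
writeExpression <- function(cohort, path, annotationPath = NULL) {
    m <- asExprMatrix(cohort)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(annotationPath) && methods::is(cohort, "ExpressionCohort")) {
        ann <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
        if (!is.null(classLabels(cohort)))    ann$class    <- unname(classLabels(cohort))
        if (!is.null(platformLabels(cohort))) ann$platform <- unname(platformLabels(cohort))
        if (!is.null(datasetLabels(cohort)))  ann$dataset  <- unname(datasetLabels(cohort))
        utils::write.table(ann, annotationPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' @rdname rankTransform
#' @export
setMethod("rankTransform", "matrix", function(x) colRanks(x))

#' @rdname rankTransform
#' @export
setMethod("rankTransform", "ExpressionCohort", function(x) {
    out <- x
    SummarizedExperiment::assay(out, "exprs") <- colRanks(exprValues(x))
    out
})

#' Combine labeled cohorts into one
#'
#' Cohorts are joined on their gene sets: by default the intersection is
#' used and the number of dropped genes reported; `genes = "strict"`
#' requires identical gene sets. The `dataset` metadata column records each
#' sample's cohort of origin and class sets are unioned.
#'
#' @param cohorts named (or unnamed) list of [ExpressionCohort-class]
#'   objects.
#' @param genes `"intersect"` (default) or `"strict"`.
#' @return a combined [ExpressionCohort-class].
#' @export
combineCohorts <- function(cohorts, genes = c("intersect", "strict")) {
    genes <- match.arg(genes)
    stopifnot(length(cohorts) >= 1L)
    nms <- names(cohorts) %||% paste0("dataset", seq_along(cohorts))
    nms[nms == ""] <- paste0("dataset", which(nms == ""))
    geneSets <- lapply(cohorts, rownames)
    common <- Reduce(intersect, geneSets)
    if (length(common) == 0L) stop("empty gene intersection across cohorts")
    if (genes == "strict" &&
        !all(vapply(geneSets, function(g) setequal(g, common), logical(1))))
        stop("cohorts differ in gene sets (strict mode)")
    dropped <- sum(vapply(geneSets, function(g) length(setdiff(g, common)), 1L))
    if (dropped > 0L)
        message("combineCohorts: dropped ", dropped,
                " gene entries outside the common set of ", length(common), " genes")
    mats <- lapply(cohorts, function(co) asExprMatrix(co)[common, , drop = FALSE])
    values <- do.call(cbind, mats)
    lab <- unlist(lapply(cohorts, function(co)
        classLabels(co) %||% rep(NA_character_, ncol(co))), use.names = FALSE)
    plat <- unlist(lapply(cohorts, function(co)
        platformLabels(co) %||% rep(NA_character_, ncol(co))), use.names = FALSE)
    ds <- unlist(mapply(function(co, nm) {
        datasetLabels(co) %||% rep(nm, ncol(co))
    }, cohorts, nms, SIMPLIFY = FALSE), use.names = FALSE)
    ExpressionCohort(values,
                     labels = if (!all(is.na(lab))) lab,
                     platform = if (!all(is.na(plat))) plat,
                     dataset = ds)
}

#' Stratified train/test split
#'
#' Deterministic given `seed`; per-class train counts are
#' `round(n_c * trainFraction)` clipped so both partitions keep at least one
#' sample per class, preserving class proportions within one sample. The
#' partition is exhaustive and disjoint.
#'
#' @param cohort a labeled [ExpressionCohort-class].
#' @param trainFraction proportion of samples assigned to training, in (0,1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
stratifiedSplit <- function(cohort, trainFraction = 0.8, seed = 1L) {
    stopifnot(trainFraction > 0, trainFraction < 1)
    lab <- requireLabels(cohort, minPerClass = 2L)
    trainIdx <- withSeed(seed, {
        unlist(lapply(split(seq_along(lab), lab), function(idx) {
            nTr <- min(max(round(length(idx) * trainFraction), 1L), length(idx) - 1L)
            sample(idx, nTr)
        }), use.names = FALSE)
    })
    trainIdx <- sort(trainIdx)
    list(train = cohort[, trainIdx], test = cohort[, -trainIdx])
}
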