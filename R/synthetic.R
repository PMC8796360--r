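#' @include AllClasses.R
NULL

# Deterministic per-sample stream seed so that growing the cohort appends
# new draws without perturbing existing samples' noise.
sampleStreamSeed <- function(base, idx) (as.numeric(base) * 7919 + idx * 101) %% 2147483629

#' Simulate a labeled multi-class, multi-platform, variable-purity cohort
#'
#' Generative model, applied in order on the natural-log abundance scale:
#' \enumerate{
#'   \item baseline gene means `b_g ~ Uniform(baselineRange)`;
#'   \item class tumor profiles `m_gc = b_g +/- effectSize` for the
#'     informative genes of class c (half up, half down), else `b_g`;
#'   \item a stromal/immune background profile `s_g = b_g + stromalEffectSize`
#'     on the designated stromal gene set, else `b_g`;
#'   \item per-sample tumor signal `t_gi = m_g,label(i) + N(0, noiseSD)`;
#'   \item purity mixing on the natural (anti-logged) scale —
#'     `x_gi = purity_i * exp(t_gi) + (1 - purity_i) * exp(s_g + N(0, noiseSD))`
#'     with `purity_i ~ Beta(purityAlpha, purityBeta)` (or 1) — dilution is
#'     additive in transcript abundance, not in log space;
#'   \item platform distortion
#'     `y_gi = x_gi ^ compression(platform(i)) * exp(offset_g,platform(i))`
#'     with per-gene offsets `~ N(0, offsetSD)`, emulating the reduced
#'     dynamic range of arrays and platform-specific probe effects.
#' }
#' The emitted matrix is `log2(y + 1)`. Gene-level draws (baselines,
#' informative sets, platform offsets) and sample-level draws use separate
#' seed streams, so regenerating samples (e.g. a fresh test set) keeps the
#' same gene universe. Deterministic given seeds.
#'
#' @param config a [SyntheticConfig-class].
#' @param nPerClassPerPlatform optional override of the config sample count.
#' @param sampleSeed optional seed for the sample-level stream (defaults to
#'   `config@seed + 1`); vary it to draw new samples from the same universe.
#' @param fixedPurity optional purity in (0,1] applied to every sample,
#'   overriding the Beta draw.
#' @return list with elements `cohort` ([ExpressionCohort-class], labels and
#'   platforms attached) and `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulateCohort(syntheticConfig(nClasses = 3, nGenes = 60,
#'                                       nSamplesPerClassPerPlatform = 5))
#' sim$cohort
#' @export
simulateCohort <- function(config, nPerClassPerPlatform = NULL,
                           sampleSeed = NULL, fixedPurity = NULL) {
    methods::validObject(config)
    nG <- config@nGenes; nC <- config@nClasses
    nInf <- config@nInformativePerClass
    nPer <- as.integer(nPerClassPerPlatform %||% config@nSamplesPerClassPerPlatform)
    classes <- paste0("class", seq_len(nC))
    genes <- sprintf("g%04d", seq_len(nG))
    nPlat <- length(config@platforms)
    platNames <- vapply(config@platforms, `[[`, "", "name")

    ## ---- gene-level stream -------------------------------------------------
    gene <- withSeed(config@seed, {
        b <- stats::runif(nG, config@baselineRange[1], config@baselineRange[2])
        names(b) <- genes
        ord <- sample.int(nG)
        nOv <- floor(config@overlapFraction * nInf)
        own <- nInf - nOv
        blocks <- lapply(seq_len(nC), function(c)
            ord[(c - 1L) * own + seq_len(own)])
        informative <- lapply(seq_len(nC), function(c) {
            idx <- blocks[[c]]
            if (nOv > 0L) idx <- c(idx, blocks[[c %% nC + 1L]][seq_len(nOv)])
            data.frame(gene = genes[idx],
                       direction = rep_len(c("up", "down"), length(idx)),
                       stringsAsFactors = FALSE)
        })
        names(informative) <- classes
        used <- unique(unlist(lapply(informative, `[[`, "gene")))
        free <- setdiff(genes[ord], used)
        if (length(free) < config@nStromal)
            stop("not enough genes left for the stromal program")
        stromal <- free[seq_len(config@nStromal)]
        offsets <- lapply(config@platforms, function(p) {
            o <- stats::rnorm(nG, 0, p$offsetSD); names(o) <- genes; o
        })
        list(b = b, informative = informative, stromal = stromal, offsets = offsets)
    })
    classMeans <- matrix(gene$b, nG, nC, dimnames = list(genes, classes))
    for (c in seq_len(nC)) {
        inf <- gene$informative[[c]]
        eff <- config@effectSize * config@effectDecay^(seq_len(nrow(inf)) - 1L)
        shift <- ifelse(inf$direction == "up", eff, -eff)
        classMeans[inf$gene, c] <- classMeans[inf$gene, c] + shift
    }
    stromalSet <- gene$stromal
    if (!is.na(config@stromalOverlapClass)) {
        ov <- gene$informative[[config@stromalOverlapClass]]
        stromalSet <- union(stromalSet, ov$gene[ov$direction == "up"])
    }
    stromalProfile <- gene$b
    stromalProfile[stromalSet] <- stromalProfile[stromalSet] + config@stromalEffectSize

    ## ---- sample-level stream -----------------------------------------------
    baseSS <- as.numeric(sampleSeed %||% (config@seed + 1L))
    nSamples <- nPlat * nC * nPer
    values <- matrix(NA_real_, nG, nSamples)
    labels <- character(nSamples); platform <- character(nSamples)
    purity <- numeric(nSamples)
    sampleIds <- character(nSamples)
    col <- 0L
    for (rep in seq_len(nPer)) for (p in seq_len(nPlat)) for (c in seq_len(nC)) {
        col <- col + 1L
        idx <- ((rep - 1L) * nPlat + (p - 1L)) * nC + (c - 1L)
        pl <- config@platforms[[p]]
        pa <- rep_len(config@purityAlpha, nC)[c]
        pb <- rep_len(config@purityBeta, nC)[c]
        smp <- withSeed(sampleStreamSeed(baseSS, idx), {
            pu <- if (!is.null(fixedPurity)) fixedPurity
                  else if (is.na(pa)) 1
                  else stats::rbeta(1L, pa, pb)
            pu <- min(max(pu, 1e-3), 1)
            t <- classMeans[, c] + stats::rnorm(nG, 0, config@noiseSD)
            s <- stromalProfile + stats::rnorm(nG, 0, config@noiseSD)
            x <- pu * exp(t) + (1 - pu) * exp(s)
            y <- x^pl$compression * exp(gene$offsets[[p]])
            list(v = log2(y + 1), purity = pu)
        })
        values[, col] <- smp$v
        purity[col] <- smp$purity
        labels[col] <- classes[c]
        platform[col] <- platNames[p]
        sampleIds[col] <- sprintf("s%04d_%s_%s", col, platNames[p], classes[c])
    }
    dimnames(values) <- list(genes, sampleIds)
    names(purity) <- sampleIds
    cohort <- ExpressionCohort(values, labels = labels,
                               platform = if (nPlat > 1L) platform else NULL)
    truth <- methods::new("GroundTruth",
        informative = gene$informative, stromalGenes = stromalSet,
        purity = purity, baselineMeans = gene$b, classMeans = classMeans,
        injectedPairs = data.frame(geneA = character(), geneB = character(),
                                   class = character(),
                                   discriminativePlatform = character(),
                                   constantPlatform = character(),
                                   stringsAsFactors = FALSE))
    list(cohort = cohort, truth = truth)
}

#' Inject platform-specific gene-pair rules into a simulated cohort
#'
#' Rewrites designated pairs so that the rule "gene A > gene B" is
#' class-discriminative on one platform but constant (here: always TRUE) on
#' another — the expression-ratio crossover present on the first platform
#' never occurs on the second. Gene A is an informative up-gene of some
#' class; gene B (a previously uninformative gene) is set near the midpoint
#' of A's within/without class means on the discriminative platform, and
#' below A's minimum on the constant platform. Affected pairs are recorded
#' in the returned truth.
#'
#' @param cohort,truth output of [simulateCohort()]; >= 2 platforms required.
#' @param nPairs number of pairs to inject (0 = no-op).
#' @param discriminativePlatform,constantPlatform platform names (defaults:
#'   first and second platform present).
#' @param seed seed for the small jitter applied to the rewritten gene.
#' @return list with modified `cohort` and updated `truth`.
#' @export
injectPlatformSpecificPairs <- function(cohort, truth, nPairs,
                                        discriminativePlatform = NULL,
                                        constantPlatform = NULL, seed = 1L) {
    if (nPairs == 0L) return(list(cohort = cohort, truth = truth))
    plat <- platformLabels(cohort)
    if (is.null(plat) || length(unique(plat)) < 2L)
        stop("injection requires >= 2 platforms")
    discriminativePlatform <- discriminativePlatform %||% unique(plat)[1L]
    constantPlatform <- constantPlatform %||% unique(plat)[2L]
    lab <- classLabels(cohort)
    values <- exprValues(cohort)
    infoAll <- do.call(rbind, lapply(names(truth@informative), function(cl)
        cbind(truth@informative[[cl]], class = cl, stringsAsFactors = FALSE)))
    upPool <- infoAll[infoAll$direction == "up", , drop = FALSE]
    # interleave classes so injected pairs spread across the class set
    upPool <- upPool[order(stats::ave(seq_len(nrow(upPool)), upPool$class,
                                      FUN = seq_along)), , drop = FALSE]
    usedB <- character(0)
    freeB <- setdiff(rownames(values),
                     c(unlist(lapply(truth@informative, `[[`, "gene")),
                       truth@stromalGenes))
    if (nrow(upPool) < nPairs || length(freeB) < nPairs)
        stop("fewer than ", nPairs, " eligible gene pairs")
    recs <- vector("list", nPairs)
    withSeed(seed, for (i in seq_len(nPairs)) {
        a <- upPool$gene[i]; cl <- upPool$class[i]
        b <- setdiff(freeB, usedB)[1L]; usedB <- c(usedB, b)
        d1 <- plat == discriminativePlatform
        d2 <- plat == constantPlatform
        tau <- (mean(values[a, d1 & lab == cl]) + mean(values[a, d1 & lab != cl])) / 2
        values[b, d1] <- tau + stats::rnorm(sum(d1), 0, 0.02)
        values[b, d2] <- min(values[a, d2]) - 1
        recs[[i]] <- data.frame(geneA = a, geneB = b, class = cl,
                                discriminativePlatform = discriminativePlatform,
                                constantPlatform = constantPlatform,
                                stringsAsFactors = FALSE)
    })
    newCohort <- ExpressionCohort(values, labels = lab, platform = plat,
                                  dataset = datasetLabels(cohort))
    truth@injectedPairs <- rbind(truth@injectedPairs, do.call(rbind, recs))
    list(cohort = newCohort, truth = truth)
}
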