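#' @import methods
NULL

#' GeneExpressionSet: expression matrix with encoded class labels
#'
#' The central container of the package. Internally a
#' \linkS4class{SummarizedExperiment} with genes as rows and samples as
#' columns; the assay is named \code{"exprs"}. Per-sample class labels are
#' stored as integer codes \code{0..C-1} in \code{colData(x)$label}, with the
#' code-to-name mapping in \code{metadata(x)$labelNames}. User-facing
#' accessors (\code{\link{exprValues}}) present the matrix in the
#' samples-by-genes orientation common to microarray flat files.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#'
#' @seealso \code{\link{GeneExpressionSet}} (constructor),
#'   \code{\link{exprValues}}, \code{\link{classLabels}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass GeneExpressionSet
setClass("GeneExpressionSet", contains = "SummarizedExperiment")

setValidity("GeneExpressionSet", function(object) {
    msg <- character(0)
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is missing")
    if (is.null(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) are missing")
    else if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"label" %in% colnames(cd)) {
        msg <- c(msg, "colData column 'label' (integer class codes) is missing")
    } else {
        lab <- cd$label
        if (!is.integer(lab))
            msg <- c(msg, "labels must be integer codes")
        else {
            u <- sort(unique(lab))
            if (length(u) < 2L)
                msg <- c(msg, "at least 2 classes are required")
            if (!identical(u, seq.int(0L, length(u) - 1L)))
                msg <- c(msg, "label codes must form a contiguous range 0..C-1")
        }
        ln <- S4Vectors::metadata(object)$labelNames
        if (is.null(ln))
            msg <- c(msg, "metadata 'labelNames' is missing")
        else if (!all(as.character(lab) %in% names(ln)))
            msg <- c(msg, "every label code must be named in labelNames")
    }
    if (length(msg)) msg else TRUE
})

#' GeneRanking: per-gene relevance scores and rank order
#'
#' Result of \code{\link{rankGenes}} (or \code{\link{fScore}} /
#' \code{\link{anovaF}} directly). \code{scores} are non-negative (possibly
#' infinite for genes with zero within-class variance but distinct class
#' means); \code{rankOrder} is the permutation of gene indices sorted by
#' descending score, ties broken by lower original index.
#'
#' @slot scores numeric, one relevance score per gene.
#' @slot rankOrder integer permutation of \code{seq_along(scores)}.
#' @slot method character, \code{"anova"} or \code{"fscore"}.
#' @slot geneIds character, gene identifiers aligned with \code{scores}.
#'
#' @exportClass GeneRanking
setClass("GeneRanking",
    representation(scores = "numeric", rankOrder = "integer",
                   method = "character", geneIds = "character"))

setValidity("GeneRanking", function(object) {
    msg <- character(0)
    n <- length(object@scores)
    if (length(object@geneIds) != n)
        msg <- c(msg, "geneIds and scores lengths differ")
    if (!identical(sort(object@rankOrder), seq_len(n)))
        msg <- c(msg, "rankOrder is not a permutation of 1..n")
    else {
        s <- object@scores[object@rankOrder]
        if (n > 1L && any(diff(s) > 0, na.rm = TRUE))
            msg <- c(msg, "scores[rankOrder] must be non-increasing")
    }
    if (any(is.na(object@scores)))
        msg <- c(msg, "scores must not be NA")
    if (any(object@scores < 0))
        msg <- c(msg, "scores must be non-negative")
    if (!object@method %in% c("anova", "fscore"))
        msg <- c(msg, "method must be 'anova' or 'fscore'")
    if (length(msg)) msg else TRUE
})

#' GNRConfig: tunables of the GNR search
#'
#' All knobs of the optimizer in one validated object; see
#' \code{\link{gnrConfig}} for defaults and units.
#'
#' @slot populationSize integer, number of candidate solutions.
#' @slot maxGenerations integer, hard cap on generations.
#' @slot patience integer, early stop after this many consecutive
#'   non-improving generations.
#' @slot nRuns integer, independent restarts used by the experiment harness.
#' @slot pCrossover numeric in [0,1], probability that fusion is replaced by
#'   uniform crossover.
#' @slot pInheritBest numeric in [0,1], per-component probability of
#'   inheriting from the best parent during crossover.
#' @slot subsetSizes integer vector, gene subset sizes swept by the harness.
#' @slot pBeta numeric in [0,1], fission branch probability.
#' @slot levyAlpha positive numeric, Levy flight scale.
#' @slot levyExponent numeric in (1,2], Levy stability exponent.
#' @slot stagnationEpsilon positive numeric, threshold under which a
#'   difference vector counts as degenerate.
#' @slot targetFitness numeric, stop once best fitness reaches this value
#'   (the LOOCV-accuracy objective is bounded by 1).
#' @slot neutron character, "mean" or "product": how the two neutron peers
#'   are combined.
#' @slot seed integer or NA, RNG seed for a single run.
#'
#' @exportClass GNRConfig
setClass("GNRConfig",
    representation(populationSize = "integer", maxGenerations = "integer",
                   patience = "integer", nRuns = "integer",
                   pCrossover = "numeric", pInheritBest = "numeric",
                   subsetSizes = "integer", pBeta = "numeric",
                   levyAlpha = "numeric", levyExponent = "numeric",
                   stagnationEpsilon = "numeric", targetFitness = "numeric",
                   neutron = "character", seed = "integer"))

setValidity("GNRConfig", function(object) {
    msg <- character(0)
    chkCount <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 1L)
            c(msg, paste0(nm, " must be a count >= 1")) else msg
    }
    msg <- chkCount(object@populationSize, "populationSize")
    msg <- chkCount(object@maxGenerations, "maxGenerations")
    msg <- chkCount(object@patience, "patience")
    msg <- chkCount(object@nRuns, "nRuns")
    for (nm in c("pCrossover", "pInheritBest", "pBeta")) {
        p <- slot(object, nm)
        if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
            msg <- c(msg, paste0(nm, " must lie in [0,1]"))
    }
    if (length(object@subsetSizes) < 1L || any(object@subsetSizes < 1L))
        msg <- c(msg, "subsetSizes must be counts >= 1")
    if (object@levyAlpha <= 0)
        msg <- c(msg, "levyAlpha must be positive")
    if (object@levyExponent <= 1 || object@levyExponent > 2)
        msg <- c(msg, "levyExponent must lie in (1,2]")
    if (object@stagnationEpsilon <= 0)
        msg <- c(msg, "stagnationEpsilon must be positive")
    if (!object@neutron %in% c("mean", "product"))
        msg <- c(msg, "neutron must be 'mean' or 'product'")
    if (length(msg)) msg else TRUE
})

#' GNRTrajectory: one GNR run
#'
#' Record of a single optimizer run: the per-generation best fitness (a
#' non-decreasing sequence by the elitist update rule), the stopping
#' condition that fired, and the best candidate found.
#'
#' @slot bestFitness numeric, best-so-far fitness after each executed
#'   generation.
#' @slot generationsExecuted integer.
#' @slot stoppedEarly logical, TRUE unless the generation cap was hit.
#' @slot stopReason character: "patience", "target" or "max_generations".
#' @slot bestPosition numeric, best continuous position in [0,1]^D.
#' @slot bestSubset integer, decoded gene indices (1-based, ascending).
#' @slot bestFitnessValue numeric, fitness of the best candidate.
#' @slot subsetSize integer, k used for decoding.
#' @slot improvedAt integer, generations at which the best improved.
#' @slot initialBest numeric, best fitness of the initial population.
#'
#' @exportClass GNRTrajectory
setClass("GNRTrajectory",
    representation(bestFitness = "numeric", generationsExecuted = "integer",
                   stoppedEarly = "logical", stopReason = "character",
                   bestPosition = "numeric", bestSubset = "integer",
                   bestFitnessValue = "numeric", subsetSize = "integer",
                   improvedAt = "integer", initialBest = "numeric"))

setValidity("GNRTrajectory", function(object) {
    msg <- character(0)
    if (length(object@bestFitness) != object@generationsExecuted)
        msg <- c(msg, "bestFitness length must equal generationsExecuted")
    if (length(object@bestFitness) > 1L &&
        any(diff(object@bestFitness) < 0))
        msg <- c(msg, "bestFitness must be non-decreasing")
    if (length(object@bestSubset) != object@subsetSize)
        msg <- c(msg, "bestSubset must have subsetSize entries")
    if (anyDuplicated(object@bestSubset))
        msg <- c(msg, "bestSubset indices must be distinct")
    if (length(msg)) msg else TRUE
})
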