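#' Simulate an expression dataset with planted discriminative genes
#'
#' Gaussian class-shift model: background genes are
#' \eqn{N(0, \mathrm{noiseSd}^2)} independent of class; each planted gene
#' has class-c mean \eqn{c \cdot \mathrm{effectSize}} (classes coded
#' 0..C-1), so the shift between adjacent classes is \code{effectSize}
#' noise-sd units when \code{noiseSd = 1}. Missing cells are masked
#' completely at random, either at a Bernoulli rate
#' (\code{missingFraction}) or as an exact count (\code{nMissing}).
#' Defaults emulate the shape of a small two-class tumor/normal microarray
#' study (62 samples, 2000 genes, 3 planted markers, shift 3 sd).
#'
#' @param nSamples,nGenes matrix dimensions.
#' @param nClasses number of classes (>= 2).
#' @param plantedGenes integer indices of class-informative genes; default
#'   the first \code{nPlanted} genes.
#' @param nPlanted number of planted genes when \code{plantedGenes} is
#'   NULL.
#' @param effectSize between-class mean shift, in units of
#'   \code{noiseSd}.
#' @param noiseSd Gaussian noise standard deviation.
#' @param missingFraction Bernoulli masking rate in [0,1].
#' @param nMissing exact number of cells to mask (overrides
#'   \code{missingFraction}).
#' @param classProportions simplex vector of class proportions; default
#'   equal.
#' @param seed RNG seed; the generator is fully deterministic under it.
#' @return list with \code{dataset} (a \linkS4class{GeneExpressionSet})
#'   and \code{planted} (integer indices of the planted genes).
#' @examples
#' sim <- simulateExpression(nSamples = 20, nGenes = 50, seed = 1)
#' sim$planted
#' @export
simulateExpression <- function(nSamples = 62L, nGenes = 2000L,
                               nClasses = 2L, plantedGenes = NULL,
                               nPlanted = 3L, effectSize = 3,
                               noiseSd = 1, missingFraction = 0,
                               nMissing = NULL, classProportions = NULL,
                               seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(plantedGenes))
        plantedGenes <- seq_len(min(nPlanted, nGenes))
    plantedGenes <- as.integer(plantedGenes)
    if (anyDuplicated(plantedGenes) ||
        any(plantedGenes < 1L | plantedGenes > nGenes))
        stop("plantedGenes must be distinct indices in 1..", nGenes)
    if (is.null(classProportions))
        classProportions <- rep(1 / nClasses, nClasses)
    if (length(classProportions) != nClasses ||
        abs(sum(classProportions) - 1) > 1e-8)
        stop("classProportions must be a length-", nClasses,
             " vector summing to 1")

    counts <- floor(classProportions * nSamples)
    while (sum(counts) < nSamples)
        counts[which.max(classProportions * nSamples - counts)] <-
            counts[which.max(classProportions * nSamples - counts)] + 1L
    codes <- rep.int(seq_len(nClasses) - 1L, counts)

    vals <- matrix(stats::rnorm(nSamples * nGenes, sd = noiseSd),
                   nrow = nSamples, ncol = nGenes)
    for (gidx in plantedGenes)
        vals[, gidx] <- vals[, gidx] + codes * effectSize

    if (!is.null(nMissing)) {
        if (nMissing > length(vals)) stop("nMissing exceeds matrix size")
        if (nMissing > 0)
            vals[sample(length(vals), nMissing)] <- NA_real_
    } else if (missingFraction > 0) {
        vals[stats::runif(length(vals)) < missingFraction] <- NA_real_
    }

    labels <- sprintf("class%02d", codes)
    colnames(vals) <- sprintf("gene_%d", seq_len(nGenes))
    rownames(vals) <- sprintf("sample_%d", seq_len(nSamples))
    list(dataset = GeneExpressionSet(vals, labels = labels),
         planted = plantedGenes)
}

#' Audit missingness of a dataset
#'
#' Exact counts of missing cells and genes containing them, plus the
#' missing fraction — the audit one runs on a freshly loaded dataset
#' before deciding on an imputation strategy.
#'
#' @param ds a \linkS4class{GeneExpressionSet}.
#' @return A \code{PreprocessReport} list: \code{nMissingCells},
#'   \code{nGenesWithMissing}, \code{missingFraction},
#'   \code{genesConstantAfterImpute} (genes whose observed values are
#'   constant, i.e. that mean imputation would leave constant).
#' @export
maskReport <- function(ds) {
    a <- SummarizedExperiment::assay(ds, "exprs")  # genes x samples
    missByGene <- rowSums(is.na(a))
    constant <- vapply(seq_len(nrow(a)), function(i) {
        obs <- a[i, !is.na(a[i, ])]
        length(obs) > 0L && max(obs) == min(obs)
    }, logical(1))
    report <- list(
        nMissingCells = as.integer(sum(missByGene)),
        nGenesWithMissing = as.integer(sum(missByGene > 0)),
        missingFraction = sum(missByGene) / length(a),
        genesConstantAfterImpute = rownames(a)[constant])
    class(report) <- c("PreprocessReport", "list")
    report
}
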