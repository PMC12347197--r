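#' Two-class F-score gene ranking
#'
#' For each gene, the ratio of between-class to within-class variance for a
#' binary labelling: with class means \eqn{\mu^+,\mu^-}, global mean
#' \eqn{\mu} and class sample variances \eqn{s_+^2,s_-^2} (n-1
#' denominators),
#' \deqn{F = \frac{(\mu^+-\mu)^2 + (\mu^--\mu)^2}{s_+^2 + s_-^2}.}
#' When both class variances are zero the score is \code{Inf} if the class
#' means differ and 0 if they coincide.
#'
#' @param ds a \linkS4class{GeneExpressionSet} with exactly 2 classes, each
#'   holding at least 2 samples.
#' @return A \linkS4class{GeneRanking} with \code{method = "fscore"}.
#' @examples
#' m <- cbind(g1 = c(1, 2, 3, 5, 6, 7), g2 = rep(1, 6))
#' gds <- GeneExpressionSet(m, labels = rep(c("pos", "neg"), each = 3))
#' geneScores(fScore(gds))  # g1 = 4, g2 = 0
#' @export
fScore <- function(ds) {
    y <- classLabels(ds)
    if (length(unique(y)) != 2L)
        stop("fScore requires exactly 2 classes; use anovaF for ",
             length(unique(y)), " classes")
    a <- SummarizedExperiment::assay(ds, "exprs")  # genes x samples
    pos <- y == 1L; neg <- y == 0L
    if (sum(pos) < 2L || sum(neg) < 2L)
        stop("each class needs at least 2 samples")
    muP <- rowMeans(a[, pos, drop = FALSE])
    muN <- rowMeans(a[, neg, drop = FALSE])
    mu <- rowMeans(a)
    varP <- rowSums((a[, pos, drop = FALSE] - muP)^2) / (sum(pos) - 1L)
    varN <- rowSums((a[, neg, drop = FALSE] - muN)^2) / (sum(neg) - 1L)
    num <- (muP - mu)^2 + (muN - mu)^2
    den <- varP + varN
    scores <- ifelse(den > 0, num / den, ifelse(muP != muN, Inf, 0))
    newRanking(scores, "fscore", geneIds(ds))
}

#' One-way ANOVA F gene ranking
#'
#' Per-gene one-way ANOVA F statistic (between-group mean square over
#' within-group mean square) for two or more classes. Genes whose
#' within-group mean square is zero score \code{Inf} when group means
#' differ and 0 when all values are identical.
#'
#' @param ds a \linkS4class{GeneExpressionSet}; every class must hold at
#'   least 2 samples.
#' @return A \linkS4class{GeneRanking} with \code{method = "anova"}.
#' @examples
#' m <- cbind(g1 = c(1, 2, 3, 5, 6, 7))
#' gds <- GeneExpressionSet(m, labels = rep(c("pos", "neg"), each = 3))
#' geneScores(anovaF(gds))  # 24
#' @export
anovaF <- function(ds) {
    y <- classLabels(ds)
    classes <- sort(unique(y))
    C <- length(classes)
    sizes <- tabulate(y + 1L, nbins = C)
    if (any(sizes < 2L))
        stop("every class needs at least 2 samples for the ANOVA F ",
             "statistic (class code ", classes[which(sizes < 2L)[1L]],
             " has ", min(sizes), ")")
    a <- SummarizedExperiment::assay(ds, "exprs")
    n <- ncol(a)
    grand <- rowMeans(a)
    ssb <- 0
    ssw <- 0
    for (c in classes) {
        sel <- y == c
        mc <- rowMeans(a[, sel, drop = FALSE])
        ssb <- ssb + sum(sel) * (mc - grand)^2
        ssw <- ssw + rowSums((a[, sel, drop = FALSE] - mc)^2)
    }
    msb <- ssb / (C - 1L)
    msw <- ssw / (n - C)
    scores <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
    newRanking(scores, "anova", geneIds(ds))
}

newRanking <- function(scores, method, ids) {
    ord <- order(-scores, seq_along(scores), method = "radix")
    new("GeneRanking", scores = unname(scores), rankOrder = as.integer(ord),
        method = method, geneIds = ids)
}

#' Rank genes by class-discriminative power
#'
#' Dispatches to \code{\link{anovaF}} (the default, which also covers the
#' two-class case) or the two-class \code{\link{fScore}} variant.
#'
#' @param ds a \linkS4class{GeneExpressionSet}.
#' @param method \code{"anova"} (default) or \code{"fscore"}.
#' @return A \linkS4class{GeneRanking}.
#' @export
rankGenes <- function(ds, method = c("anova", "fscore")) {
    method <- match.arg(method)
    if (method == "anova") anovaF(ds) else fScore(ds)
}

#' @describeIn rankGenes per-gene scores, in original gene order.
#' @param x a \linkS4class{GeneRanking}.
#' @export
setMethod("geneScores", "GeneRanking", function(x) {
    stats::setNames(x@scores, x@geneIds)
})

#' @describeIn rankGenes permutation of gene indices by descending score.
#' @export
setMethod("rankOrder", "GeneRanking", function(x) x@rankOrder)

#' @describeIn rankGenes the scoring method used.
#' @export
setMethod("rankMethod", "GeneRanking", function(x) x@method)

setMethod("show", "GeneRanking", function(object) {
    cat("GeneRanking (", object@method, "): ", length(object@scores),
        " genes\n", sep = "")
    top <- utils::head(object@rankOrder, 5L)
    cat("top genes:", paste(sprintf("%s (%.4g)", object@geneIds[top],
                                    object@scores[top]), collapse = ", "),
        "\n")
    invisible(NULL)
})

#' Restrict a dataset to the top-k ranked genes
#'
#' Keeps the k highest-scoring genes. Within the selected pool genes retain
#' their original identifiers and relative original order; ties at the cut
#' boundary are broken in favour of the lower original index, so the
#' selection is deterministic and idempotent.
#'
#' @param ranking a \linkS4class{GeneRanking} computed on \code{ds}.
#' @param ds the matching \linkS4class{GeneExpressionSet}.
#' @param k number of genes to keep, \code{1 <= k <= nGenes(ds)}.
#' @return A \linkS4class{GeneExpressionSet} with \code{k} genes.
#' @export
selectTopK <- function(ranking, ds, k) {
    stopifnot(is(ranking, "GeneRanking"))
    if (length(ranking@scores) != nGenes(ds))
        stop("ranking and dataset have different gene counts")
    if (k < 1L || k > nGenes(ds))
        stop("k must lie in 1..", nGenes(ds), " (got ", k, ")")
    keep <- sort(ranking@rankOrder[seq_len(k)])
    restrictGenes(ds, keep)
}

#' Export a gene ranking as CSV
#'
#' Columns \code{gene_id}, \code{score}, \code{rank} (1 = most relevant).
#'
#' @param ranking a \linkS4class{GeneRanking}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportRanking <- function(ranking, path) {
    rk <- integer(length(ranking@scores))
    rk[ranking@rankOrder] <- seq_along(ranking@scores)
    df <- data.frame(gene_id = ranking@geneIds, score = ranking@scores,
                     rank = rk)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
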