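#' Construct a GeneExpressionSet
#'
#' Builds the package's central container from a samples-by-genes matrix and
#' per-sample class labels. Character or factor labels are encoded to
#' integer codes \code{0..C-1} in byte-lexicographic order of the class
#' names (see \code{\link{encodeLabels}}); integer-like labels are mapped by
#' ascending numeric value, so labels already coded \code{0..C-1} keep their
#' identity.
#'
#' @param values numeric matrix, samples in rows and genes in columns.
#'   Missing cells are \code{NA}.
#' @param geneIds character vector of unique gene identifiers (defaults to
#'   \code{colnames(values)}, or \code{gene_1..m}).
#' @param sampleIds character vector of sample identifiers (defaults to
#'   \code{rownames(values)}, or \code{sample_1..n}).
#' @param labels per-sample class labels: character, factor, or integer
#'   codes.
#' @param labelNames optional named character vector mapping code (as name)
#'   to class name; required only when \code{labels} are pre-encoded codes
#'   whose original names should be kept.
#' @return A \linkS4class{GeneExpressionSet}.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(NULL, paste0("g", 1:4)))
#' gds <- GeneExpressionSet(m, labels = c("tumor", "normal", "tumor"))
#' classLabels(gds)
#' @export
GeneExpressionSet <- function(values, geneIds = NULL, sampleIds = NULL,
                              labels, labelNames = NULL) {
    values <- as.matrix(values)
    if (is.null(geneIds)) geneIds <- colnames(values)
    if (is.null(geneIds)) geneIds <- paste0("gene_", seq_len(ncol(values)))
    if (is.null(sampleIds)) sampleIds <- rownames(values)
    if (is.null(sampleIds)) sampleIds <- paste0("sample_", seq_len(nrow(values)))
    if (length(geneIds) != ncol(values))
        stop("geneIds length must match the number of genes (columns)")
    if (length(labels) != nrow(values))
        stop("labels length must match the number of samples (rows)")

    if (is.null(labelNames)) {
        enc <- encodeLabels(labels)
        codes <- enc$codes
        labelNames <- enc$labelNames
    } else {
        codes <- as.integer(labels)
    }
    assay <- t(values)
    dimnames(assay) <- list(as.character(geneIds), as.character(sampleIds))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = assay),
        colData = S4Vectors::DataFrame(
            label = codes,
            className = unname(labelNames[as.character(codes)]),
            row.names = as.character(sampleIds)))
    S4Vectors::metadata(se)$labelNames <- labelNames
    new("GeneExpressionSet", se)
}

#' Accessors for GeneExpressionSet
#'
#' \code{exprValues} returns the expression matrix in samples-by-genes
#' orientation (the user-facing convention of this package);
#' \code{classLabels} returns the integer class codes; \code{labelNames}
#' the code-to-name mapping; \code{nSamples}/\code{nGenes} the dimensions.
#'
#' @param x a \linkS4class{GeneExpressionSet}.
#' @return See individual descriptions.
#' @name GeneExpressionSet-accessors
#' @aliases exprValues geneIds sampleIds classLabels labelNames nSamples
#'   nGenes preprocessReport
NULL

#' @rdname GeneExpressionSet-accessors
#' @export
setMethod("exprValues", "GeneExpressionSet", function(x) {
    t(SummarizedExperiment::assay(x, "exprs"))
})

#' @rdname GeneExpressionSet-accessors
#' @export
setMethod("geneIds", "GeneExpressionSet", function(x) rownames(x))

#' @rdname GeneExpressionSet-accessors
#' @export
setMethod("sampleIds", "GeneExpressionSet", function(x) colnames(x))

#' @rdname GeneExpressionSet-accessors
#' @export
setMethod("classLabels", "GeneExpressionSet", function(x) {
    SummarizedExperiment::colData(x)$label
})

#' @rdname GeneExpressionSet-accessors
#' @export
setMethod("labelNames", "GeneExpressionSet", function(x) {
    S4Vectors::metadata(x)$labelNames
})

#' @rdname GeneExpressionSet-accessors
#' @export
setMethod("nSamples", "GeneExpressionSet", function(x) ncol(x))

#' @rdname GeneExpressionSet-accessors
#' @export
setMethod("nGenes", "GeneExpressionSet", function(x) nrow(x))

#' @rdname GeneExpressionSet-accessors
#' @export
setMethod("preprocessReport", "GeneExpressionSet", function(x) {
    S4Vectors::metadata(x)$preprocess
})

setMethod("show", "GeneExpressionSet", function(object) {
    lab <- classLabels(object)
    ln <- labelNames(object)
    cat("GeneExpressionSet:", ncol(object), "samples x", nrow(object),
        "genes\n")
    tab <- table(factor(unname(ln[as.character(lab)]), levels = unname(ln)))
    cat("classes:", paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
    nmiss <- sum(is.na(SummarizedExperiment::assay(object, "exprs")))
    if (nmiss > 0) cat("missing cells:", nmiss, "\n")
    invisible(NULL)
})

# restrict to a subset of genes (columns of the user-facing matrix),
# keeping labels and metadata
restrictGenes <- function(x, geneIdx) {
    out <- x[geneIdx, ]
    new("GeneExpressionSet", out)
}
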