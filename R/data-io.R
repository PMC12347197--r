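MISSING_MARKERS <- c("", "?", "NA", "NaN")

#' Encode class labels as contiguous integer codes
#'
#' Character/factor labels are mapped to \code{0..C-1} in byte-lexicographic
#' order of the distinct class names (locale-independent, so the encoding is
#' stable across machines and file orderings). Numeric labels are mapped in
#' ascending numeric order, which preserves an existing \code{0..C-1}
#' coding as the identity.
#'
#' @param raw vector of class labels (character, factor or numeric).
#' @return list with \code{codes} (integer vector) and \code{labelNames}
#'   (named character vector, names are the codes).
#' @examples
#' encodeLabels(c("tumor", "normal", "tumor"))
#' @export
encodeLabels <- function(raw) {
    if (length(raw) < 1L) stop("no labels supplied")
    if (is.factor(raw)) raw <- as.character(raw)
    if (is.numeric(raw)) {
        lev <- sort(unique(raw))
        names <- as.character(lev)
    } else {
        raw <- as.character(raw)
        lev <- sort(unique(raw), method = "radix")
        names <- lev
    }
    if (length(lev) < 2L)
        stop("at least 2 distinct classes are required")
    codes <- match(raw, lev) - 1L
    labelNames <- stats::setNames(names, as.character(seq_along(lev) - 1L))
    list(codes = as.integer(codes), labelNames = labelNames)
}

#' Read an expression dataset from ARFF or delimited text
#'
#' Loads a labelled expression matrix and returns it in the package's
#' samples-by-genes convention regardless of the on-disk orientation.
#' Missing markers (empty field, \code{"?"}, \code{"NA"}, \code{NaN}) are
#' preserved as missing cells. Labels are encoded via
#' \code{\link{encodeLabels}}.
#'
#' CSV/TSV dialect: in \code{samples_by_genes} orientation the header row
#' carries gene identifiers plus the label column (and optionally a
#' \code{sample_id} column); in \code{genes_by_samples} orientation the
#' first column carries gene identifiers, the header carries sample
#' identifiers, and the row whose identifier equals \code{labelColumn}
#' carries the class labels. ARFF files are read with the standard dialect
#' (samples as instances, class as a nominal attribute).
#'
#' @param path file path.
#' @param format one of \code{"csv"}, \code{"tsv"}, \code{"arff"}; default
#'   guessed from the file extension.
#' @param orientation \code{"samples_by_genes"} (default) or
#'   \code{"genes_by_samples"} (delimited text only).
#' @param labelColumn name of the label column (or label row in
#'   genes-by-samples orientation). Default \code{"class"}.
#' @param idColumn optional name of a sample-identifier column; default
#'   uses \code{"sample_id"} when present.
#' @return A \linkS4class{GeneExpressionSet}.
#' @export
readExpression <- function(path,
                           format = c("auto", "csv", "tsv", "arff"),
                           orientation = c("samples_by_genes",
                                           "genes_by_samples"),
                           labelColumn = "class",
                           idColumn = NULL) {
    format <- match.arg(format)
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("file does not exist: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, arff = "arff", tsv = "tsv", "csv")
    }

    if (format == "arff") {
        df <- tryCatch(foreign::read.arff(path),
                       error = function(e) stop("malformed ARFF file '",
                                                path, "': ",
                                                conditionMessage(e)))
        return(frameToDataset(df, labelColumn, idColumn, path))
    }

    sep <- if (format == "tsv") "\t" else ","
    df <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = MISSING_MARKERS,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = ""),
        error = function(e) stop("malformed file '", path, "': ",
                                 conditionMessage(e)))

    if (orientation == "genes_by_samples") {
        geneCol <- colnames(df)[1L]
        rowIds <- as.character(df[[geneCol]])
        labRow <- which(rowIds == labelColumn)
        if (length(labRow) != 1L)
            stop("label row '", labelColumn, "' not found in ", path)
        sampleIdsV <- colnames(df)[-1L]
        rawLabels <- as.character(unlist(df[labRow, -1L]))
        expr <- df[-labRow, -1L, drop = FALSE]
        geneIdsV <- rowIds[-labRow]
        vals <- t(coerceNumericMatrix(expr, geneIdsV, path, byRow = TRUE))
        rownames(vals) <- sampleIdsV
        colnames(vals) <- geneIdsV
        return(GeneExpressionSet(vals, geneIds = geneIdsV,
                                 sampleIds = sampleIdsV, labels = rawLabels))
    }
    frameToDataset(df, labelColumn, idColumn, path)
}

# samples-by-genes data.frame -> GeneExpressionSet
frameToDataset <- function(df, labelColumn, idColumn, path) {
    if (!labelColumn %in% colnames(df))
        stop("label column '", labelColumn, "' not found in ", path)
    rawLabels <- df[[labelColumn]]
    df[[labelColumn]] <- NULL
    if (is.null(idColumn) && "sample_id" %in% colnames(df))
        idColumn <- "sample_id"
    if (!is.null(idColumn) && idColumn %in% colnames(df)) {
        sampleIdsV <- as.character(df[[idColumn]])
        df[[idColumn]] <- NULL
    } else {
        sampleIdsV <- paste0("sample_", seq_len(nrow(df)))
    }
    geneIdsV <- colnames(df)
    vals <- coerceNumericMatrix(df, geneIdsV, path, byRow = FALSE)
    rownames(vals) <- sampleIdsV
    GeneExpressionSet(vals, geneIds = geneIdsV, sampleIds = sampleIdsV,
                      labels = rawLabels)
}

# validate expression cells: anything non-numeric that is not a missing
# marker is a validation error naming the offending row
coerceNumericMatrix <- function(df, ids, path, byRow = FALSE) {
    m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df))
    for (j in seq_len(ncol(df))) {
        col <- df[[j]]
        if (is.numeric(col)) { m[, j] <- col; next }
        col <- as.character(col)
        col[col %in% MISSING_MARKERS] <- NA_character_
        num <- suppressWarnings(as.numeric(col))
        bad <- which(!is.na(col) & is.na(num))
        if (length(bad))
            stop("non-numeric expression value '", col[bad[1L]], "' in '",
                 path, "' (row ", bad[1L], ", column ", j, ")")
        m[, j] <- num
    }
    m
}

#' Mean-impute missing expression values
#'
#' Replaces every missing cell by the mean of the observed values of the
#' same gene. Observed cells are never changed. An audit of the missingness
#' (counts, fraction, genes left constant after imputation) is attached to
#' the returned object and available via \code{\link{preprocessReport}}.
#'
#' @param ds a \linkS4class{GeneExpressionSet}.
#' @return The imputed \linkS4class{GeneExpressionSet}; its
#'   \code{preprocessReport} is a list with \code{nMissingCells},
#'   \code{nGenesWithMissing}, \code{missingFraction} and
#'   \code{genesConstantAfterImpute}.
#' @export
imputeMissing <- function(ds) {
    a <- SummarizedExperiment::assay(ds, "exprs")  # genes x samples
    missByGene <- rowSums(is.na(a))
    allMissing <- which(missByGene == ncol(a))
    if (length(allMissing))
        stop("gene '", rownames(a)[allMissing[1L]],
             "' has no observed values; cannot mean-impute")
    nMissing <- sum(missByGene)
    report <- list(
        nMissingCells = as.integer(nMissing),
        nGenesWithMissing = as.integer(sum(missByGene > 0)),
        missingFraction = nMissing / length(a),
        genesConstantAfterImpute = character(0))
    if (nMissing > 0) {
        gm <- rowMeans(a, na.rm = TRUE)
        idx <- which(is.na(a), arr.ind = TRUE)
        a[idx] <- gm[idx[, 1L]]
    }
    constant <- apply(a, 1L, function(x) max(x) == min(x))
    report$genesConstantAfterImpute <- rownames(a)[constant]
    class(report) <- c("PreprocessReport", "list")
    SummarizedExperiment::assay(ds, "exprs") <- a
    S4Vectors::metadata(ds)$preprocess <- report
    ds
}

#' Z-score normalize each gene
#'
#' Centers and scales every gene to mean 0 and standard deviation 1. The
#' default scaling uses the sample standard deviation (n-1 denominator,
#' matching common library defaults); set \code{sdType = "population"} for
#' the n denominator. Genes with zero variance are mapped to all-zero
#' columns rather than producing division by zero.
#'
#' @param ds a \linkS4class{GeneExpressionSet} with no missing cells (run
#'   \code{\link{imputeMissing}} first).
#' @param sdType \code{"sample"} (default) or \code{"population"}.
#' @return The normalized \linkS4class{GeneExpressionSet}.
#' @export
zscoreNormalize <- function(ds, sdType = c("sample", "population")) {
    sdType <- match.arg(sdType)
    a <- SummarizedExperiment::assay(ds, "exprs")
    if (anyNA(a))
        stop("missing cells present; run imputeMissing() first")
    mu <- rowMeans(a)
    ctr <- a - mu
    n <- ncol(a)
    denom <- if (sdType == "sample") n - 1L else n
    sdv <- sqrt(rowSums(ctr^2) / denom)
    z <- ctr / ifelse(sdv > 0, sdv, 1)
    z[sdv == 0, ] <- 0
    SummarizedExperiment::assay(ds, "exprs") <- z
    ds
}

#' Write an expression dataset as CSV
#'
#' Samples-by-genes layout with a \code{sample_id} column and the class
#' labels (original names) in a \code{class} column; missing cells are
#' written as empty fields. \code{\link{readExpression}} round-trips this
#' format.
#'
#' @param ds a \linkS4class{GeneExpressionSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionCSV <- function(ds, path) {
    vals <- exprValues(ds)
    ln <- labelNames(ds)
    df <- data.frame(sample_id = sampleIds(ds), check.names = FALSE)
    df <- cbind(df, as.data.frame(vals, check.names = FALSE))
    df$class <- unname(ln[as.character(classLabels(ds))])
    utils::write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Write an expression dataset as ARFF
#'
#' Standard ARFF dialect: samples as instances, genes as numeric
#' attributes, class as a nominal attribute; missing cells become
#' \code{"?"}.
#'
#' @inheritParams writeExpressionCSV
#' @return \code{path}, invisibly.
#' @export
writeExpressionARFF <- function(ds, path) {
    vals <- exprValues(ds)
    ln <- labelNames(ds)
    df <- as.data.frame(vals, check.names = FALSE)
    df$class <- factor(unname(ln[as.character(classLabels(ds))]),
                       levels = unname(ln))
    foreign::write.arff(df, path)
    invisible(path)
}

#' Write a preprocessing report as JSON
#'
#' @param report a PreprocessReport list (from
#'   \code{\link{preprocessReport}} or \code{\link{maskReport}}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePreprocessReport <- function(report, path) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}
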