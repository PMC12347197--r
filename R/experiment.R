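#' Build and validate an experiment configuration
#'
#' Describes a full pipeline run: dataset source, preprocessing, filter
#' pool, optimizer settings and the multi-run sweep over subset sizes.
#' Invalid fields raise an error naming the field before any computation
#' starts.
#'
#' @param dataset a \linkS4class{GeneExpressionSet}, or a file path to be
#'   read with \code{\link{readExpression}}.
#' @param format,orientation,labelColumn passed to
#'   \code{\link{readExpression}} when \code{dataset} is a path.
#' @param filterMethod \code{"anova"} (default) or \code{"fscore"}.
#' @param poolSize filter pool size (top-ranked genes kept), default 500;
#'   capped at the number of genes.
#' @param gnr a \linkS4class{GNRConfig}.
#' @param masterSeed integer; run r of every subset size uses seed
#'   \code{masterSeed + r}.
#' @param sweepStopAtPerfect stop sweeping larger subset sizes after the
#'   first size whose best accuracy reaches 1 (the reporting convention
#'   for "smallest perfect panel"); disable to sweep all sizes.
#' @param outputDir optional directory for artifacts and the run log.
#' @param verbose emit progress messages.
#' @return list of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(dataset, format = "auto",
                             orientation = "samples_by_genes",
                             labelColumn = "class",
                             filterMethod = "anova", poolSize = 500L,
                             gnr = gnrConfig(), masterSeed = 1L,
                             sweepStopAtPerfect = TRUE, outputDir = NULL,
                             verbose = FALSE) {
    if (is.character(dataset)) {
        if (!file.exists(dataset))
            stop("config field 'dataset': file does not exist: ", dataset)
    } else if (!is(dataset, "GeneExpressionSet")) {
        stop("config field 'dataset': must be a file path or a ",
             "GeneExpressionSet")
    }
    if (!filterMethod %in% c("anova", "fscore"))
        stop("config field 'filterMethod': must be 'anova' or 'fscore'")
    if (!is.numeric(poolSize) || length(poolSize) != 1L || poolSize < 1)
        stop("config field 'poolSize': must be a count >= 1")
    if (!is(gnr, "GNRConfig"))
        stop("config field 'gnr': must be a GNRConfig")
    validObject(gnr)
    if (!is.numeric(masterSeed) || length(masterSeed) != 1L ||
        is.na(masterSeed))
        stop("config field 'masterSeed': must be a single integer")
    structure(list(dataset = dataset, format = format,
                   orientation = orientation, labelColumn = labelColumn,
                   filterMethod = filterMethod,
                   poolSize = as.integer(poolSize), gnr = gnr,
                   masterSeed = as.integer(masterSeed),
                   sweepStopAtPerfect = isTRUE(sweepStopAtPerfect),
                   outputDir = outputDir, verbose = isTRUE(verbose)),
              class = c("ExperimentConfig", "list"))
}

#' Read an experiment configuration from YAML
#'
#' Field names mirror \code{\link{experimentConfig}} and
#' \code{\link{gnrConfig}}; optimizer settings live under a \code{gnr}
#' block.
#'
#' @param path YAML file path.
#' @return list of class \code{ExperimentConfig}.
#' @export
readExperimentConfig <- function(path) {
    y <- yaml::read_yaml(path)
    gnrArgs <- y$gnr
    gnrCfg <- if (is.null(gnrArgs)) gnrConfig() else
        do.call(gnrConfig, gnrArgs)
    args <- y[setdiff(names(y), "gnr")]
    args$gnr <- gnrCfg
    do.call(experimentConfig, args)
}

#' Run the full gene-selection experiment
#'
#' The pipeline in its published order: mean imputation, per-gene Z-score
#' normalization, relevance ranking, restriction to the top-\code{poolSize}
#' pool, then for each subset size \code{nRuns} independent seeded
#' optimizer runs (run r uses seed \code{masterSeed + r}). Each run's best
#' subset is re-scored with the LOOCV-SVM wrapper to obtain its full
#' metrics; runs are aggregated per size into a \code{RunSummary}. When a
#' size attains best accuracy 1 the sweep stops by default (smallest
#' perfect panel convention).
#'
#' When \code{cfg$outputDir} is set, a plain-text log records every run's
#' seed, improvement generations and stop reason, and summary tables are
#' written via \code{\link{reportTables}}.
#'
#' @param cfg an \code{ExperimentConfig}, see
#'   \code{\link{experimentConfig}}.
#' @return list with \code{summaries} (one \code{RunSummary} per swept
#'   size), \code{smallestPerfectSize} (or NA), \code{bestSubsetGenes}
#'   (gene identifiers of the best subset found at the reported size),
#'   \code{pool} (the filtered \linkS4class{GeneExpressionSet}) and
#'   \code{datasetInfo}.
#' @export
runExperiment <- function(cfg) {
    stopifnot(inherits(cfg, "ExperimentConfig"))
    ds <- cfg$dataset
    if (is.character(ds))
        ds <- readExpression(ds, format = cfg$format,
                             orientation = cfg$orientation,
                             labelColumn = cfg$labelColumn)
    totalGenes <- nGenes(ds)
    ds <- imputeMissing(ds)
    ds <- zscoreNormalize(ds)
    ranking <- rankGenes(ds, method = cfg$filterMethod)
    poolK <- min(cfg$poolSize, nGenes(ds))
    pool <- selectTopK(ranking, ds, poolK)

    logLines <- character(0)
    say <- function(...) {
        line <- paste0(...)
        logLines <<- c(logLines, line)
        if (cfg$verbose) message(line)
    }
    say("experiment: ", nSamples(ds), " samples, ", totalGenes,
        " genes, pool ", poolK, ", filter ", cfg$filterMethod,
        ", master seed ", cfg$masterSeed)

    gnrCfg <- cfg$gnr
    summaries <- list()
    bestGenesPerSize <- list()
    smallestPerfect <- NA_integer_
    for (k in sort(gnrCfg@subsetSizes)) {
        results <- vector("list", gnrCfg@nRuns)
        bestRunFit <- -Inf
        bestRunGenes <- character(0)
        for (r in seq_len(gnrCfg@nRuns)) {
            runCfg <- gnrCfg
            runCfg@seed <- cfg$masterSeed + r
            traj <- runGNR(pool, k, runCfg)
            res <- loocvFitness(pool, traj@bestSubset)
            results[[r]] <- res
            say("k=", k, " run=", r, " seed=", runCfg@seed,
                " acc=", format(res$accuracy, digits = 6),
                " stop=", traj@stopReason,
                " improvedAt=[", paste(traj@improvedAt, collapse = ","),
                "]")
            if (res$accuracy > bestRunFit) {
                bestRunFit <- res$accuracy
                bestRunGenes <- geneIds(pool)[traj@bestSubset]
            }
        }
        summ <- aggregateRuns(results, subsetSize = k)
        summaries[[as.character(k)]] <- summ
        bestGenesPerSize[[as.character(k)]] <- bestRunGenes
        if (is.na(smallestPerfect) && summ$bestAcc >= 1) {
            smallestPerfect <- k
            if (cfg$sweepStopAtPerfect) {
                say("perfect accuracy at k=", k, "; stopping sweep")
                break
            }
        }
    }

    reportSize <- if (!is.na(smallestPerfect)) smallestPerfect else
        names(summaries)[which.max(vapply(summaries,
                                          function(s) s$bestAcc,
                                          numeric(1)))]
    bestSubsetGenes <- bestGenesPerSize[[as.character(reportSize)]]

    out <- list(summaries = unname(summaries),
                smallestPerfectSize = smallestPerfect,
                bestSubsetGenes = bestSubsetGenes,
                pool = pool,
                datasetInfo = list(totalGenes = totalGenes,
                                   filteredGenes = poolK,
                                   nSamples = nSamples(ds)))
    if (!is.null(cfg$outputDir)) {
        dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
        writeLines(logLines, file.path(cfg$outputDir, "run.log"))
        reportTables(out, dir = cfg$outputDir)
    }
    out
}

#' Write experiment summary tables
#'
#' Renders the per-size summaries in the standard benchmark layout
#' (Dataset, Total Genes, Filtered Genes, Selected Genes, Best/Average/
#' Worst accuracy, Precision, Recall, F1, CI) as CSV and JSON, plus the
#' predictive gene list of the best subset as JSON. A constant-accuracy
#' interval renders as e.g. \code{"100\% (constant)"}.
#'
#' @param result the list returned by \code{\link{runExperiment}}, or a
#'   list of \code{RunSummary} objects (then \code{bestSubsetGenes} must
#'   be given).
#' @param dir output directory (created if needed).
#' @param datasetName label for the Dataset column.
#' @param bestSubsetGenes character vector of gene identifiers; must be
#'   non-empty.
#' @return (invisibly) the summary data.frame.
#' @export
reportTables <- function(result, dir, datasetName = "dataset",
                         bestSubsetGenes = NULL) {
    if (!is.null(result$summaries)) {
        summaries <- result$summaries
        if (is.null(bestSubsetGenes))
            bestSubsetGenes <- result$bestSubsetGenes
        info <- result$datasetInfo
    } else {
        summaries <- result
        info <- list(totalGenes = NA_integer_, filteredGenes = NA_integer_)
    }
    if (length(summaries) < 1L) stop("no summaries to report")
    if (is.null(bestSubsetGenes) || length(bestSubsetGenes) < 1L)
        stop("predictive gene list is empty")
    df <- do.call(rbind, lapply(summaries, function(s) {
        data.frame(Dataset = datasetName,
                   TotalGenes = info$totalGenes,
                   FilteredGenes = info$filteredGenes,
                   SelectedGenes = s$subsetSize,
                   Best = formatPercent(s$bestAcc),
                   Average = formatPercent(s$avgAcc),
                   Worst = formatPercent(s$worstAcc),
                   Precision = formatPercent(s$precision),
                   Recall = formatPercent(s$recall),
                   F1 = formatPercent(s$f1),
                   CI = formatCI(s))
    }))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(
        list(table = df, predictive_genes = bestSubsetGenes),
        file.path(dir, "summary.json"), dataframe = "rows",
        auto_unbox = TRUE, digits = NA)
    invisible(df)
}
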