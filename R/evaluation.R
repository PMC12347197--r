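# linear SVM (C fixed by caller) train/predict on integer class codes;
# multiclass is one-vs-rest on decision values, ties to the lower code
svmPredict <- function(trainX, trainY, testX, C = 1) {
    classes <- sort(unique(trainY))
    if (length(classes) < 2L)
        stop("training fold lost all but one class")
    if (is.vector(testX)) testX <- matrix(testX, nrow = 1L)
    if (length(classes) == 2L) {
        yf <- factor(trainY, levels = classes)
        fit <- e1071::svm(trainX, yf, kernel = "linear", cost = C,
                          scale = FALSE, type = "C-classification")
        return(as.integer(as.character(predict(fit, testX))))
    }
    dv <- matrix(NA_real_, nrow = nrow(testX), ncol = length(classes))
    for (ci in seq_along(classes)) {
        yf <- factor(ifelse(trainY == classes[ci], "pos", "neg"),
                     levels = c("pos", "neg"))
        fit <- e1071::svm(trainX, yf, kernel = "linear", cost = C,
                          scale = FALSE, type = "C-classification")
        p <- predict(fit, testX, decision.values = TRUE)
        d <- attr(p, "decision.values")
        # libsvm orients the decision value by whichever label it saw
        # first in the training data; normalize so positive means "pos"
        if (identical(colnames(d), "neg/pos")) d <- -d
        dv[, ci] <- as.numeric(d)
    }
    classes[max.col(dv, ties.method = "first")]
}

#' Classification metrics from pooled predictions
#'
#' Accuracy is the exact-match fraction. Precision, recall and F1 are
#' computed per class and combined by support-weighted average (weights =
#' class frequencies in \code{yTrue}); a class with an empty
#' predicted-positive or denominator-zero F1 contributes 0 for that
#' metric.
#'
#' @param yTrue integer class codes.
#' @param yPred integer class codes; every predicted label must appear in
#'   the encoding of \code{yTrue}.
#' @return list with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}.
#' @examples
#' classificationMetrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
classificationMetrics <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred) || length(yTrue) < 1L)
        stop("yTrue and yPred must have equal positive length")
    classes <- sort(unique(yTrue))
    if (!all(yPred %in% classes))
        stop("predicted label outside the encoding of the true labels")
    acc <- mean(yTrue == yPred)
    prec <- rec <- f1 <- numeric(length(classes))
    w <- numeric(length(classes))
    for (ci in seq_along(classes)) {
        c <- classes[ci]
        tp <- sum(yTrue == c & yPred == c)
        fp <- sum(yTrue != c & yPred == c)
        fn <- sum(yTrue == c & yPred != c)
        prec[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
        rec[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
        f1[ci] <- if (prec[ci] + rec[ci] > 0)
            2 * prec[ci] * rec[ci] / (prec[ci] + rec[ci]) else 0
        w[ci] <- sum(yTrue == c)
    }
    w <- w / sum(w)
    list(accuracy = acc,
         precision = sum(w * prec),
         recall = sum(w * rec),
         f1 = sum(w * f1))
}

#' Leave-one-out cross-validated SVM fitness of a gene subset
#'
#' The wrapper objective: each sample is held out in turn, a linear-kernel
#' SVM (regularization C, default 1) is trained on the remaining samples
#' restricted to the subset's genes, and the held-out sample is predicted.
#' Metrics are computed from the pooled predictions. Fully deterministic
#' (no randomness anywhere in the fold loop).
#'
#' @param ds a \linkS4class{GeneExpressionSet} (no missing cells).
#' @param subset integer vector of gene indices (1-based), length >= 1.
#' @param C SVM regularization parameter.
#' @return A \code{FitnessResult} list: \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f1}, \code{predictions} (per-sample predicted
#'   codes, in sample order).
#' @export
loocvFitness <- function(ds, subset, C = 1) {
    if (length(subset) < 1L) stop("subset must contain at least one gene")
    X <- exprValues(ds)[, subset, drop = FALSE]
    y <- classLabels(ds)
    n <- length(y)
    if (n < 3L) stop("LOOCV needs at least 3 samples")
    if (any(table(y) < 2L))
        stop("every class needs at least 2 samples (a LOOCV fold would ",
             "otherwise lose a class)")
    preds <- integer(n)
    for (i in seq_len(n))
        preds[i] <- svmPredict(X[-i, , drop = FALSE], y[-i],
                               X[i, , drop = FALSE], C)
    res <- classificationMetrics(y, preds)
    res$predictions <- preds
    class(res) <- c("FitnessResult", "list")
    res
}

#' Stratified k-fold cross-validated SVM fitness
#'
#' Samples are shuffled within class under \code{seed}, ordered by class,
#' and fold labels are assigned cyclically across that ordering, so every
#' fold receives a near-proportional share of each class. With
#' \code{folds = nSamples(ds)} every fold is a singleton and the result
#' equals \code{\link{loocvFitness}} exactly.
#'
#' @inheritParams loocvFitness
#' @param folds number of folds, \code{2 <= folds <= nSamples(ds)}.
#' @param seed RNG seed for the fold assignment.
#' @return A \code{FitnessResult} list (see \code{\link{loocvFitness}}).
#' @export
kfoldFitness <- function(ds, subset, folds, seed = 1L, C = 1) {
    if (length(subset) < 1L) stop("subset must contain at least one gene")
    y <- classLabels(ds)
    n <- length(y)
    if (folds < 2L) stop("folds must be >= 2")
    if (folds > n) stop("folds must not exceed the number of samples")
    X <- exprValues(ds)[, subset, drop = FALSE]
    set.seed(seed)
    ord <- unlist(lapply(sort(unique(y)), function(c) {
        idx <- which(y == c)
        if (length(idx) > 1L) sample(idx) else idx
    }))
    foldId <- integer(n)
    foldId[ord] <- rep_len(seq_len(folds), n)
    preds <- integer(n)
    for (f in seq_len(folds)) {
        test <- which(foldId == f)
        preds[test] <- svmPredict(X[-test, , drop = FALSE], y[-test],
                                  X[test, , drop = FALSE], C)
    }
    res <- classificationMetrics(y, preds)
    res$predictions <- preds
    class(res) <- c("FitnessResult", "list")
    res
}

#' Aggregate repeated runs into a summary row
#'
#' Best/average/worst accuracy over independent runs; precision, recall
#' and F1 of the best run (first run attaining the best accuracy); and a
#' Student-t 95 percent confidence interval on the per-run accuracies.
#' When all runs agree the interval is degenerate and flagged
#' \code{"constant"}; a single run yields no interval
#' (\code{"unavailable"}).
#'
#' @param results list of \code{FitnessResult}s (one per run).
#' @param level confidence level, default 0.95.
#' @param subsetSize optional subset size annotation.
#' @return A \code{RunSummary} list: \code{subsetSize}, \code{nRuns},
#'   \code{bestAcc}, \code{avgAcc}, \code{worstAcc}, \code{precision},
#'   \code{recall}, \code{f1}, \code{ciLow}, \code{ciHigh},
#'   \code{ciType} ("t", "constant" or "unavailable").
#' @export
aggregateRuns <- function(results, level = 0.95, subsetSize = NA_integer_) {
    if (length(results) < 1L) stop("no run results to aggregate")
    accs <- vapply(results, function(r) r$accuracy, numeric(1))
    n <- length(accs)
    bestRun <- which.max(accs)
    out <- list(subsetSize = as.integer(subsetSize), nRuns = n,
                bestAcc = max(accs), avgAcc = mean(accs),
                worstAcc = min(accs),
                precision = results[[bestRun]]$precision,
                recall = results[[bestRun]]$recall,
                f1 = results[[bestRun]]$f1)
    if (n == 1L) {
        out$ciLow <- NA_real_; out$ciHigh <- NA_real_
        out$ciType <- "unavailable"
    } else if (max(accs) == min(accs)) {
        out$ciLow <- out$avgAcc; out$ciHigh <- out$avgAcc
        out$ciType <- "constant"
    } else {
        half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) *
            stats::sd(accs) / sqrt(n)
        out$ciLow <- out$avgAcc - half
        out$ciHigh <- out$avgAcc + half
        out$ciType <- "t"
    }
    class(out) <- c("RunSummary", "list")
    out
}

#' @export
print.RunSummary <- function(x, ...) {
    cat(sprintf("RunSummary (k = %s, %d runs): best %s avg %s worst %s; CI %s\n",
                x$subsetSize, x$nRuns, formatPercent(x$bestAcc),
                formatPercent(x$avgAcc), formatPercent(x$worstAcc),
                formatCI(x)))
    invisible(x)
}

formatPercent <- function(x) {
    s <- sprintf("%.2f", 100 * x)
    s <- sub("0+$", "", s)
    s <- sub("\\.$", "", s)
    paste0(s, "%")
}

formatCI <- function(s) {
    switch(s$ciType,
           constant = paste0(formatPercent(s$avgAcc), " (constant)"),
           unavailable = "n/a",
           sprintf("[%s, %s]", formatPercent(s$ciLow),
                   formatPercent(s$ciHigh)))
}
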