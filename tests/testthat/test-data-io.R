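test_that("CSV write/read round-trips values, ids and labels exactly", {
    m <- matrix(c(1.5, -2, 3, 0.25, 4, -1, 2, 0, 7, 8, -3, 0.5),
                nrow = 3, dimnames = list(NULL, paste0("g", 1:4)))
    gds <- GeneExpressionSet(m, sampleIds = c("s1", "s2", "s3"),
                             labels = c("tumor", "normal", "tumor"))
    f <- withr::local_tempfile(fileext = ".csv")
    writeExpressionCSV(gds, f)
    back <- readExpression(f, format = "csv")
    expect_identical(unname(exprValues(back)), unname(m))
    expect_identical(geneIds(back), paste0("g", 1:4))
    expect_identical(sampleIds(back), c("s1", "s2", "s3"))
    expect_identical(classLabels(back), classLabels(gds))
    expect_identical(labelNames(back), labelNames(gds))
})

test_that("ARFF missing marker yields exactly one missing cell at its coordinate", {
    m <- matrix(as.numeric(1:12), nrow = 3,
                dimnames = list(NULL, paste0("g", 1:4)))
    m[2, 3] <- NA
    gds <- GeneExpressionSet(m, labels = c("a", "b", "a"))
    f <- withr::local_tempfile(fileext = ".arff")
    writeExpressionARFF(gds, f)
    expect_true(any(grepl("\\?", readLines(f))))
    back <- readExpression(f, format = "arff")
    vals <- exprValues(back)
    expect_identical(which(is.na(vals)), which(is.na(m)))
    expect_equal(sum(is.na(vals)), 1L)
    expect_identical(vals[!is.na(vals)], m[!is.na(m)])
})

test_that("genes-by-samples orientation transposes to samples-by-genes", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("gene,s1,s2,s3",
                 "class,a,b,a",
                 "g1,1,2,3",
                 "g2,4,5,6",
                 "g3,7,8,9",
                 "g4,10,11,12"), f)
    gds <- readExpression(f, orientation = "genes_by_samples")
    expect_equal(nSamples(gds), 3L)
    expect_equal(nGenes(gds), 4L)
    expected <- t(matrix(1:12, nrow = 4, byrow = TRUE))
    expect_identical(unname(exprValues(gds)), expected * 1)
    expect_identical(geneIds(gds), paste0("g", 1:4))
    expect_identical(classLabels(gds), c(0L, 1L, 0L))
})

test_that("non-numeric expression cell raises a validation error naming the row", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("g1,g2,class", "1,2,a", "oops,4,b", "5,6,a"), f)
    expect_error(readExpression(f), "oops.*row 2")
})

test_that("mean imputation fills gene means, leaves observed cells, counts exactly", {
    # identity when nothing is missing
    gds <- toyBinary()
    out <- imputeMissing(gds)
    expect_identical(exprValues(out), exprValues(gds))
    expect_equal(preprocessReport(out)$nMissingCells, 0L)

    # midpoint of a symmetric pair
    m <- cbind(g1 = c(1, NA, 3), g2 = c(2, 2, 2))
    gds <- GeneExpressionSet(m, labels = c("a", "b", "a"))
    out <- imputeMissing(gds)
    expect_equal(exprValues(out)[2, "g1"], 2)
    rep <- preprocessReport(out)
    expect_equal(rep$nMissingCells, 1L)
    expect_equal(rep$nGenesWithMissing, 1L)
    expect_equal(rep$missingFraction, 1 / 6)
    expect_true("g2" %in% rep$genesConstantAfterImpute)

    # random 62 x 50 with 5% masked vs an independent per-column fill
    set.seed(7)
    vals <- matrix(rnorm(62 * 50), 62, 50,
                   dimnames = list(NULL, paste0("g", 1:50)))
    mask <- matrix(runif(62 * 50) < 0.05, 62, 50)
    mask[, 1] <- c(TRUE, rep(FALSE, 61))  # keep every gene observed somewhere
    masked <- vals
    masked[mask] <- NA
    gds <- GeneExpressionSet(masked, labels = rep(c("a", "b"), each = 31))
    out <- imputeMissing(gds)
    got <- exprValues(out)
    oracle <- masked
    for (j in seq_len(ncol(oracle))) {
        col <- masked[, j]
        fill <- mean(col[!is.na(col)])
        for (i in seq_len(nrow(oracle)))
            if (is.na(oracle[i, j])) oracle[i, j] <- fill
    }
    expect_equal(unname(got), unname(oracle))
    # observed cells untouched
    expect_identical(got[!mask], masked[!mask])
    # exact count
    expect_equal(preprocessReport(out)$nMissingCells, sum(mask))
    expect_equal(preprocessReport(out)$nGenesWithMissing,
                 sum(colSums(mask) > 0))
})

test_that("imputation refuses a gene with no observed values, naming it", {
    m <- cbind(g1 = c(NA, NA, NA), g2 = c(1, 2, 3))
    gds <- GeneExpressionSet(m, labels = c("a", "b", "a"))
    expect_error(imputeMissing(gds), "g1")
})

test_that("z-score normalization hits mean 0 / sd 1 per gene and is idempotent", {
    m <- cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
    gds <- GeneExpressionSet(m, labels = c("a", "b", "a"))
    out <- exprValues(zscoreNormalize(gds))
    expect_equal(out[, "g1"], c(-1, 0, 1), ignore_attr = TRUE)
    expect_equal(out[, "g2"], c(0, 0, 0), ignore_attr = TRUE)
    # population-sd convention
    outP <- exprValues(zscoreNormalize(gds, sdType = "population"))
    expect_equal(outP[, "g1"],
                 c(-1, 0, 1) * sqrt(3 / 2), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(outP[1, "g1"], -1.2247, tolerance = 1e-4)

    set.seed(11)
    m2 <- matrix(rnorm(200, 5, 3), 20, 10,
                 dimnames = list(NULL, paste0("g", 1:10)))
    g2 <- GeneExpressionSet(m2, labels = rep(c("a", "b"), 10))
    z1 <- zscoreNormalize(g2)
    v1 <- exprValues(z1)
    expect_true(all(abs(colMeans(v1)) < 1e-9))
    expect_true(all(abs(apply(v1, 2, sd) - 1) < 1e-9))
    z2 <- zscoreNormalize(z1)
    expect_equal(exprValues(z2), v1, tolerance = 1e-9)
    expect_error(zscoreNormalize(GeneExpressionSet(
        cbind(g1 = c(1, NA, 3)), labels = c("a", "b", "a"))), "impute")
})

test_that("label encoding is lexicographic, stable, and identity on integer codes", {
    enc <- encodeLabels(c("tumor", "normal", "tumor"))
    expect_identical(enc$codes, c(1L, 0L, 1L))
    expect_identical(enc$labelNames, c(`0` = "normal", `1` = "tumor"))

    enc2 <- encodeLabels(c("B", "AML", "T", "AML"))
    expect_identical(enc2$codes, c(1L, 0L, 2L, 0L))

    enc3 <- encodeLabels(c(0L, 1L, 2L, 1L))
    expect_identical(enc3$codes, c(0L, 1L, 2L, 1L))

    expect_error(encodeLabels(c("a", "a")), "2 distinct classes")
})

test_that("preprocessing chain is deterministic across repeated invocations", {
    sim <- simulateExpression(nSamples = 15, nGenes = 30,
                              missingFraction = 0.08, seed = 5)
    run <- function() {
        d <- zscoreNormalize(imputeMissing(sim$dataset))
        list(v = exprValues(d), r = preprocessReport(imputeMissing(sim$dataset)))
    }
    a <- run(); b <- run()
    expect_identical(a$v, b$v)
    expect_identical(a$r, b$r)
})
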